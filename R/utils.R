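# internal: run code under a local, restored RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# internal: derive a named substream seed from a base seed, kept below 2^31
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + as.numeric(index) * 17 + 1) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
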