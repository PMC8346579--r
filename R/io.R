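#' Read a 3D volume from NIfTI or MetaImage
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; MetaImage (`.mhd` with a
#' companion `.raw`) through a built-in reader. Values and spacing round-trip
#' bit-exactly for integer masks. NIfTI volumes with a complete orientation
#' matrix are normalized to RAS axis order so that on-disk orientation does
#' not leak into the internal index convention.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @return a [volume_grid].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    img <- tryCatch({ RNifti::orientation(img) <- "RAS"; img }, error = function(e) img)
    v <- as.array(img)
    if (length(dim(v)) == 4L && dim(v)[4] == 1L) v <- array(v, dim(v)[1:3])
    if (length(dim(v)) != 3L)
      stop("expected a 3D image, got shape ", paste(dim(v), collapse = "x"),
           " in ", path)
    sp <- RNifti::pixdim(img)[1:3]
    volume_grid(v, abs(sp))
  } else if (ext == ".mhd") {
    read_metaimage(path)
  } else {
    stop("unknown volume extension '", ext, "' (expected .nii, .nii.gz or .mhd)")
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' @param grid a [volume_grid] (or 3D array; unit spacing assumed).
#' @param path output path (`.nii`, `.nii.gz` or `.mhd`).
#' @param datatype storage type: `"auto"` writes binary masks as uint8 and
#'   everything else as float64; or one of `"uint8"`, `"int16"`, `"float"`,
#'   `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, datatype = "auto") {
  v <- if (inherits(grid, "volume_grid")) vg_values(grid) else {
    if (length(dim(grid)) != 3L) stop("expected a 3D array")
    array(as.numeric(grid), dim(grid))
  }
  sp <- voxel_spacing(grid)
  if (datatype == "auto") {
    u <- unique(as.vector(v))
    datatype <- if (all(u %in% c(0, 1))) "uint8" else "double"
  }
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(v)
    # record spacing both in pixdim and in a scanner-anatomy sform so the
    # reader's orientation normalization has a defined frame
    xf <- structure(rbind(cbind(diag(sp), 0), c(0, 0, 0, 1)), code = 2L)
    RNifti::sform(img) <- xf
    RNifti::qform(img) <- xf
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path, datatype = datatype)
  } else if (ext == ".mhd") {
    write_metaimage(v, sp, path, datatype)
  } else {
    stop("unknown volume extension '", ext, "'")
  }
  invisible(path)
}

# --- MetaImage (.mhd/.raw): minimal uncompressed reader/writer --------------

read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  if (!identical(kv[["NDims"]], "3"))
    stop("MetaImage: expected NDims = 3, got ", kv[["NDims"]])
  if (identical(toupper(kv[["CompressedData"]]), "TRUE"))
    stop("MetaImage: compressed data is not supported")
  dims <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1]])
  sp <- if (!is.null(kv[["ElementSpacing"]]))
    as.numeric(strsplit(kv[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  type <- kv[["ElementType"]]
  raw_file <- kv[["ElementDataFile"]]
  if (is.null(raw_file) || identical(raw_file, "LIST"))
    stop("MetaImage: ElementDataFile must name a single raw file")
  raw_path <- file.path(dirname(path), raw_file)
  n <- prod(dims)
  big <- identical(toupper(kv[["BinaryDataByteOrderMSB"]]), "TRUE") ||
         identical(toupper(kv[["ElementByteOrderMSB"]]), "TRUE")
  endian <- if (big) "big" else "little"
  con <- file(raw_path, "rb"); on.exit(close(con))
  v <- switch(type,
    "MET_UCHAR"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian)),
    "MET_CHAR"   = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE, endian = endian)),
    "MET_SHORT"  = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE, endian = endian)),
    "MET_USHORT" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian)),
    "MET_INT"    = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    "MET_FLOAT"  = readBin(con, "numeric", n, size = 4, endian = endian),
    "MET_DOUBLE" = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("MetaImage: unsupported ElementType ", type))
  if (length(v) != n) stop("MetaImage: raw file shorter than DimSize implies")
  volume_grid(array(v, dims), sp)
}

write_metaimage <- function(v, spacing, path, datatype) {
  type <- switch(datatype,
                 uint8 = "MET_UCHAR", int16 = "MET_SHORT",
                 float = "MET_FLOAT", double = "MET_DOUBLE",
                 stop("unsupported MetaImage datatype ", datatype))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(v), collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, digits = 10), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", raw_name))
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb"); on.exit(close(con))
  switch(datatype,
    uint8  = writeBin(as.integer(v), con, size = 1),
    int16  = writeBin(as.integer(v), con, size = 2),
    float  = writeBin(as.numeric(v), con, size = 4),
    double = writeBin(as.numeric(v), con, size = 8))
  invisible(path)
}
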