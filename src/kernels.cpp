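// Numerical kernels for the 3D U-Net and the volumetric post-processing.
// Feature maps are stored channels-last: dim (nx, ny, nz, C), so the inner
// convolution loops run over contiguous x-rows and vectorize.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: (nx,ny,nz,Cin); w: (Cout,Cin,k,k,k); b: length Cout.
// pad 0 (valid) or (k-1)/2 (same). Returns (ox,oy,oz,Cout).
// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], Cin = xd[3];
  const int Cout = wd[0], k = wd[2];
  const int ox = nx - k + 1 + 2 * pad, oy = ny - k + 1 + 2 * pad, oz = nz - k + 1 + 2 * pad;
  if (ox < 1 || oy < 1 || oz < 1) stop("convolution output size would be non-positive");
  NumericVector y((R_xlen_t)ox * oy * oz * Cout);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  const R_xlen_t xplane = (R_xlen_t)nx * ny * nz;
  const R_xlen_t yplane = (R_xlen_t)ox * oy * oz;
  for (int co = 0; co < Cout; ++co) {
    double* yc = yp + yplane * co;
    for (R_xlen_t i = 0; i < yplane; ++i) yc[i] = bp[co];
  }
  for (int iz = 0; iz < oz; ++iz)
    for (int kz = 0; kz < k; ++kz) {
      const int z = iz + kz - pad;
      if (z < 0 || z >= nz) continue;
      for (int iy = 0; iy < oy; ++iy)
        for (int ky = 0; ky < k; ++ky) {
          const int yyi = iy + ky - pad;
          if (yyi < 0 || yyi >= ny) continue;
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xrow = xp + xplane * ci + (R_xlen_t)nx * (yyi + (R_xlen_t)ny * z);
            for (int kx = 0; kx < k; ++kx) {
              const int lo = std::max(0, pad - kx);
              const int hi = std::min(ox - 1, nx - 1 - kx + pad);
              if (lo > hi) continue;
              const double* xs = xrow + kx - pad;
              const R_xlen_t wbase = (R_xlen_t)Cout * (ci + (R_xlen_t)Cin * (kx + k * (ky + k * kz)));
              for (int co = 0; co < Cout; ++co) {
                const double wv = wp[co + wbase];
                double* yrow = yp + yplane * co + (R_xlen_t)ox * (iy + (R_xlen_t)oy * iz);
                for (int ix = lo; ix <= hi; ++ix) yrow[ix] += wv * xs[ix];
              }
            }
          }
        }
    }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, Cout);
  return y;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], Cin = xd[3];
  const int Cout = wd[0], k = wd[2];
  const int ox = gd[0], oy = gd[1], oz = gd[2];
  NumericVector gxv((R_xlen_t)nx * ny * nz * Cin);
  NumericVector gwv(w.size());
  NumericVector gbv(Cout);
  double* gx = REAL(gxv); double* gw = REAL(gwv); double* gb = REAL(gbv);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gp = REAL(gy);
  const R_xlen_t xplane = (R_xlen_t)nx * ny * nz;
  const R_xlen_t yplane = (R_xlen_t)ox * oy * oz;
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + yplane * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < yplane; ++i) acc += gc[i];
    gb[co] = acc;
  }
  for (int iz = 0; iz < oz; ++iz)
    for (int kz = 0; kz < k; ++kz) {
      const int z = iz + kz - pad;
      if (z < 0 || z >= nz) continue;
      for (int iy = 0; iy < oy; ++iy)
        for (int ky = 0; ky < k; ++ky) {
          const int yyi = iy + ky - pad;
          if (yyi < 0 || yyi >= ny) continue;
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xrow = xp + xplane * ci + (R_xlen_t)nx * (yyi + (R_xlen_t)ny * z);
            double* gxrow = gx + xplane * ci + (R_xlen_t)nx * (yyi + (R_xlen_t)ny * z);
            for (int kx = 0; kx < k; ++kx) {
              const int lo = std::max(0, pad - kx);
              const int hi = std::min(ox - 1, nx - 1 - kx + pad);
              if (lo > hi) continue;
              const int sh = kx - pad;
              const R_xlen_t wbase = (R_xlen_t)Cout * (ci + (R_xlen_t)Cin * (kx + k * (ky + k * kz)));
              for (int co = 0; co < Cout; ++co) {
                const double wv = wp[co + wbase];
                const double* grow = gp + yplane * co + (R_xlen_t)ox * (iy + (R_xlen_t)oy * iz);
                double* gxs = gxrow + sh;
                const double* xs = xrow + sh;
                double dot = 0.0;
                for (int ix = lo; ix <= hi; ++ix) {
                  gxs[ix] += wv * grow[ix];
                  dot += grow[ix] * xs[ix];
                }
                gw[co + wbase] += dot;
              }
            }
          }
        }
    }
  gxv.attr("dim") = xd;
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gbv);
}

// Max pooling by factor f; spatial sizes must be divisible by f.
// x: (nx,ny,nz,C) -> y: (nx/f, ny/f, nz/f, C) plus argmax linear indices.
// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], C = xd[3];
  const int ox = nx / f, oy = ny / f, oz = nz / f;
  NumericVector y((R_xlen_t)ox * oy * oz * C);
  IntegerVector idx(y.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  for (int c = 0; c < C; ++c)
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix) {
          double best = -INFINITY; R_xlen_t bo = 0;
          for (int dz = 0; dz < f; ++dz)
            for (int dy = 0; dy < f; ++dy)
              for (int dx = 0; dx < f; ++dx) {
                const R_xlen_t o = (f * ix + dx) +
                  (R_xlen_t)nx * ((f * iy + dy) + (R_xlen_t)ny * (f * iz + dz)) +
                  (R_xlen_t)nx * ny * nz * c;
                if (xp[o] > best) { best = xp[o]; bo = o; }
              }
          const R_xlen_t oo = ix + (R_xlen_t)ox * (iy + (R_xlen_t)oy * iz) +
            (R_xlen_t)ox * oy * oz * c;
          yp[oo] = best; ip[oo] = (int)bo;
        }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double* g = REAL(gx);
  const double* gp = REAL(gy);
  const int* ip = INTEGER(idx);
  for (R_xlen_t i = 0; i < gy.size(); ++i) g[ip[i]] += gp[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Transposed convolution, kernel f, stride f (learned upsampling).
// x: (nx,ny,nz,Cin); w: (Cout,Cin,f,f,f); out (f*nx, f*ny, f*nz, Cout).
// [[Rcpp::export(name = ".upconv_fw")]]
NumericVector upconv_fw(NumericVector x, NumericVector w, NumericVector b, int f) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], Cin = xd[3];
  const int Cout = wd[0];
  const int ox = f * nx, oy = f * ny, oz = f * nz;
  NumericVector y((R_xlen_t)ox * oy * oz * Cout);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  const R_xlen_t xplane = (R_xlen_t)nx * ny * nz;
  const R_xlen_t yplane = (R_xlen_t)ox * oy * oz;
  for (int co = 0; co < Cout; ++co) {
    double* yc = yp + yplane * co;
    for (R_xlen_t i = 0; i < yplane; ++i) yc[i] = bp[co];
  }
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dz = 0; dz < f; ++dz)
        for (int dy = 0; dy < f; ++dy)
          for (int dx = 0; dx < f; ++dx) {
            const double wv = wp[co + (R_xlen_t)Cout * (ci +
              (R_xlen_t)Cin * (dx + f * (dy + f * dz)))];
            for (int iz = 0; iz < nz; ++iz)
              for (int iy = 0; iy < ny; ++iy) {
                const double* xrow = xp + xplane * ci +
                  (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                double* yrow = yp + yplane * co + (R_xlen_t)(f * iz + dz) * ox * oy +
                  (R_xlen_t)(f * iy + dy) * ox + dx;
                for (int ix = 0; ix < nx; ++ix) yrow[f * ix] += wv * xrow[ix];
              }
          }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, Cout);
  return y;
}

// [[Rcpp::export(name = ".upconv_bw")]]
List upconv_bw(NumericVector x, NumericVector w, NumericVector gy, int f) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], Cin = xd[3];
  const int Cout = wd[0];
  const int ox = f * nx, oy = f * ny, oz = f * nz;
  NumericVector gxv(x.size());
  NumericVector gwv(w.size());
  NumericVector gbv(Cout);
  double* gx = REAL(gxv); double* gw = REAL(gwv); double* gb = REAL(gbv);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gp = REAL(gy);
  const R_xlen_t xplane = (R_xlen_t)nx * ny * nz;
  const R_xlen_t yplane = (R_xlen_t)ox * oy * oz;
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + yplane * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < yplane; ++i) acc += gc[i];
    gb[co] = acc;
  }
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dz = 0; dz < f; ++dz)
        for (int dy = 0; dy < f; ++dy)
          for (int dx = 0; dx < f; ++dx) {
            const R_xlen_t wi = co + (R_xlen_t)Cout * (ci +
              (R_xlen_t)Cin * (dx + f * (dy + f * dz)));
            const double wv = wp[wi];
            double wacc = 0.0;
            for (int iz = 0; iz < nz; ++iz)
              for (int iy = 0; iy < ny; ++iy) {
                const double* xrow = xp + xplane * ci +
                  (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                double* gxrow = gx + xplane * ci +
                  (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
                const double* grow = gp + yplane * co + (R_xlen_t)(f * iz + dz) * ox * oy +
                  (R_xlen_t)(f * iy + dy) * ox + dx;
                for (int ix = 0; ix < nx; ++ix) {
                  const double g = grow[f * ix];
                  gxrow[ix] += wv * g;
                  wacc += g * xrow[ix];
                }
              }
            gw[wi] += wacc;
          }
  gxv.attr("dim") = xd;
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gbv);
}

// Affine resampling of a plain 3D volume. M is 3x4 (row-major given as a
// 12-vector) mapping output voxel indices (0-based) to input voxel indices.
// [[Rcpp::export(name = ".affine_resample")]]
NumericVector affine_resample(NumericVector vol, NumericVector M,
                              bool nearest, double fill) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* v = REAL(vol);
  double* o = REAL(out);
  const double* m = REAL(M);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double sx = m[0] * x + m[1] * y + m[2] * z + m[3];
        const double sy = m[4] * x + m[5] * y + m[6] * z + m[7];
        const double sz = m[8] * x + m[9] * y + m[10] * z + m[11];
        const R_xlen_t oo = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (nearest) {
          const int ix = (int)std::lround(sx), iy = (int)std::lround(sy), iz = (int)std::lround(sz);
          o[oo] = (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
                    ? fill : v[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
          if (x0 < -1 || x0 >= nx || y0 < -1 || y0 >= ny || z0 < -1 || z0 >= nz) { o[oo] = fill; continue; }
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                const int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
                const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                const double val = (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
                                     ? fill : v[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
                acc += wgt * val;
              }
          o[oo] = acc;
        }
      }
  out.attr("dim") = d;
  return out;
}

static const int D6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

// Connected-component labelling, connectivity 6 or 26. Returns integer array
// of labels (0 = background), labelled in scan order (deterministic).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  const int* m = INTEGER(mask);
  int* L = INTEGER(lab);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || L[s]) continue;
    ++next;
    L[s] = next;
    stack.clear(); stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      if (connectivity == 6) {
        for (int k = 0; k < 6; ++k) {
          const int xx = x + D6[k][0], yy = y + D6[k][1], zz = z + D6[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          const R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (m[q] && !L[q]) { L[q] = next; stack.push_back(q); }
        }
      } else {
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
              const R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
              if (m[q] && !L[q]) { L[q] = next; stack.push_back(q); }
            }
      }
    }
  }
  lab.attr("dim") = d;
  return lab;
}

// One iteration of binary dilation/erosion with the 6- or 26-neighbourhood,
// repeated `iters` times.
// [[Rcpp::export(name = ".binary_morph")]]
IntegerVector binary_morph(IntegerVector mask, int iters, bool dilate, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> cur(INTEGER(mask), INTEGER(mask) + n), nxt(n);
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t o = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          bool hit = false;
          if (connectivity == 6) {
            for (int k = 0; k < 6 && !hit; ++k) {
              const int xx = x + D6[k][0], yy = y + D6[k][1], zz = z + D6[k][2];
              const bool in = xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz;
              const int v = in ? cur[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] : 0;
              if (dilate ? (v != 0) : (v == 0)) hit = true;
            }
          } else {
            for (int dz = -1; dz <= 1 && !hit; ++dz)
              for (int dy = -1; dy <= 1 && !hit; ++dy)
                for (int dx = -1; dx <= 1 && !hit; ++dx) {
                  if (!dx && !dy && !dz) continue;
                  const int xx = x + dx, yy = y + dy, zz = z + dz;
                  const bool in = xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz;
                  const int v = in ? cur[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] : 0;
                  if (dilate ? (v != 0) : (v == 0)) hit = true;
                }
          }
          nxt[o] = dilate ? (cur[o] || hit) : (cur[o] && !hit);
        }
    cur.swap(nxt);
  }
  IntegerVector out(n);
  std::copy(cur.begin(), cur.end(), INTEGER(out));
  out.attr("dim") = d;
  return out;
}

// Intensity-window region growing from a seed voxel (linear 0-based index).
// [[Rcpp::export(name = ".region_grow")]]
IntegerVector region_grow(NumericVector img, int seed, double lo, double hi,
                          int connectivity, double max_frac) {
  IntegerVector d = img.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t maxvox = (R_xlen_t)(max_frac * n);
  IntegerVector out(n);
  int* M = INTEGER(out);
  const double* v = REAL(img);
  out.attr("dim") = d;
  if (seed < 0 || seed >= n || v[seed] < lo || v[seed] > hi) return out;
  std::vector<R_xlen_t> stack;
  stack.push_back(seed);
  M[seed] = 1;
  R_xlen_t count = 1;
  while (!stack.empty() && count <= maxvox) {
    const R_xlen_t cur = stack.back(); stack.pop_back();
    const int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          const R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          if (!M[q] && v[q] >= lo && v[q] <= hi) {
            M[q] = 1; ++count; stack.push_back(q);
          }
        }
  }
  return out;
}

// ---- 3D skeletonization by topology-preserving border peeling -------------

// Simple-point test for (26,6) connectivity: the foreground of the 26-
// neighbourhood must form exactly one 26-connected component, and the
// background restricted to the 18-neighbourhood exactly one 6-connected
// component containing a face neighbour of the centre.
static bool is_simple(const int* m, int x, int y, int z, int nx, int ny, int nz) {
  int fg[27], bg[27];
  int idx = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++idx) {
        const int xx = x + dx, yy = y + dy, zz = z + dz;
        const bool in = xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz;
        const int v = in ? m[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] : 0;
        fg[idx] = v; bg[idx] = !v;
      }
  fg[13] = 0; // exclude centre
  // count 26-components of fg over the 26-neighbourhood
  int seen[27] = {0};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !fg[i] || seen[i]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int st[27], sp = 0;
    st[sp++] = i; seen[i] = 1;
    while (sp) {
      const int cur = st[--sp];
      const int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !fg[j] || seen[j]) continue;
        const int jx = j % 3, jy = (j / 3) % 3, jz = j / 9;
        if (std::abs(jx - cx) <= 1 && std::abs(jy - cy) <= 1 && std::abs(jz - cz) <= 1) {
          seen[j] = 1; st[sp++] = j;
        }
      }
    }
  }
  if (ncomp != 1) return false;
  // 6-components of bg on the 18-neighbourhood, counting only those that
  // contain a face neighbour of the centre.
  int seenb[27] = {0};
  int nbg = 0;
  static const int face[6] = {4, 10, 12, 14, 16, 22}; // 6-neighbours of centre
  for (int fi = 0; fi < 6; ++fi) {
    const int i = face[fi];
    if (!bg[i] || seenb[i]) continue;
    ++nbg;
    if (nbg > 1) return false;
    int st[27], sp = 0;
    st[sp++] = i; seenb[i] = 1;
    while (sp) {
      const int cur = st[--sp];
      const int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || !bg[j] || seenb[j]) continue;
        const int jx = j % 3, jy = (j / 3) % 3, jz = j / 9;
        const int dd = std::abs(jx - cx) + std::abs(jy - cy) + std::abs(jz - cz);
        const int manh = std::abs(jx - 1) + std::abs(jy - 1) + std::abs(jz - 1);
        if (dd == 1 && manh <= 2) { seenb[j] = 1; st[sp++] = j; } // stay in N18
      }
    }
  }
  return nbg == 1;
}

static int count_fg_neighbours(const int* m, int x, int y, int z, int nx, int ny, int nz) {
  int cnt = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        const int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        cnt += m[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] != 0;
      }
  return cnt;
}

// Medial-axis thinning: directional sub-iterations peel simple, non-endpoint
// border voxels until stable. Produces a 26-connected unit-width skeleton.
// [[Rcpp::export(name = ".skeletonize3d")]]
IntegerVector skeletonize3d(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out = clone(mask);
  int* m = INTEGER(out);
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const R_xlen_t o = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            if (!m[o]) continue;
            const int xx = x + D6[dir][0], yy = y + D6[dir][1], zz = z + D6[dir][2];
            const bool in = xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz;
            const int v = in ? m[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] : 0;
            // border voxel in this direction, not a curve endpoint at the
            // start of the sub-iteration (endpoint status is frozen here, as
            // in Lee-style thinning, so transient endpoints created during
            // the pass do not seed spurious side branches)
            if (!v && count_fg_neighbours(m, x, y, z, nx, ny, nz) > 1)
              cand.push_back(o);
          }
      for (R_xlen_t i = 0; i < (R_xlen_t)cand.size(); ++i) {
        const R_xlen_t o = cand[i];
        if (!m[o]) continue;
        const int x = o % nx, y = (o / nx) % ny, z = o / ((R_xlen_t)nx * ny);
        if (is_simple(m, x, y, z, nx, ny, nz)) { m[o] = 0; changed = true; }
      }
    }
  }
  out.attr("dim") = d;
  return out;
}

// Rasterize capsules (segments with spherical caps): voxel centres within
// radius r_i of segment i become foreground.
// [[Rcpp::export(name = ".rasterize_capsules")]]
IntegerVector rasterize_capsules(NumericMatrix starts, NumericMatrix ends,
                                 NumericVector radii, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  int* M = INTEGER(out);
  for (int s = 0; s < starts.nrow(); ++s) {
    const double ax = starts(s, 0), ay = starts(s, 1), az = starts(s, 2);
    const double bx = ends(s, 0), by = ends(s, 1), bz = ends(s, 2);
    const double r = radii[s], r2 = r * r;
    const double vx = bx - ax, vy = by - ay, vz = bz - az;
    const double vv = vx * vx + vy * vy + vz * vz;
    const int x0 = std::max(0, (int)std::floor(std::min(ax, bx) - r - 1));
    const int x1 = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + r + 1));
    const int y0 = std::max(0, (int)std::floor(std::min(ay, by) - r - 1));
    const int y1 = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + r + 1));
    const int z0 = std::max(0, (int)std::floor(std::min(az, bz) - r - 1));
    const int z1 = std::min(nz - 1, (int)std::ceil(std::max(az, bz) + r + 1));
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          const double px = x - ax, py = y - ay, pz = z - az;
          double t = vv > 0 ? (px * vx + py * vy + pz * vz) / vv : 0.0;
          t = std::min(1.0, std::max(0.0, t));
          const double dx = px - t * vx, dy = py - t * vy, dz = pz - t * vz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            M[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = 1;
        }
  }
  out.attr("dim") = dims;
  return out;
}
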