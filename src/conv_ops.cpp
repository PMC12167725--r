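// Dense 3D network primitives for the U-Net segmenter.
//
// Layout convention (R column-major): activation arrays have dim
// (nx, ny, nz, C) so the voxel index runs fastest and each channel is a
// contiguous block.  Convolutions are 3x3x3 same-padding, realised as
// im2col (kept as N voxels x 27*cin so every hot loop is contiguous)
// followed by one BLAS gemm in single precision.  The forward pass can
// hand its im2col matrix back as an external pointer so the backward pass
// reuses it for the weight gradient; the input gradient is computed as a
// forward convolution with channel-transposed, spatially flipped kernels,
// which avoids any scatter (col2im) step entirely.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// cols(v, r): voxel v, kernel tap r = ci*27 + (dx+1) + 3(dy+1) + 9(dz+1)
static arma::fmat im2col3(const double* p, int nx, int ny, int nz, int cin) {
  const std::size_t N = (std::size_t)nx * ny * nz;
  arma::fmat cols(N, 27 * cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    const double* pc = p + (std::size_t)N * ci;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int r = ci * 27 + (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          float* col = cols.colptr(r);
          for (int k = 0; k < nz; ++k) {
            int kk = k + dz;
            if (kk < 0 || kk >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              int jj = j + dy;
              if (jj < 0 || jj >= ny) continue;
              const double* src = pc + (std::size_t)nx * (jj + (std::size_t)ny * kk) + dx;
              float* dst = col + (std::size_t)nx * (j + (std::size_t)ny * k);
              int i0 = std::max(0, -dx), i1 = std::min(nx, nx - dx);
              for (int i = i0; i < i1; ++i) dst[i] = (float)src[i];
            }
          }
        }
  }
  return cols;
}

// R weight matrix (cout x 27cin) -> fmat (27cin x cout)
static arma::fmat weights_t(const NumericMatrix& W) {
  int cout = W.nrow(), kc = W.ncol();
  arma::fmat Wt(kc, cout);
  for (int j = 0; j < kc; ++j)
    for (int i = 0; i < cout; ++i) Wt(j, i) = (float)W(i, j);
  return Wt;
}

// [[Rcpp::export(name = ".conv3_fwd")]]
List conv3_fwd(NumericVector x, IntegerVector dims,
               NumericMatrix W, NumericVector b, bool want_cache) {
  int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const std::size_t N = (std::size_t)nx * ny * nz;
  int cout = W.nrow();
  arma::fmat* cols = new arma::fmat(im2col3(x.begin(), nx, ny, nz, cin));
  arma::fmat Y = (*cols) * weights_t(W);         // N x cout
  NumericVector out(N * cout);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  for (int co = 0; co < cout; ++co) {
    double bb = b[co];
    const float* py = Y.colptr(co);
    double* po = out.begin() + N * co;
    for (std::size_t v = 0; v < N; ++v) po[v] = (double)py[v] + bb;
  }
  if (want_cache) {
    XPtr<arma::fmat> ptr(cols, true);
    return List::create(_["y"] = out, _["cols"] = ptr);
  }
  delete cols;
  return List::create(_["y"] = out);
}

// Backward using the cached im2col matrix of the input.
// dx = conv(dy, Wflip) with Wflip[ci, co*27 + (26 - t)] = W[co, ci*27 + t];
// same-padding zero boundaries make this identity exact.
// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(SEXP cols_ptr, IntegerVector dims,
               NumericMatrix W, NumericVector dy) {
  int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const std::size_t N = (std::size_t)nx * ny * nz;
  int cout = W.nrow();
  XPtr<arma::fmat> cols(cols_ptr);

  arma::fmat DY(N, cout);
  NumericVector dbr(cout);
  for (int co = 0; co < cout; ++co) {
    const double* pd = dy.begin() + N * co;
    float* pc = DY.colptr(co);
    double s = 0;
    for (std::size_t v = 0; v < N; ++v) { pc[v] = (float)pd[v]; s += pd[v]; }
    dbr[co] = s;
  }
  arma::fmat dWt = cols->t() * DY;               // 27cin x cout
  NumericMatrix dWr(cout, 27 * cin);
  for (int j = 0; j < 27 * cin; ++j)
    for (int i = 0; i < cout; ++i) dWr(i, j) = dWt(j, i);

  // input gradient as a forward conv with flipped transposed kernels
  arma::fmat Wflip(27 * cout, cin);
  for (int ci = 0; ci < cin; ++ci)
    for (int co = 0; co < cout; ++co)
      for (int t = 0; t < 27; ++t)
        Wflip(co * 27 + (26 - t), ci) = (float)W(co, ci * 27 + t);
  arma::fmat gcols = im2col3(dy.begin(), nx, ny, nz, cout);
  arma::fmat dX = gcols * Wflip;                 // N x cin
  NumericVector dx_out(N * cin);
  dx_out.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  for (int ci = 0; ci < cin; ++ci) {
    const float* src = dX.colptr(ci);
    double* pc = dx_out.begin() + N * ci;
    for (std::size_t v = 0; v < N; ++v) pc[v] = (double)src[v];
  }
  return List::create(_["dx"] = dx_out, _["dW"] = dWr, _["db"] = dbr);
}

// Fused instance normalization + leaky rectifier.
// Per channel (over the spatial voxels of this one sample):
//   zhat = (y - mean) / sqrt(var + eps)
//   o = gamma * zhat + beta;  out = o > 0 ? o : slope * o
// The small negative-side slope keeps every unit trainable: with a hard
// rectifier a short schedule can silence whole feature maps over entire
// structures, which freezes any information they carried.
// [[Rcpp::export(name = ".in_relu_fwd")]]
List in_relu_fwd(NumericVector y, IntegerVector dims,
                 NumericVector gamma, NumericVector beta, double eps,
                 double slope) {
  int C = dims[3];
  const std::size_t N = (std::size_t)dims[0] * dims[1] * dims[2];
  NumericVector out(N * C);
  out.attr("dim") = dims;
  NumericVector mu(C), inv_sd(C);
  for (int c = 0; c < C; ++c) {
    const double* p = y.begin() + N * c;
    double s = 0, s2 = 0;
    for (std::size_t v = 0; v < N; ++v) { s += p[v]; s2 += p[v] * p[v]; }
    double m = s / N;
    double var = s2 / N - m * m;
    if (var < 0) var = 0;
    double isd = 1.0 / std::sqrt(var + eps);
    mu[c] = m; inv_sd[c] = isd;
    double g = gamma[c], b = beta[c];
    double* q = out.begin() + N * c;
    for (std::size_t v = 0; v < N; ++v) {
      double o = g * ((p[v] - m) * isd) + b;
      q[v] = o > 0 ? o : slope * o;
    }
  }
  return List::create(_["out"] = out, _["mu"] = mu, _["inv_sd"] = inv_sd);
}

// Backward of the fused block: recomputes zhat and the ReLU mask from the
// cached pre-norm activations and the saved channel statistics.
// [[Rcpp::export(name = ".in_relu_bwd")]]
List in_relu_bwd(NumericVector y, IntegerVector dims, NumericVector dy,
                 NumericVector gamma, NumericVector beta,
                 NumericVector mu, NumericVector inv_sd, double slope) {
  int C = dims[3];
  const std::size_t N = (std::size_t)dims[0] * dims[1] * dims[2];
  NumericVector dx(N * C);
  dx.attr("dim") = dims;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* p = y.begin() + N * c;
    const double* pd = dy.begin() + N * c;
    double g = gamma[c], b = beta[c], m = mu[c], isd = inv_sd[c];
    double s_dym = 0, s_dymz = 0;
    for (std::size_t v = 0; v < N; ++v) {
      double z = (p[v] - m) * isd;
      double o = g * z + b;
      double w = (o > 0) ? pd[v] : slope * pd[v];
      s_dym += w; s_dymz += w * z;
    }
    dgamma[c] = s_dymz;
    dbeta[c] = s_dym;
    double m1 = g * s_dym / N, m2 = g * s_dymz / N;
    double* q = dx.begin() + N * c;
    for (std::size_t v = 0; v < N; ++v) {
      double z = (p[v] - m) * isd;
      double o = g * z + b;
      double dz = (o > 0) ? g * pd[v] : slope * g * pd[v];
      q[v] = isd * (dz - m1 - z * m2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x2x2 max pooling, stride 2, with argmax indices for the backward scatter.
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], c = dims[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool requires even spatial dims");
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  std::size_t Nout = (std::size_t)mx * my * mz * c;
  NumericVector y(Nout);
  y.attr("dim") = IntegerVector::create(mx, my, mz, c);
  IntegerVector arg(Nout);
  const double* p = x.begin();
  std::size_t o = 0;
  for (int ch = 0; ch < c; ++ch) {
    std::size_t base = (std::size_t)nx * ny * nz * ch;
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double best = -1e300; std::size_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                std::size_t idx = base + (std::size_t)(2 * i + dx) +
                  (std::size_t)nx * ((2 * j + dy) + (std::size_t)ny * (2 * k + dz));
                if (p[idx] > best) { best = p[idx]; bi = idx; }
              }
          y[o] = best; arg[o] = (int)bi; ++o;
        }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(IntegerVector argmax, NumericVector dy, IntegerVector in_dims) {
  std::size_t Nin = (std::size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx(Nin);
  dx.attr("dim") = in_dims;
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[argmax[o]] += dy[o];
  return dx;
}

// Transposed convolution 2x2x2, stride 2 (the U-Net up-convolution).
// W has shape (8*cout x cin); offset o = dx + 2*dy + 4*dz selects which of
// the 8 output voxels fed by each input voxel a row block maps to.
// [[Rcpp::export(name = ".upconv_fwd")]]
NumericVector upconv_fwd(NumericVector x, IntegerVector dims,
                         NumericMatrix W, NumericVector b) {
  int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const std::size_t Nin = (std::size_t)nx * ny * nz;
  int cout = W.nrow() / 8;
  arma::fmat X(Nin, cin);
  for (int ci = 0; ci < cin; ++ci) {
    const double* pc = x.begin() + Nin * ci;
    float* dst = X.colptr(ci);
    for (std::size_t v = 0; v < Nin; ++v) dst[v] = (float)pc[v];
  }
  arma::fmat Y = X * weights_t(W);               // Nin x 8cout
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const std::size_t Nout = (std::size_t)ox * oy * oz;
  NumericVector out(Nout * cout);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  double* po = out.begin();
  for (int co = 0; co < cout; ++co) {
    double bb = b[co];
    double* pc = po + Nout * co;
    for (std::size_t v = 0; v < Nout; ++v) pc[v] = bb;
    for (int o = 0; o < 8; ++o) {
      int dx = o & 1, dy = (o >> 1) & 1, dz = (o >> 2) & 1;
      const float* py = Y.colptr(o * cout + co);
      std::size_t v = 0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          double* dst = pc + (std::size_t)dx +
            (std::size_t)ox * ((2 * j + dy) + (std::size_t)oy * (2 * k + dz));
          for (int i = 0; i < nx; ++i, ++v) dst[2 * i] += (double)py[v];
        }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".upconv_bwd")]]
List upconv_bwd(NumericVector x, IntegerVector dims,
                NumericMatrix W, NumericVector dy) {
  int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const std::size_t Nin = (std::size_t)nx * ny * nz;
  int cout = W.nrow() / 8;
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const std::size_t Nout = (std::size_t)ox * oy * oz;
  arma::fmat DY(Nin, 8 * cout);
  NumericVector dbr(cout);
  const double* pdy = dy.begin();
  for (int co = 0; co < cout; ++co) {
    const double* pc = pdy + Nout * co;
    double s = 0;
    for (std::size_t v = 0; v < Nout; ++v) s += pc[v];
    dbr[co] = s;
    for (int o = 0; o < 8; ++o) {
      int dx = o & 1, dyo = (o >> 1) & 1, dz = (o >> 2) & 1;
      float* dst = DY.colptr(o * cout + co);
      std::size_t v = 0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          const double* src = pc + (std::size_t)dx +
            (std::size_t)ox * ((2 * j + dyo) + (std::size_t)oy * (2 * k + dz));
          for (int i = 0; i < nx; ++i, ++v) dst[v] = (float)src[2 * i];
        }
    }
  }
  arma::fmat X(Nin, cin);
  for (int ci = 0; ci < cin; ++ci) {
    const double* pc = x.begin() + Nin * ci;
    float* dst = X.colptr(ci);
    for (std::size_t v = 0; v < Nin; ++v) dst[v] = (float)pc[v];
  }
  arma::fmat dWt = X.t() * DY;                   // cin x 8cout
  arma::fmat dX = DY * weights_t(W).t();         // Nin x cin
  NumericMatrix dWr(W.nrow(), cin);
  for (int j = 0; j < cin; ++j)
    for (int i = 0; i < W.nrow(); ++i) dWr(i, j) = dWt(j, i);
  NumericVector dx_out(Nin * cin);
  dx_out.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  for (int ci = 0; ci < cin; ++ci) {
    double* pc = dx_out.begin() + Nin * ci;
    const float* src = dX.colptr(ci);
    for (std::size_t v = 0; v < Nin; ++v) pc[v] = (double)src[v];
  }
  return List::create(_["dx"] = dx_out, _["dW"] = dWr, _["db"] = dbr);
}
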