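// Geometric and morphological primitives for 3D volumes.
// All index arithmetic is 0-based continuous voxel coordinates; the R side
// owns the world/voxel conventions.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Sample `x` on an affine output grid: for output voxel (i,j,k) the input
// coordinate is A %*% c(i,j,k) + b (0-based, voxel units).
// method: 0 = trilinear, 1 = nearest.  If clamp, out-of-range coordinates
// are clamped to the edge (constant extension); otherwise `fill` is used.
// [[Rcpp::export(name = ".affine_sample")]]
NumericVector affine_sample(NumericVector x, IntegerVector in_dim,
                            IntegerVector out_dim, NumericMatrix A,
                            NumericVector b, int method, bool clamp,
                            double fill) {
  int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((std::size_t)ox * oy * oz);
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  const double* p = x.begin();
  double* q = out.begin();
  std::size_t v = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++v) {
        double xi = A(0,0)*i + A(0,1)*j + A(0,2)*k + b[0];
        double yj = A(1,0)*i + A(1,1)*j + A(1,2)*k + b[1];
        double zk = A(2,0)*i + A(2,1)*j + A(2,2)*k + b[2];
        if (method == 1) {
          int ii = (int)std::floor(xi + 0.5), jj = (int)std::floor(yj + 0.5),
              kk = (int)std::floor(zk + 0.5);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) {
            if (clamp) {
              ii = std::min(std::max(ii, 0), nx - 1);
              jj = std::min(std::max(jj, 0), ny - 1);
              kk = std::min(std::max(kk, 0), nz - 1);
            } else { q[v] = fill; continue; }
          }
          q[v] = p[(std::size_t)ii + (std::size_t)nx * (jj + (std::size_t)ny * kk)];
        } else {
          if (!clamp && (xi < -0.5 || xi > nx - 0.5 || yj < -0.5 || yj > ny - 0.5 ||
                         zk < -0.5 || zk > nz - 0.5)) { q[v] = fill; continue; }
          if (clamp) {
            xi = std::min(std::max(xi, 0.0), (double)(nx - 1));
            yj = std::min(std::max(yj, 0.0), (double)(ny - 1));
            zk = std::min(std::max(zk, 0.0), (double)(nz - 1));
          }
          int i0 = (int)std::floor(xi), j0 = (int)std::floor(yj), k0 = (int)std::floor(zk);
          double fx = xi - i0, fy = yj - j0, fz = zk - k0;
          double acc = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                if (w == 0) continue;
                int ii = i0 + dx, jj = j0 + dy, kk = k0 + dz;
                double val;
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) {
                  if (clamp) {
                    ii = std::min(std::max(ii, 0), nx - 1);
                    jj = std::min(std::max(jj, 0), ny - 1);
                    kk = std::min(std::max(kk, 0), nz - 1);
                    val = p[(std::size_t)ii + (std::size_t)nx * (jj + (std::size_t)ny * kk)];
                  } else val = fill;
                } else {
                  val = p[(std::size_t)ii + (std::size_t)nx * (jj + (std::size_t)ny * kk)];
                }
                acc += w * val;
              }
          q[v] = acc;
        }
      }
  return out;
}

// Separable Gaussian blur, mirror boundary, kernel truncated at 3 sigma.
// sigma is given per axis in voxel units; an axis with sigma <= 0 is skipped.
// [[Rcpp::export(name = ".gaussian_blur3")]]
NumericVector gaussian_blur3(NumericVector x, IntegerVector dim, NumericVector sigma) {
  int n[3] = { dim[0], dim[1], dim[2] };
  std::size_t N = (std::size_t)n[0] * n[1] * n[2];
  std::vector<double> cur(x.begin(), x.end()), nxt(N);
  std::size_t stride[3] = { 1, (std::size_t)n[0], (std::size_t)n[0] * n[1] };
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += ker[t + r]; }
    for (double& w : ker) w /= tot;
    int len = n[ax];
    std::size_t st = stride[ax];
    // iterate over all lines along axis ax
    int na = n[(ax + 1) % 3], nb = n[(ax + 2) % 3];
    std::size_t sa = stride[(ax + 1) % 3], sb = stride[(ax + 2) % 3];
    for (int bidx = 0; bidx < nb; ++bidx)
      for (int aidx = 0; aidx < na; ++aidx) {
        std::size_t base = sa * aidx + sb * bidx;
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0) ii = -ii - 1;          // mirror
            if (ii >= len) ii = 2 * len - ii - 1;
            if (ii < 0) ii = 0; else if (ii >= len) ii = len - 1; // tiny axes
            acc += ker[t + r] * cur[base + st * ii];
          }
          nxt[base + st * i] = acc;
        }
      }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling of voxels equal to `target`.
// Components are numbered 1..K in order of their first (smallest) linear
// index; returns the component map plus component sizes.
// [[Rcpp::export(name = ".label_components26")]]
List label_components26(IntegerVector lab, IntegerVector dim, int target) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::size_t N = (std::size_t)nx * ny * nz;
  IntegerVector comp(N);
  comp.attr("dim") = dim;
  std::vector<int> sizes;
  int next_id = 0;
  std::vector<std::size_t> stack;
  for (std::size_t s = 0; s < N; ++s) {
    if (lab[s] != target || comp[s] != 0) continue;
    ++next_id;
    int sz = 0;
    stack.push_back(s);
    comp[s] = next_id;
    while (!stack.empty()) {
      std::size_t v = stack.back(); stack.pop_back();
      ++sz;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((std::size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int ii = i + dx, jj = j + dy, kk = k + dz;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            std::size_t w = (std::size_t)ii + (std::size_t)nx * (jj + (std::size_t)ny * kk);
            if (lab[w] == target && comp[w] == 0) { comp[w] = next_id; stack.push_back(w); }
          }
    }
    sizes.push_back(sz);
  }
  return List::create(_["comp"] = comp, _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// One binary dilation (op = 1) or erosion (op = 0) with the full 3x3x3
// (26-connected) structuring element; outside the volume counts as 0.
// [[Rcpp::export(name = ".morph26")]]
IntegerVector morph26(IntegerVector mask, IntegerVector dim, int op) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::size_t N = (std::size_t)nx * ny * nz;
  IntegerVector out(N);
  out.attr("dim") = dim;
  std::size_t v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        bool hit = (op == 1) ? false : true;
        for (int dz = -1; dz <= 1 && (op == 1 ? !hit : hit); ++dz)
          for (int dy = -1; dy <= 1 && (op == 1 ? !hit : hit); ++dy)
            for (int dx = -1; dx <= 1 && (op == 1 ? !hit : hit); ++dx) {
              int ii = i + dx, jj = j + dy, kk = k + dz;
              int val = 0;
              if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
                val = mask[(std::size_t)ii + (std::size_t)nx * (jj + (std::size_t)ny * kk)];
              if (op == 1) { if (val) hit = true; }
              else         { if (!val) hit = false; }
            }
        out[v] = hit ? 1 : 0;
      }
  return out;
}
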