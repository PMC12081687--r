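#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher separable
// parabola algorithm) with nearest-feature tracking, on an anisotropic grid.
// Distances are computed between voxel centers in physical units.

static const double INF = 1e30;

// One 1-D pass along a line of length n with stride `stride` starting at
// `base`. f holds current squared distances, feat the nearest feature's
// linear index (-1 if none reachable yet). w is the physical step.
static void edt_line(std::vector<double>& f, std::vector<int>& feat,
                     double* D, int* F, R_xlen_t base, int n, R_xlen_t stride,
                     double w) {
  // gather
  for (int i = 0; i < n; ++i) {
    f[i] = D[base + stride * i];
    feat[i] = F[base + stride * i];
  }
  std::vector<int> v(n);      // parabola sites
  std::vector<double> z(n + 1); // envelope boundaries
  int k = -1;
  double w2 = w * w;
  for (int q = 0; q < n; ++q) {
    if (f[q] >= INF) continue; // no finite parabola at q
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) return; // whole line infinite
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double d = w2 * (q - v[j]) * (q - v[j]) + f[v[j]];
    D[base + stride * q] = d;
    F[base + stride * q] = feat[v[j]];
  }
}

// [[Rcpp::export]]
List edt_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  IntegerVector F(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) { D[i] = 0.0; F[i] = (int)i; }
    else { D[i] = INF; F[i] = -1; }
  }
  double* Dp = REAL(D);
  int* Fp = INTEGER(F);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax);
  std::vector<int> feat(nmax);
  // axis x
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      edt_line(f, feat, Dp, Fp, (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0), nx, 1,
               spacing[0]);
  // axis y
  for (int z0 = 0; z0 < nz; ++z0)
    for (int x0 = 0; x0 < nx; ++x0)
      edt_line(f, feat, Dp, Fp, x0 + (R_xlen_t)nx * ny * z0, ny, nx,
               spacing[1]);
  // axis z
  for (int y0 = 0; y0 < ny; ++y0)
    for (int x0 = 0; x0 < nx; ++x0)
      edt_line(f, feat, Dp, Fp, x0 + (R_xlen_t)nx * y0, nz, (R_xlen_t)nx * ny,
               spacing[2]);
  for (R_xlen_t i = 0; i < n; ++i)
    Dp[i] = (Dp[i] >= INF) ? R_PosInf : std::sqrt(Dp[i]);
  // 1-based feature indices for R
  for (R_xlen_t i = 0; i < n; ++i)
    if (Fp[i] >= 0) Fp[i] += 1; else Fp[i] = NA_INTEGER;
  return List::create(_["distance"] = D, _["feature"] = F);
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  // 26-connectivity flood fill
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int* L = INTEGER(lab);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || L[s]) continue;
    ++cur;
    L[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[q] && !L[q]) { L[q] = cur; stack.push_back(q); }
          }
    }
  }
  return lab;
}
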