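#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 3D array helpers: R column-major layout, idx = i + nx*(j + ny*k).

// 1D squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher 2012), with physical sample spacing s.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sden = 2.0 * (xq - xv);
      double sp = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / sden;
      if (sp <= z[k]) { --k; continue; }
      ++k; v[k] = q; z[k] = sp; z[k + 1] = INF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Anisotropic Euclidean distance (physical units) from every voxel to the
// nearest TRUE voxel of `ref`. Voxels of ref itself get 0.
// [[Rcpp::export]]
NumericVector edt3d(LogicalVector ref, IntegerVector dims,
                    NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel: true infinities make the parabola intersection NaN
  const double BIG = 1e30;
  R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = ref[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = out[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j)
        out[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = out[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k)
        out[i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k)] = std::sqrt(d[k]);
    }
  return out;
}

// 6-connected components of a binary mask. Returns integer labels, 0 for
// background; labels assigned in raster order (deterministic).
// [[Rcpp::export]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    stack.clear(); stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = p % nx, j = (p / nx) % ny, k = p / (static_cast<R_xlen_t>(nx) * ny);
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t q = ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

struct WsNode {
  double pri; R_xlen_t ord; R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.pri != b.pri) return a.pri < b.pri;   // max-heap on priority
    return a.ord > b.ord;                       // FIFO tie-break: deterministic
  }
};

// Seeded 3D watershed by priority flooding: voxels are claimed in order of
// decreasing `priority` (here the distance transform), starting from the
// seed voxels, growing 6-connected within `mask`. Ties broken by insertion
// order, so results are fully deterministic.
// [[Rcpp::export]]
IntegerVector watershed3d(NumericVector priority, IntegerVector seeds,
                          LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t ord = 0;
  for (R_xlen_t s = 0; s < n; ++s)
    if (seeds[s] > 0 && mask[s]) {
      lab[s] = seeds[s];
      pq.push({priority[s], ord++, s});
    }
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t p = nd.idx;
    int i = p % nx, j = (p / nx) % ny, k = p / (static_cast<R_xlen_t>(nx) * ny);
    for (int m = 0; m < 6; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t q = ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk);
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[p];
        pq.push({priority[q], ord++, q});
      }
    }
  }
  return lab;
}

// Local maxima of `values` within `mask` under 26-connectivity (plateau
// voxels count as maxima; suppression by distance is done in R).
// [[Rcpp::export]]
LogicalVector local_max3d(NumericVector values, LogicalVector mask,
                          IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  LogicalVector out(n, false);
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    int i = p % nx, j = (p / nx) % ny, k = p / (static_cast<R_xlen_t>(nx) * ny);
    bool ismax = true;
    for (int dk2 = -1; dk2 <= 1 && ismax; ++dk2)
      for (int dj2 = -1; dj2 <= 1 && ismax; ++dj2)
        for (int di2 = -1; di2 <= 1 && ismax; ++di2) {
          if (!di2 && !dj2 && !dk2) continue;
          int ii = i + di2, jj = j + dj2, kk = k + dk2;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          R_xlen_t q = ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk);
          if (values[q] > values[p]) ismax = false;
        }
    out[p] = ismax;
  }
  return out;
}
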