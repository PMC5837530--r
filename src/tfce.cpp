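#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static void neighbour_offsets(int connectivity,
                              std::vector<int> &di, std::vector<int> &dj,
                              std::vector<int> &dk) {
  di.clear(); dj.clear(); dk.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// Connected-component labelling of a logical 3-D mask (6 or 26 connectivity).
// Returns integer labels (0 = outside mask), components numbered from 1.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  const int *m = LOGICAL(mask);
  int *lab = INTEGER(labels);
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, di, dj, dk);
  const int noff = (int)di.size();
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++current;
    lab[s] = current;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int i = (int)(idx % nx);
      int j = (int)((idx / nx) % ny);
      int k = (int)(idx / ((R_xlen_t)nx * ny));
      for (int t = 0; t < noff; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (m[nb] && !lab[nb]) {
          lab[nb] = current;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}

// Threshold-free cluster enhancement of a non-negative statistic map.
// TFCE(p) = sum over heights h = dh, 2dh, ... of e(h,p)^E * h^H * dh,
// where e(h,p) is the voxel count of the suprathreshold component containing p.
// Negative input values are treated as zero (callers sign-split).
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, LogicalVector mask,
                       IntegerVector dim, double E, double H,
                       double dh, int nsteps, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, 0.0);
  const double *s = REAL(stat);
  const int *m = LOGICAL(mask);
  double *o = REAL(out);

  double maxstat = 0.0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (m[i] && s[i] > maxstat) maxstat = s[i];
  if (maxstat <= 0.0) return out;
  if (dh <= 0.0) dh = maxstat / nsteps;

  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, di, dj, dk);
  const int noff = (int)di.size();
  std::vector<int> lab(n);
  std::vector<R_xlen_t> stack;
  std::vector<double> csize;

  for (double h = dh; h <= maxstat + 1e-12; h += dh) {
    std::fill(lab.begin(), lab.end(), 0);
    csize.clear();
    csize.push_back(0.0); // dummy for label 0
    int current = 0;
    for (R_xlen_t start = 0; start < n; ++start) {
      if (!m[start] || s[start] < h || lab[start]) continue;
      ++current;
      csize.push_back(0.0);
      lab[start] = current;
      csize[current] += 1.0;
      stack.clear();
      stack.push_back(start);
      while (!stack.empty()) {
        R_xlen_t idx = stack.back();
        stack.pop_back();
        int i = (int)(idx % nx);
        int j = (int)((idx / nx) % ny);
        int k = (int)(idx / ((R_xlen_t)nx * ny));
        for (int t = 0; t < noff; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (m[nb] && s[nb] >= h && !lab[nb]) {
            lab[nb] = current;
            csize[current] += 1.0;
            stack.push_back(nb);
          }
        }
      }
    }
    double hH = std::pow(h, H);
    for (R_xlen_t i = 0; i < n; ++i) {
      if (lab[i])
        o[i] += std::pow(csize[lab[i]], E) * hH * dh;
    }
  }
  return out;
}
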