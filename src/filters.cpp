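#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filtering with zero initial conditions.
// b and a are pre-normalized (a[0] == 1) and padded to equal length L.
static inline void iir_filter(const double* b, const double* a, const int L,
                              const double* x, double* y, double* z,
                              const int n) {
  const int nz = L - 1;
  for (int k = 0; k < nz; ++k) z[k] = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering of every column of x, with
// reflective (odd) end padding of npad samples to tame edge transients.
// [[Rcpp::export]]
NumericMatrix iir_filtfilt_mat(NumericVector b, NumericVector a,
                               NumericMatrix x, int npad) {
  const int n = x.nrow();
  const int nc = x.ncol();
  if (npad > n - 1) npad = n - 1;
  if (npad < 0) npad = 0;
  const int m = n + 2 * npad;
  const int L = std::max(b.size(), a.size());
  if (L < 1 || a.size() < 1 || a[0] == 0.0)
    stop("invalid filter coefficients");
  std::vector<double> bb(L, 0.0), aa(L, 0.0);
  for (int k = 0; k < b.size(); ++k) bb[k] = b[k] / a[0];
  for (int k = 0; k < a.size(); ++k) aa[k] = a[k] / a[0];
  NumericMatrix out(n, nc);
  std::vector<double> xp(m), tmp(m), z(L);
  for (int j = 0; j < nc; ++j) {
    const double* col = &x(0, j);
    for (int i = 0; i < npad; ++i)
      xp[i] = 2.0 * col[0] - col[npad - i];
    std::copy(col, col + n, xp.begin() + npad);
    for (int i = 0; i < npad; ++i)
      xp[npad + n + i] = 2.0 * col[n - 1] - col[n - 2 - i];
    iir_filter(bb.data(), aa.data(), L, xp.data(), tmp.data(), z.data(), m);
    std::reverse(tmp.begin(), tmp.end());
    iir_filter(bb.data(), aa.data(), L, tmp.data(), xp.data(), z.data(), m);
    for (int i = 0; i < n; ++i) out(i, j) = xp[m - 1 - npad - i];
  }
  return out;
}
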