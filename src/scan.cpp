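#include <Rcpp.h>
using namespace Rcpp;

// Window set for a contiguous run of m SNPs: all windows whose length
// is a multiple of `step`, capped at min(cap, m); a run shorter than
// `step` contributes its single full-length window.
static inline void window_lengths(int m, int step, int cap,
                                  std::vector<int>& out) {
  out.clear();
  if (m < step) {
    if (m >= 1) out.push_back(m);
    return;
  }
  int maxlen = std::min(cap, m);
  for (int L = step; L <= maxlen; L += step) out.push_back(L);
}

// Best window (max |Q|) in one contiguous run. Ties broken by
// smallest start, then smallest length. Returns [q_signed, start, len]
// with 1-based start; start = 0 when no window exists.
// [[Rcpp::export]]
NumericVector cpp_best_window(NumericVector z1, NumericVector z2,
                              NumericVector l, double theta,
                              int step, int cap) {
  int m = z1.size();
  std::vector<int> lens;
  window_lengths(m, step, cap, lens);
  std::vector<double> cp(m + 1, 0.0), cl(m + 1, 0.0);
  for (int i = 0; i < m; ++i) {
    cp[i + 1] = cp[i] + z1[i] * z2[i];
    cl[i + 1] = cl[i] + l[i];
  }
  double best = -1.0, bestq = 0.0;
  int bs = 0, bl = 0;
  for (size_t k = 0; k < lens.size(); ++k) {
    int L = lens[k];
    for (int s = 0; s + L <= m; ++s) {
      double num = cp[s + L] - cp[s];
      double den = std::pow(cl[s + L] - cl[s], theta);
      double q = num / den;
      double aq = std::fabs(q);
      bool take = aq > best ||
        (aq == best && (s + 1 < bs || (s + 1 == bs && L < bl)));
      if (take) { best = aq; bestq = q; bs = s + 1; bl = L; }
    }
  }
  return NumericVector::create(bestq, (double)bs, (double)bl);
}

// Max |Q| per column over the same window set; Z1, Z2 are SNPs x B.
// [[Rcpp::export]]
NumericVector cpp_qmax_batch(NumericMatrix Z1, NumericMatrix Z2,
                             NumericVector l, double theta,
                             int step, int cap) {
  int m = Z1.nrow(), B = Z1.ncol();
  std::vector<int> lens;
  window_lengths(m, step, cap, lens);
  std::vector<double> cl(m + 1, 0.0);
  for (int i = 0; i < m; ++i) cl[i + 1] = cl[i] + l[i];
  // Precompute denominators per (length, start)
  std::vector<std::vector<double>> den(lens.size());
  for (size_t k = 0; k < lens.size(); ++k) {
    int L = lens[k];
    den[k].resize(m - L + 1);
    for (int s = 0; s + L <= m; ++s)
      den[k][s] = std::pow(cl[s + L] - cl[s], theta);
  }
  NumericVector out(B);
  std::vector<double> cp(m + 1, 0.0);
  for (int j = 0; j < B; ++j) {
    for (int i = 0; i < m; ++i)
      cp[i + 1] = cp[i] + Z1(i, j) * Z2(i, j);
    double best = 0.0;
    for (size_t k = 0; k < lens.size(); ++k) {
      int L = lens[k];
      for (int s = 0; s + L <= m; ++s) {
        double q = std::fabs((cp[s + L] - cp[s]) / den[k][s]);
        if (q > best) best = q;
      }
    }
    out[j] = best;
  }
  return out;
}
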