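#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM
// (the liblinear algorithm). X is n x p with the bias column already
// appended by the caller; y is +/-1. Deterministic: the coordinate order is
// shuffled by an internal LCG seeded from `seed`.
// [[Rcpp::export]]
NumericVector svm_dcd_train(NumericMatrix X, NumericVector y, double C,
                            int max_passes, double tol, int seed) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector w(p), alpha(n), qii(n);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) {
    order[i] = i;
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  unsigned long long rng = (unsigned long long)seed * 2862933555777941757ULL + 3037000493ULL;
  for (int pass = 0; pass < max_passes; ++pass) {
    // Fisher-Yates with the LCG
    for (int i = n - 1; i > 0; --i) {
      rng = rng * 6364136223846793005ULL + 1442695040888963407ULL;
      int j = (int)((rng >> 33) % (unsigned long long)(i + 1));
      std::swap(order[i], order[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      if (qii[i] <= 0) continue;
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      const double G = y[i] * wx - 1.0;
      double pg = G;
      if (alpha[i] <= 0.0 && G > 0.0) pg = 0.0;
      else if (alpha[i] >= C && G < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        if (d != 0.0) for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
      }
    }
    if (max_pg < tol) break;
  }
  return w;
}
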