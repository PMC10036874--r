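#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM on a
// precomputed Gram matrix. The bias is handled by augmenting the kernel
// with a constant (+1) term, i.e. callers pass K + 1. Small problems
// (tens of trials) converge in a handful of sweeps, which is what makes
// the 10^5-10^6 refits of the permutation/bootstrap inference tractable.
static void dcd_solve(const NumericMatrix &K, const std::vector<double> &y,
                      double C, std::vector<double> &alpha) {
  const int n = y.size();
  std::vector<double> grad(n, -1.0); // grad_i = (Q alpha)_i - 1, alpha = 0
  std::fill(alpha.begin(), alpha.end(), 0.0);
  const int max_sweeps = 1000;
  const double tol = 1e-10;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      double G = grad[i];
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double qii = K(i, i); // y_i^2 = 1
        double a_new = alpha[i] - G / qii;
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        double delta = a_new - alpha[i];
        if (delta != 0.0) {
          alpha[i] = a_new;
          for (int j = 0; j < n; ++j)
            grad[j] += delta * y[i] * y[j] * K(j, i);
        }
      }
    }
    if (max_pg < tol) break;
  }
}

// Decision values on test items for an SVM trained on (K_train, y_train).
// K_train: n_tr x n_tr (bias-augmented), K_cross: n_te x n_tr.
// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix K_train, NumericMatrix K_cross,
                               NumericVector y_train, double C) {
  const int n = y_train.size(), m = K_cross.nrow();
  std::vector<double> y(y_train.begin(), y_train.end());
  std::vector<double> alpha(n);
  dcd_solve(K_train, y, C, alpha);
  NumericVector f(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += alpha[i] * y[i] * K_cross(j, i);
    f[j] = s;
  }
  return f;
}

// Label-permutation null: retrain on permuted training labels, score test
// accuracy. perms is n_perm x n_tr, 1-based indices into y_train.
// [[Rcpp::export]]
NumericVector svm_perm_acc_cpp(NumericMatrix K_train, NumericMatrix K_cross,
                               NumericVector y_train, NumericVector y_test,
                               IntegerMatrix perms, double C) {
  const int n = y_train.size(), m = y_test.size(), P = perms.nrow();
  std::vector<double> y(n), alpha(n);
  NumericVector acc(P);
  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < n; ++i) y[i] = y_train[perms(p, i) - 1];
    dcd_solve(K_train, y, C, alpha);
    int correct = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += alpha[i] * y[i] * K_cross(j, i);
      if ((s > 0.0 ? 1.0 : -1.0) == y_test[j]) ++correct;
    }
    acc[p] = static_cast<double>(correct) / m;
  }
  return acc;
}
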