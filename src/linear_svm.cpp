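// Deterministic weighted linear SVM via dual coordinate descent
// (hinge loss, liblinear-style with the intercept folded into the
// weight vector through an augmented constant feature).  Cyclic
// update order, no random permutation: results are bit-reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Solve min_w 0.5 w'w + sum_i C_i max(0, 1 - y_i w'x_i) on the
// augmented design (last column == 1).  X is n x d, row-major copy.
void dcd_solve(const std::vector<double>& X, int n, int d,
               const std::vector<double>& y, const std::vector<double>& C,
               std::vector<double>& w, std::vector<double>& alpha,
               int max_pass, double tol) {
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X[i * d + j] * X[i * d + j];
    qii[i] = s;
  }
  // deterministic pseudo-random visiting order (golden-ratio stride):
  // far better conditioned than cyclic order, still bit-reproducible
  std::vector<int> order(n);
  {
    std::vector<char> used(n, 0);
    int idx = 0;
    for (int k = 0; k < n; ++k) {
      int pos = (int)(((long long)(k + 1) * 2654435761u) % (unsigned)n);
      while (used[pos]) pos = (pos + 1) % n;
      used[pos] = 1;
      order[idx++] = pos;
    }
  }
  // w must be consistent with incoming alpha (warm start support)
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_viol = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = order[t];
      if (qii[i] <= 0.0) continue;
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * X[i * d + j];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C[i]) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_viol) max_viol = std::fabs(pg);
      if (pg != 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C[i]) a_new = C[i];
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X[i * d + j];
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
}

void copy_design(const NumericMatrix& Xin, std::vector<double>& X,
                 int n, int d) {
  // augment with constant 1 as last column; row-major for locality
  X.assign((size_t)n * (d + 1), 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) X[i * (d + 1) + j] = Xin(i, j);
    X[i * (d + 1) + d] = 1.0;
  }
}

} // namespace

// [[Rcpp::export(name = ".svm_dcd_fit")]]
List svm_dcd_fit(NumericMatrix Xin, NumericVector yin, NumericVector Cin,
                 int max_pass = 2000, double tol = 1e-6) {
  int n = Xin.nrow(), d = Xin.ncol();
  std::vector<double> X;
  copy_design(Xin, X, n, d);
  std::vector<double> y(yin.begin(), yin.end());
  std::vector<double> C(Cin.begin(), Cin.end());
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0);
  dcd_solve(X, n, d + 1, y, C, w, alpha, max_pass, tol);
  NumericVector wout(d);
  for (int j = 0; j < d; ++j) wout[j] = w[j];
  return List::create(_["w"] = wout, _["b"] = w[d],
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()));
}

// Leave-one-out decision values: for each held-out i the SVM is refit
// on the remaining n-1 rows (warm-started from the full-data solution)
// and the decision value w'x_i + b for the held-out row is returned.
// [[Rcpp::export(name = ".svm_dcd_loo")]]
NumericVector svm_dcd_loo(NumericMatrix Xin, NumericVector yin,
                          NumericVector Cin, int max_pass = 2000,
                          double tol = 1e-6) {
  int n = Xin.nrow(), d = Xin.ncol(), da = d + 1;
  std::vector<double> X;
  copy_design(Xin, X, n, da - 1);
  std::vector<double> y(yin.begin(), yin.end());
  std::vector<double> C(Cin.begin(), Cin.end());

  std::vector<double> w0(da, 0.0), a0(n, 0.0);
  dcd_solve(X, n, da, y, C, w0, a0, max_pass, tol);

  NumericVector dec(n);
  std::vector<double> Xs((size_t)(n - 1) * da);
  std::vector<double> ys(n - 1), Cs(n - 1), as(n - 1), w(da);
  for (int hold = 0; hold < n; ++hold) {
    int k = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      for (int j = 0; j < da; ++j) Xs[k * da + j] = X[i * da + j];
      ys[k] = y[i];
      Cs[k] = C[i];
      as[k] = a0[i];
      ++k;
    }
    // warm start: drop the held-out point's dual contribution from w
    for (int j = 0; j < da; ++j)
      w[j] = w0[j] - a0[hold] * y[hold] * X[hold * da + j];
    dcd_solve(Xs, n - 1, da, ys, Cs, w, as, max_pass, tol);
    double s = 0.0;
    for (int j = 0; j < da; ++j) s += w[j] * X[hold * da + j];
    dec[hold] = s;
  }
  return dec;
}
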