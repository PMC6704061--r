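// Soft-margin RBF-kernel SVM dual solved by SMO with maximal-violating-pair
// working-set selection (the stopping rule and pair choice used by the
// standard C-SVC solvers).  Supports per-class penalty C so minority-class
// errors can be weighted more heavily.  The full Gram matrix is precomputed:
// memory is O(n^2), fine for the trimmed training sets this package targets
// (guard at n = 8192).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double rbf(const NumericMatrix &X, int i, int j, double gamma) {
  double s = 0.0;
  const int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = X(i, k) - X(j, k);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix X, NumericVector y, double C_pos, double C_neg,
               double gamma, double tol = 1e-3, int max_iter = -1) {
  const int n = X.nrow();
  if (n > 8192) stop("training set too large for dense kernel SMO (n > 8192)");
  if (max_iter < 0) max_iter = std::max(200000, 200 * n);

  // per-sample box constraint
  std::vector<double> C(n);
  for (int i = 0; i < n; ++i) C[i] = (y[i] > 0) ? C_pos : C_neg;

  // dense Gram matrix
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = rbf(X, i, j, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0);
  // F_i = sum_l alpha_l y_l K(l, i)  (decision value without bias)
  std::vector<double> F(n, 0.0);

  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    // maximal violating pair: i in I_up maximizing y_i - F_i,
    //                         j in I_low minimizing y_j - F_j
    int i = -1, j = -1;
    double up = -HUGE_VAL, low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double g = y[t] - F[t];
      const bool in_up  = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      const bool in_low = (y[t] > 0) ? (alpha[t] > 0)   : (alpha[t] < C[t]);
      if (in_up && g > up)  { up = g;  i = t; }
      if (in_low && g < low) { low = g; j = t; }
    }
    if (i < 0 || j < 0 || up - low < tol) { converged = true; break; }

    const double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
                 Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = 1e-12;

    const double ai_old = alpha[i], aj_old = alpha[j];
    const double Ei = F[i] - y[i], Ej = F[j] - y[j];
    // optimize alpha[j] along the equality constraint
    double aj = aj_old + y[j] * (Ei - Ej) / eta;

    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C[j], C[i] + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C[i]);
      H = std::min(C[j], ai_old + aj_old);
    }
    if (aj > H) aj = H;
    if (aj < L) aj = L;
    const double ai = ai_old + y[i] * y[j] * (aj_old - aj);

    const double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    if (std::fabs(di) < 1e-15 && std::fabs(dj) < 1e-15) {
      // numerically stuck pair; treat as converged at this tolerance
      converged = true;
      break;
    }
    alpha[i] = ai;
    alpha[j] = aj;
    const double *Ki = &K[(size_t)i * n], *Kj = &K[(size_t)j * n];
    for (int t = 0; t < n; ++t) F[t] += di * Ki[t] + dj * Kj[t];
    ++iter;
  }

  // bias: average y_i - F_i over free SVs, else midpoint of bounds
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-8 && alpha[t] < C[t] - 1e-8) { b += y[t] - F[t]; ++nfree; }
  if (nfree > 0) {
    b /= nfree;
  } else {
    double up = -HUGE_VAL, low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double g = y[t] - F[t];
      const bool in_up  = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      const bool in_low = (y[t] > 0) ? (alpha[t] > 0)   : (alpha[t] < C[t]);
      if (in_up && g > up) up = g;
      if (in_low && g < low) low = g;
    }
    b = (up + low) / 2.0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged);
}

// Decision values f(x) = sum_i coef_i K(x_i, x) + b for new rows, where
// coef_i = alpha_i * y_i over the support vectors.
// [[Rcpp::export(name = ".rbf_decision")]]
NumericVector rbf_decision(NumericMatrix Xsv, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int m = Xnew.nrow(), nsv = Xsv.nrow(), d = Xsv.ncol();
  if (Xnew.ncol() != d) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double f = b;
    for (int i = 0; i < nsv; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = Xsv(i, k) - Xnew(q, k);
        s += diff * diff;
      }
      f += coef[i] * std::exp(-gamma * s);
    }
    out[q] = f;
  }
  return out;
}
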