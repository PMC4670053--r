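#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sequential minimal optimization for the binary C-SVM dual with an RBF
// kernel and per-sample box constraints (class-weighted C). Working-set
// selection is the second-order maximal-violating-pair rule; iteration stops
// when m(alpha) - M(alpha) < eps. The full kernel matrix is precomputed:
// training sets in this package are at most a few thousand rows.
//
// Dual: min 1/2 a'Qa - e'a, 0 <= a_i <= C_i, y'a = 0, Q_ij = y_i y_j K_ij.
// Decision function: f(x) = sum_i a_i y_i K(x_i, x) - rho.
// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit(const NumericMatrix& X, const NumericVector& y, double gamma,
             const NumericVector& C, double eps, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> sq(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) { const double v = X(i, k); s += v * v; }
    sq[i] = s;
  }
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < p; ++k) { const double v = X(i, k) - X(j, k); d += v * v; }
      const double kv = std::exp(-gamma * d);
      K[(size_t)i * n + j] = kv;
      K[(size_t)j * n + i] = kv;
    }
  }

  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  int iter = 0;
  while (iter < max_iter) {
    // i: most violating index in I_up
    double Gmax = -1e300; int i = -1;
    for (int t = 0; t < n; ++t) {
      const bool up = (y[t] > 0 && alpha[t] < C[t]) || (y[t] < 0 && alpha[t] > 0);
      if (up) { const double v = -y[t] * grad[t]; if (v > Gmax) { Gmax = v; i = t; } }
    }
    // j: second-order gain among I_low
    double Gmin = 1e300; int j = -1; double obj_min = 1e300;
    if (i >= 0) {
      const double Kii = K[(size_t)i * n + i];
      for (int t = 0; t < n; ++t) {
        const bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C[t]);
        if (!low) continue;
        const double v = -y[t] * grad[t];
        if (v < Gmin) Gmin = v;
        const double b = Gmax - v;
        if (b > 0) {
          double a = Kii + K[(size_t)t * n + t] - 2.0 * y[i] * y[t] * K[(size_t)i * n + t];
          if (a <= 0) a = 1e-12;
          const double obj = -(b * b) / a;
          if (obj < obj_min) { obj_min = obj; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    const double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
                 Kij = K[(size_t)i * n + j];
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = 1e-12;
    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      const double delta = (-grad[i] - grad[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > C[i] - C[j]) { if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = C[i] - diff; } }
      else                    { if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = C[j] + diff; } }
    } else {
      const double delta = (grad[i] - grad[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C[i]) { if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = sum - C[i]; } }
      else            { if (alpha[j] < 0)    { alpha[j] = 0;    alpha[i] = sum; } }
      if (sum > C[j]) { if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = sum - C[j]; } }
      else            { if (alpha[i] < 0)    { alpha[i] = 0;    alpha[j] = sum; } }
    }
    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t) {
      grad[t] += y[t] * (y[i] * K[(size_t)i * n + t] * dai +
                         y[j] * K[(size_t)j * n + t] * daj);
    }
    ++iter;
  }

  // rho from the KKT conditions (free SVs averaged; midpoint fallback)
  double ub = 1e300, lb = -1e300, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * grad[t];
    if (alpha[t] >= C[t] - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++n_free; sum_free += yG; }
  }
  const double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iter"] = iter,
                      _["converged"] = (iter < max_iter));
}
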