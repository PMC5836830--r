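// Sequential minimal optimization for class-weighted C-SVC on a
// precomputed kernel matrix.
//
// Solves, in the unsigned variables a_i >= 0,
//   min  0.5 a' Q a - e' a
//   s.t. 0 <= a_i <= C+ (y_i = +1), 0 <= a_i <= C- (y_i = -1),
//        sum_i y_i a_i = 0,
// with Q_ij = y_i y_j K_ij, using second-order working-set selection.
// The decision function is f(x) = sum_i y_i a_i K(x_i, x) + b with
// b = -rho.  Signed coefficients y_i a_i then satisfy the asymmetric
// box constraints 0 <= coef_i <= C+ for positives and
// -C- <= coef_i <= 0 for negatives.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double TAU = 1e-12;

// [[Rcpp::export]]
List smo_csvc(const NumericMatrix& K, const IntegerVector& y,
              double c_pos, double c_neg,
              double eps = 1e-3, int max_iter = 10000000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective
  std::vector<double> C(n);
  for (int i = 0; i < n; ++i) C[i] = (y[i] > 0) ? c_pos : c_neg;

  int iter = 0;
  bool converged = false;
  const double INF = std::numeric_limits<double>::infinity();

  while (iter < max_iter) {
    // working set selection (maximal violating pair, 2nd order on j)
    int i = -1, j = -1;
    double Gmax = -INF, Gmax2 = -INF, obj_min = INF;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C[t]) : (alpha[t] > 0.0);
      if (up) {
        double v = -static_cast<double>(y[t]) * G[t];
        if (v >= Gmax) { Gmax = v; i = t; }
      }
    }
    if (i < 0) break;
    const double Kii = K(i, i);
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] > 0) ? (alpha[t] > 0.0) : (alpha[t] < C[t]);
      if (low) {
        double yG = static_cast<double>(y[t]) * G[t];
        if (yG >= Gmax2) Gmax2 = yG;
        double grad_diff = Gmax + yG;
        if (grad_diff > 0.0) {
          // curvature along the feasible direction is always
          // K_ii + K_tt - 2 K_it (the equality constraint pairs the
          // two coordinates with opposite label-scaled signs)
          double quad = Kii + K(t, t) - 2.0 * K(i, t);
          if (quad <= 0.0) quad = TAU;
          double obj = -(grad_diff * grad_diff) / quad;
          if (obj <= obj_min) { obj_min = obj; j = t; }
        }
      }
    }
    if (Gmax + Gmax2 < eps || j < 0) { converged = true; break; }

    const double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0.0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0.0) {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = -diff; }
      }
      if (diff > C[i] - C[j]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = C[i] - diff; }
      } else {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = C[j] + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0.0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C[i]) {
        if (alpha[i] > C[i]) { alpha[i] = C[i]; alpha[j] = sum - C[i]; }
      } else {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = sum; }
      }
      if (sum > C[j]) {
        if (alpha[j] > C[j]) { alpha[j] = C[j]; alpha[i] = sum - C[j]; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai;
    const double daj = alpha[j] - old_aj;
    const double yi = y[i], yj = y[j];
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (yi * K(t, i) * dai + yj * K(t, j) * daj);
    }
    ++iter;
  }

  // bias: average y_i G_i over free vectors, else the bound midpoint
  double ub = INF, lb = -INF, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = static_cast<double>(y[t]) * G[t];
    bool upper = alpha[t] >= C[t];
    bool lower = alpha[t] <= 0.0;
    if (upper) {
      if (y[t] < 0) { if (yG < ub) ub = yG; }
      else          { if (yG > lb) lb = yG; }
    } else if (lower) {
      if (y[t] > 0) { if (yG < ub) ub = yG; }
      else          { if (yG > lb) lb = yG; }
    } else {
      ++n_free;
      sum_free += yG;
    }
  }
  double rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;

  NumericVector coef(n);
  double obj = 0.0;
  for (int t = 0; t < n; ++t) {
    coef[t] = y[t] * alpha[t];
    obj += alpha[t] * (G[t] - 1.0);
  }
  obj /= 2.0;

  return List::create(_["coef"] = coef,
                      _["bias"] = -rho,
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["objective"] = obj);
}
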