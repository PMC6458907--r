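#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual:
//   min_a  0.5 * sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
//   s.t.   0 <= a_i <= C,  sum_i a_i y_i = 0
// First-order maximal-violating-pair working-set selection; stops when the
// KKT violation m - M drops below eps. The kernel matrix is passed in full
// (problems here have a few dozen samples, so no caching is needed).

// [[Rcpp::export]]
List svm_smo_cpp(NumericMatrix K, NumericVector y, double C,
                 double eps = 1e-8, int max_iter = 100000) {
  const int n = K.nrow();
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  bool converged = false;
  double m = 0.0, M = 0.0;

  while (iter < max_iter) {
    // working-set selection: i maximizes -y*G over I_up, j minimizes over I_low
    int i = -1, j = -1;
    m = -std::numeric_limits<double>::infinity();
    M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up  && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < eps) { converged = true; break; }

    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      // curvature along the feasible direction; in Q = yy'K terms this is
      // Q_ii + Q_jj + 2 Q_ij, i.e. K_ii + K_jj - 2 K_ij for opposite labels
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (K(t, i) * y[i] * dai + K(t, j) * y[j] * daj);
    }
    ++iter;
  }

  // intercept: b = -y_t G_t averaged over free support vectors, or the
  // midpoint of the feasibility interval when none are free
  double b_sum = 0.0; int b_n = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > TAU && alpha[t] < C - TAU) { b_sum += -y[t] * G[t]; ++b_n; }
  }
  double b = (b_n > 0) ? b_sum / b_n : 0.5 * (m + M);

  return List::create(_["alpha"] = alpha, _["b"] = b,
                      _["iterations"] = iter, _["converged"] = converged);
}
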