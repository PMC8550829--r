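#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the binary soft-margin C-SVC dual with a
// precomputed kernel matrix, using maximal-violating-pair working-set selection
// (the scheme of Keerthi et al. / LIBSVM's WSS1).
//
// Solves: max_a  sum a_i - 1/2 sum_ij a_i a_j y_i y_j K_ij
//         s.t.   0 <= a_i <= C,  sum a_i y_i = 0
//
// K must be symmetric PSD (up to tolerance); y in {-1, +1}.
// Returns alpha (box multipliers), b (intercept in f(x) = sum a_i y_i K(x,i) + b),
// the iteration count and the final KKT gap.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C, double tol,
               int max_iter) {
  int n = K.nrow();
  if (K.ncol() != n) stop("K must be square");
  if (y.size() != n) stop("length(y) must equal nrow(K)");

  std::vector<double> alpha(n, 0.0);
  // gradient of the dual objective w.r.t. alpha: G_i = y_i * f_i - 1, with
  // f_i = sum_j alpha_j y_j K_ij; at alpha = 0, G_i = -1.
  std::vector<double> G(n, -1.0);

  int iter = 0;
  double gap = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: i = argmax_{i in I_up} -y_i G_i,
    //                        j = argmin_{j in I_low} -y_j G_j
    int i = -1, j = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    gap = Gmax - Gmin;
    if (gap < tol || i < 0 || j < 0) break;

    // solve the 2-variable subproblem for (i, j) analytically
    double yi = y[i], yj = y[j];
    double ai = alpha[i], aj = alpha[j];
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12; // PSD guard: degenerate pair
    double delta = (Gmax - Gmin) / quad; // step along y_i e_i - y_j e_j
    double ai_new = ai + yi * delta;
    double aj_new = aj - yj * delta;

    // clip to the box while keeping sum alpha_t y_t constant
    double sum = yi * ai + yj * aj;
    if (ai_new < 0) ai_new = 0;
    if (ai_new > C) ai_new = C;
    aj_new = yj * (sum - yi * ai_new);
    if (aj_new < 0) { aj_new = 0; ai_new = yi * (sum - yj * aj_new); }
    if (aj_new > C) { aj_new = C; ai_new = yi * (sum - yj * aj_new); }
    if (ai_new < 0) ai_new = 0;
    if (ai_new > C) ai_new = C;

    double di = (ai_new - ai) * yi;
    double dj = (aj_new - aj) * yj;
    if (std::abs(di) < 1e-16 && std::abs(dj) < 1e-16) break; // numerically stuck
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (di * K(i, t) + dj * K(j, t));
    alpha[i] = ai_new;
    alpha[j] = aj_new;
  }

  // intercept: average of y_i - f_i over free vectors (0 < alpha < C);
  // fall back to the midpoint of the KKT bounds when none is free.
  double bsum = 0.0; int nfree = 0;
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    double ft = y[t] * (G[t] + 1.0); // f_t without intercept (y_t f_t = G_t + 1)
    double r = y[t] - ft;
    bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
    bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { bsum += r; ++nfree; }
    if (up && r < ub) ub = r;
    if (low && r > lb) lb = r;
  }
  double b = nfree > 0 ? bsum / nfree : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter, _["kkt_gap"] = gap);
}
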