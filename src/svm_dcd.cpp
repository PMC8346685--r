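#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM:
//   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// solved in the dual with 0 <= alpha_i <= C (Hsieh et al. style, with
// random permutation of the coordinate order and active-set shrinking).
// The bias is an augmented, regularized constant feature, the usual
// choice for linear solvers. The permutation stream comes from a private
// LCG seeded with a fixed constant, so results are fully deterministic
// and independent of R's RNG state.
// [[Rcpp::export]]
List svm_dcd(NumericMatrix X, IntegerVector y01, double C,
             double tol = 0.1, int max_passes = 1000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p + 1, 0.0), alpha(n, 0.0), Qii(n), yv(n);
  for (int i = 0; i < n; ++i) {
    yv[i] = (y01[i] == 1) ? 1.0 : -1.0;
    double q = 1.0;  // bias feature contributes 1
    for (int j = 0; j < p; ++j) q += X(i, j) * X(i, j);
    Qii[i] = q;
  }
  std::vector<int> index(n);
  for (int i = 0; i < n; ++i) index[i] = i;
  unsigned long long rng = 88172645463325252ULL;  // fixed xorshift seed
  auto next_rand = [&rng]() {
    rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    return rng;
  };
  int active = n, pass = 0;
  double PGmax_old = R_PosInf, PGmin_old = R_NegInf;
  for (; pass < max_passes; ++pass) {
    double PGmax_new = R_NegInf, PGmin_new = R_PosInf;
    for (int s = 0; s < active; ++s) {
      int r = s + (int)(next_rand() % (unsigned)(active - s));
      std::swap(index[s], index[r]);
    }
    for (int s = 0; s < active; ++s) {
      const int i = index[s];
      double dot = w[p];
      for (int j = 0; j < p; ++j) dot += w[j] * X(i, j);
      const double G = yv[i] * dot - 1.0;
      double PG = 0.0;
      if (alpha[i] <= 0.0) {
        if (G > PGmax_old) {  // shrink
          std::swap(index[s], index[--active]); --s; continue;
        }
        if (G < 0.0) PG = G;
      } else if (alpha[i] >= C) {
        if (G < PGmin_old) {
          std::swap(index[s], index[--active]); --s; continue;
        }
        if (G > 0.0) PG = G;
      } else PG = G;
      if (PG > PGmax_new) PGmax_new = PG;
      if (PG < PGmin_new) PGmin_new = PG;
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - G / Qii[i];
        if (a_new < 0.0) a_new = 0.0; else if (a_new > C) a_new = C;
        const double d = (a_new - a_old) * yv[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
          w[p] += d;
          alpha[i] = a_new;
        }
      }
    }
    if (PGmax_new - PGmin_new <= tol) {
      if (active == n) { ++pass; break; }
      // converged on the shrunken set: recheck everything
      active = n; PGmax_old = R_PosInf; PGmin_old = R_NegInf;
      continue;
    }
    PGmax_old = (PGmax_new <= 0.0) ? R_PosInf : PGmax_new;
    PGmin_old = (PGmin_new >= 0.0) ? R_NegInf : PGmin_new;
  }
  NumericVector wout(p);
  for (int j = 0; j < p; ++j) wout[j] = w[j];
  return List::create(_["w"] = wout, _["b"] = w[p], _["passes"] = pass);
}
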