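#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Mixture density over triplet internal branch lengths:
//   f(t) = pi * Exp(t; lambda) + (1 - pi) * Exp(t - c; lambda) * 1[t >= c]
// with Exp(x; lambda) = (1/lambda) exp(-x/lambda). The ILS component is the
// plain exponential; the non-ILS component adds a fixed lag c.

static double loglik(const NumericVector &t, double pi, double lambda,
                     double c) {
  const double inv = 1.0 / lambda;
  double ll = 0.0;
  for (int i = 0; i < t.size(); ++i) {
    double d1 = inv * std::exp(-t[i] * inv);
    double d2 = (t[i] >= c) ? inv * std::exp(-(t[i] - c) * inv) : 0.0;
    double f = pi * d1 + (1.0 - pi) * d2;
    if (f <= 0.0 || !std::isfinite(f))
      return -std::numeric_limits<double>::infinity();
    ll += std::log(f);
  }
  return ll;
}

// maximize loglik over c on [0, hi): coarse grid scan, then golden-section
// refinement inside the best bracket (the profile in c is only piecewise
// smooth, so the scan guards against local optima)
static double best_c(const NumericVector &t, double pi, double lambda,
                     double hi) {
  const int ngrid = 64;
  double best = 0.0, fbest = loglik(t, pi, lambda, 0.0);
  for (int g = 1; g < ngrid; ++g) {
    double cg = hi * g / ngrid;
    double f = loglik(t, pi, lambda, cg);
    if (f > fbest) { fbest = f; best = cg; }
  }
  double a = std::max(0.0, best - hi / ngrid);
  double b = std::min(hi, best + hi / ngrid);
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = loglik(t, pi, lambda, x1), f2 = loglik(t, pi, lambda, x2);
  for (int it = 0; it < 50 && (b - a) > 1e-12 * (hi + 1.0); ++it) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = loglik(t, pi, lambda, x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = loglik(t, pi, lambda, x1);
    }
  }
  double cm = 0.5 * (a + b);
  if (loglik(t, pi, lambda, cm) > fbest) return cm;
  return best;
}

// EM for (pi, lambda) with a generalized (accept-if-better) update of c by
// bounded 1-D likelihood search; the observed log-likelihood never decreases.
// [[Rcpp::export]]
List em_shift_mix_cpp(NumericVector t, double pi0, double lambda0, double c0,
                      double tol, int max_iter) {
  const int n = t.size();
  double pi = std::min(std::max(pi0, 1e-9), 1.0 - 1e-9);
  double lambda = std::max(lambda0, 1e-12);
  double tmax = Rcpp::max(t);
  double c = std::min(std::max(c0, 0.0), tmax * 0.999999);
  double ll = loglik(t, pi, lambda, c);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step + closed-form M-step for pi and lambda
    const double inv = 1.0 / lambda;
    double sr = 0.0, s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = inv * std::exp(-t[i] * inv);
      double d2 = (t[i] >= c) ? inv * std::exp(-(t[i] - c) * inv) : 0.0;
      double num = pi * d1;
      double den = num + (1.0 - pi) * d2;
      double r = (den > 0.0) ? num / den : 1.0;
      sr += r;
      s1 += r * t[i];
      s2 += (1.0 - r) * (t[i] - c);
    }
    pi = std::min(std::max(sr / n, 1e-9), 1.0 - 1e-9);
    lambda = std::max((s1 + s2) / n, 1e-12);
    // conditional maximization over c, accepted only when it improves
    double cn = best_c(t, pi, lambda, tmax * 0.999999);
    double ll_new_c = loglik(t, pi, lambda, cn);
    double ll_old_c = loglik(t, pi, lambda, c);
    if (ll_new_c > ll_old_c) c = cn;
    double ll_new = std::max(ll_new_c, ll_old_c);
    // relative convergence test: lnL magnitudes grow with n, so an absolute
    // 1e-8 would keep the EM polishing noise for thousands of iterations
    if (std::isfinite(ll_new) &&
        std::fabs(ll_new - ll) < tol * (std::fabs(ll_new) + 1.0)) {
      ll = ll_new;
      converged = true;
      break;
    }
    ll = ll_new;
  }
  return List::create(_["pi"] = pi, _["lambda"] = lambda, _["c"] = c,
                      _["lnL"] = ll, _["iterations"] = iter,
                      _["converged"] = converged);
}

// observed log-likelihood, exported for tests and the R-side profiling
// [[Rcpp::export]]
double shift_mix_loglik_cpp(NumericVector t, double pi, double lambda,
                            double c) {
  return loglik(t, pi, lambda, c);
}
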