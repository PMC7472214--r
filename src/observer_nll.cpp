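// Fast negative log-likelihood of the Bayesian-observer model.
// Mirrors the R reference implementation in run_observer(); the two paths
// are asserted equal in the test suite. Quadrature nodes/weights for the
// relative-confidence integral are supplied from R (Gauss-Legendre on
// [0, 1]; in-model beta shapes are always >= 1 so the integrand is smooth).

#include <Rcpp.h>
using namespace Rcpp;

static double p_greater(double g1, double e1, double g0, double e0,
                        const NumericVector& x, const NumericVector& w,
                        const std::vector<double>& lx,
                        const std::vector<double>& l1x) {
  const double lb = R::lbeta(g1, e1);
  double p = 0.0;
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    const double d = std::exp((g1 - 1.0) * lx[i] + (e1 - 1.0) * l1x[i] - lb);
    p += w[i] * d * R::pbeta(x[i], g0, e0, 1, 0);
  }
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export(name = ".observer_nll_cpp")]]
double observer_nll_cpp(IntegerVector choice, IntegerVector reward,
                        double beta, double omega, double lambda,
                        double upsilon, double kappa, bool literal,
                        NumericVector glx, NumericVector glw) {
  const int T = choice.size();
  const int nq = glx.size();
  std::vector<double> lx(nq), l1x(nq);
  for (int i = 0; i < nq; ++i) {
    lx[i] = std::log(glx[i]);
    l1x[i] = std::log1p(-glx[i]);
  }
  double g[2] = {1.0, 1.0}, e[2] = {1.0, 1.0};
  double m[2] = {0.5, 0.5};
  double nll = 0.0;

  for (int t = 0; t < T; ++t) {
    if (choice[t] == NA_INTEGER) continue;  // missed: no likelihood, no update
    const int a = choice[t], u = 1 - a;

    // stable log softmax probability of the observed choice
    const double z = beta * (m[a] - m[u]);
    const double lp = (z > 0.0) ? -log1p(std::exp(-z))
                                : z - log1p(std::exp(z));
    nll -= lp;

    // unchosen-bandit terms at trial t (pre-update state)
    double qu = g[u] / (g[u] + e[u]);
    double su = g[u] + e[u];
    double vu = g[u] * e[u] / (su * su * (su + 1.0));
    double crel = 2.0 * p_greater(g[a], e[a], g[u], e[u], glx, glw, lx, l1x) - 1.0;

    // belief updates: chosen relaxes at omega with outcome increment,
    // unchosen relaxes toward the uniform prior at lambda
    if (reward[t] == 1) {
      g[a] = (1.0 - omega) * g[a] + omega + 1.0;
      e[a] = (1.0 - omega) * e[a] + omega;
    } else {
      g[a] = (1.0 - omega) * g[a] + omega;
      e[a] = (1.0 - omega) * e[a] + omega + 1.0;
    }
    g[u] = (1.0 - lambda) * g[u] + lambda;
    e[u] = (1.0 - lambda) * e[u] + lambda;
    if (g[a] < 1e-8) g[a] = 1e-8;
    if (e[a] < 1e-8) e[a] = 1e-8;
    if (g[u] < 1e-8) g[u] = 1e-8;
    if (e[u] < 1e-8) e[u] = 1e-8;

    if (!literal) {  // post-update timing convention
      qu = g[u] / (g[u] + e[u]);
      su = g[u] + e[u];
      vu = g[u] * e[u] / (su * su * (su + 1.0));
      crel = 2.0 * p_greater(g[a], e[a], g[u], e[u], glx, glw, lx, l1x) - 1.0;
    }

    m[a] = g[a] / (g[a] + e[a]);
    m[u] = qu + upsilon * vu + kappa * crel;
  }
  return nll;
}
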