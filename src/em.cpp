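#include <Rcpp.h>
using namespace Rcpp;

// EM for a two-component univariate Gaussian mixture.
// Returns parameters ordered by mean, the log-likelihood trace, and
// convergence information. Variances are floored at var_floor.
// [[Rcpp::export(name = ".em2_cpp")]]
List em2_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
             NumericVector v0, double var_floor, double tol, int max_iter,
             bool equal_var) {
  const int n = x.size();
  double w1 = w0[0], w2 = w0[1];
  double m1 = mu0[0], m2 = mu0[1];
  double v1 = std::max(v0[0], var_floor), v2 = std::max(v0[1], var_floor);
  const double log2pi = std::log(2.0 * M_PI);

  std::vector<double> trace;
  trace.reserve(64);
  NumericVector r(n);
  double ll = R_NegInf, ll_prev = R_NegInf;
  bool converged = false;
  int iter = 0;

  while (iter < max_iter) {
    ++iter;
    // E step + log-likelihood (one exp and one log1p per point)
    double c1 = std::log(w1) - 0.5 * (log2pi + std::log(v1));
    double c2 = std::log(w2) - 0.5 * (log2pi + std::log(v2));
    double h1 = 0.5 / v1, h2 = 0.5 / v2;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double z1 = x[i] - m1, z2 = x[i] - m2;
      double l1 = c1 - h1 * z1 * z1;
      double l2 = c2 - h2 * z2 * z2;
      double delta = l2 - l1;
      if (delta > 0) {
        double e = std::exp(-delta);
        r[i] = e / (1.0 + e);
        ll += l2 + std::log1p(e);
      } else {
        double e = std::exp(delta);
        r[i] = 1.0 / (1.0 + e);
        ll += l1 + std::log1p(e);
      }
    }
    trace.push_back(ll);
    if (R_finite(ll_prev) && std::fabs(ll - ll_prev) < tol * (std::fabs(ll) + 1.0)) {
      converged = true;
      break;
    }
    ll_prev = ll;
    // M step
    double n1 = 0.0, s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      n1 += r[i];
      s1 += r[i] * x[i];
      s2 += (1.0 - r[i]) * x[i];
    }
    double n2 = n - n1;
    n1 = std::max(n1, 1e-8);
    n2 = std::max(n2, 1e-8);
    w1 = n1 / n;
    w2 = n2 / n;
    m1 = s1 / n1;
    m2 = s2 / n2;
    double q1 = 0.0, q2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double z1 = x[i] - m1, z2 = x[i] - m2;
      q1 += r[i] * z1 * z1;
      q2 += (1.0 - r[i]) * z2 * z2;
    }
    if (equal_var) {
      double vv = std::max((q1 + q2) / n, var_floor);
      v1 = vv;
      v2 = vv;
    } else {
      v1 = std::max(q1 / n1, var_floor);
      v2 = std::max(q2 / n2, var_floor);
    }
  }

  NumericVector w = NumericVector::create(w1, w2);
  NumericVector mu = NumericVector::create(m1, m2);
  NumericVector sd = NumericVector::create(std::sqrt(v1), std::sqrt(v2));
  if (m2 < m1) {
    w = NumericVector::create(w2, w1);
    mu = NumericVector::create(m2, m1);
    sd = NumericVector::create(sd[1], sd[0]);
  }
  return List::create(_["weights"] = w, _["means"] = mu, _["sds"] = sd,
                      _["loglik"] = ll, _["n_iter"] = iter,
                      _["converged"] = converged,
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()));
}
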