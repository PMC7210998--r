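#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM for a univariate Gaussian mixture. variance_mode: equal variance
// shares one sigma across components. Returns parameters, the
// log-likelihood trace (one entry per iteration), and convergence info.
// [[Rcpp::export(name = ".em_normal_mixture")]]
List em_normal_mixture(NumericVector x, NumericVector mu0, NumericVector sd0,
                       NumericVector w0, bool equal_var, double sd_floor,
                       int max_iter, double tol) {
  const int n = x.size();
  const int k = mu0.size();
  NumericVector mu = clone(mu0), sigma = clone(sd0), w = clone(w0);
  NumericMatrix resp(n, k);
  std::vector<double> ll_trace;
  ll_trace.reserve(64);
  double ll_old = R_NegInf;
  bool converged = false;
  int it = 0;

  std::vector<double> lw(k), inv_sigma(k), lp(k);
  for (it = 0; it < max_iter; ++it) {
    // E-step in log space per component, stabilised by row max
    for (int j = 0; j < k; ++j) {
      lw[j] = std::log(w[j]) - std::log(sigma[j]) - 0.918938533204672742;
      inv_sigma[j] = 1.0 / sigma[j];
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - mu[j]) * inv_sigma[j];
        lp[j] = lw[j] - 0.5 * z * z;
        if (lp[j] > mx) mx = lp[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        double e = std::exp(lp[j] - mx);
        resp(i, j) = e;
        s += e;
      }
      ll += mx + std::log(s);
      double inv_s = 1.0 / s;
      for (int j = 0; j < k; ++j) resp(i, j) *= inv_s;
    }
    ll_trace.push_back(ll);
    if (it > 0 && std::fabs(ll - ll_old) < tol * (1.0 + std::fabs(ll))) {
      converged = true;
      ll_old = ll;
      break;
    }
    ll_old = ll;

    // M-step
    double pooled_num = 0.0;
    for (int j = 0; j < k; ++j) {
      double nj = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) { nj += resp(i, j); sx += resp(i, j) * x[i]; }
      if (nj < 1e-10) nj = 1e-10;
      mu[j] = sx / nj;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mu[j];
        sv += resp(i, j) * d * d;
      }
      w[j] = nj / n;
      if (equal_var) {
        pooled_num += sv;
      } else {
        sigma[j] = std::sqrt(sv / nj);
        if (sigma[j] < sd_floor) sigma[j] = sd_floor;
      }
    }
    if (equal_var) {
      double s = std::sqrt(pooled_num / n);
      if (s < sd_floor) s = sd_floor;
      for (int j = 0; j < k; ++j) sigma[j] = s;
    }
    // renormalise weights defensively
    double wsum = 0.0;
    for (int j = 0; j < k; ++j) wsum += w[j];
    for (int j = 0; j < k; ++j) w[j] /= wsum;
  }

  return List::create(
    _["weights"] = w, _["means"] = mu, _["sds"] = sigma,
    _["loglik"] = ll_old,
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["n_iter"] = (int)ll_trace.size(),
    _["converged"] = converged);
}
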