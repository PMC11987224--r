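// Gibbs sampler for the BayesC-pi whole-genome regression model.
//
// Model: y_i = mu + sum_j z_ij alpha_j delta_j + e_i
//   delta_j ~ Bernoulli(1 - pi), alpha_j | delta_j = 1 ~ N(0, sigma2_alpha)
//   sigma2_alpha, sigma2_e ~ scaled inverse chi-square
//   pi ~ Uniform(0, 1)  =>  pi | k ~ Beta(m - k + 1, k + 1)
//
// The residual vector is maintained incrementally; markers are updated in
// their given (position) order each iteration.  All randomness comes from
// R's RNG so chains are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bayescpi_gibbs")]]
List bayescpi_gibbs(NumericMatrix Z, NumericVector y,
                    int chain_length, int burn_in, int thin,
                    double pi_init, bool pi_fixed,
                    double s2a_init, bool s2a_fixed,
                    double s2e_init, bool s2e_fixed,
                    double nu_a, double scale_a,
                    double nu_e, double scale_e,
                    bool save_traces, bool debug_residual_check) {
  const int n = Z.nrow();
  const int m = Z.ncol();

  std::vector<double> zz(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* col = &Z(0, j);
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    zz[j] = s;
  }

  double mu = mean(y);
  double pi = pi_init;
  double s2a = s2a_init;
  double s2e = s2e_init;
  std::vector<double> alpha(m, 0.0);   // current alpha_j * delta_j
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  const int n_saved = (chain_length - burn_in) / thin;
  NumericVector mean_alpha(m, 0.0), incl_prob(m, 0.0);
  double sum_mu = 0, sum_pi = 0, sum_s2a = 0, sum_s2e = 0;
  NumericMatrix traces;
  if (save_traces) traces = NumericMatrix(n_saved, 5);
  int saved = 0;
  double max_resid_dev = 0.0;

  RNGScope scope;

  for (int iter = 1; iter <= chain_length; ++iter) {
    // (1) intercept
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i];
    rbar = rbar / n + mu;
    double mu_new = R::rnorm(rbar, std::sqrt(s2e / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) r[i] -= dmu;
    mu = mu_new;

    // (2) marker indicators and effects, fixed order
    int k = 0;
    double ssa = 0.0;
    for (int j = 0; j < m; ++j) {
      const double* col = &Z(0, j);
      double aj = alpha[j];
      double rhs = 0.0;
      if (aj != 0.0) {
        for (int i = 0; i < n; ++i) { r[i] += col[i] * aj; rhs += col[i] * r[i]; }
      } else {
        for (int i = 0; i < n; ++i) rhs += col[i] * r[i];
      }
      double p_incl;
      if (pi <= 0.0) {
        p_incl = 1.0;
      } else if (pi >= 1.0) {
        p_incl = 0.0;
      } else {
        double v1 = zz[j] * s2a + s2e;
        double logbf = 0.5 * (std::log(s2e) - std::log(v1)) +
          0.5 * rhs * rhs * s2a / (s2e * v1);
        double logodds = std::log(1.0 - pi) - std::log(pi) + logbf;
        p_incl = 1.0 / (1.0 + std::exp(-logodds));
      }
      if (R::unif_rand() < p_incl) {
        double h = zz[j] + s2e / s2a;
        double a_new = R::rnorm(rhs / h, std::sqrt(s2e / h));
        for (int i = 0; i < n; ++i) r[i] -= col[i] * a_new;
        alpha[j] = a_new;
        ++k;
        ssa += a_new * a_new;
      } else {
        alpha[j] = 0.0;
      }
    }

    // (3) marker-effect variance
    if (!s2a_fixed)
      s2a = (ssa + nu_a * scale_a) / R::rchisq(nu_a + k);

    // (4) residual variance
    if (!s2e_fixed) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += r[i] * r[i];
      s2e = (sse + nu_e * scale_e) / R::rchisq(nu_e + n);
    }

    // (5) inclusion-null fraction
    if (!pi_fixed)
      pi = R::rbeta((double)(m - k + 1), (double)(k + 1));

    if (debug_residual_check && iter % 1000 == 0) {
      for (int i = 0; i < n; ++i) {
        double fit = mu;
        for (int j = 0; j < m; ++j)
          if (alpha[j] != 0.0) fit += Z(i, j) * alpha[j];
        double dev = std::fabs(y[i] - fit - r[i]);
        if (dev > max_resid_dev) max_resid_dev = dev;
      }
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0 && saved < n_saved) {
      for (int j = 0; j < m; ++j) {
        mean_alpha[j] += alpha[j];
        if (alpha[j] != 0.0) incl_prob[j] += 1.0;
      }
      sum_mu += mu; sum_pi += pi; sum_s2a += s2a; sum_s2e += s2e;
      if (save_traces) {
        traces(saved, 0) = mu; traces(saved, 1) = pi;
        traces(saved, 2) = s2a; traces(saved, 3) = s2e;
        traces(saved, 4) = (double)k;
      }
      ++saved;
    }
  }

  if (saved > 0) {
    for (int j = 0; j < m; ++j) {
      mean_alpha[j] /= saved;
      incl_prob[j] /= saved;
    }
  }

  List out = List::create(
    _["mean_mu"] = saved ? sum_mu / saved : mu,
    _["mean_alpha"] = mean_alpha,
    _["inclusion_prob"] = incl_prob,
    _["mean_pi"] = saved ? sum_pi / saved : pi,
    _["mean_sigma2_alpha"] = saved ? sum_s2a / saved : s2a,
    _["mean_sigma2_e"] = saved ? sum_s2e / saved : s2e,
    _["n_saved"] = saved,
    _["max_residual_deviation"] = max_resid_dev);
  if (save_traces) out["traces"] = traces;
  return out;
}
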