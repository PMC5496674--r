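#include <Rcpp.h>
using namespace Rcpp;

// Data-augmented Metropolis-Hastings-within-Gibbs sampler for the two-class
// broken-stick model. Per sweep: random-walk MH updates for alpha, beta,
// tau; a multiplicative log-normal MH update for delta (sign-preserving,
// with the |delta'|/|delta| Hastings correction); then an exact Gibbs draw
// of every latent class label from its full conditional. Uses R's RNG so a
// set.seed() in the caller makes the chain reproducible.

static const double LOG2PI = 1.8378770664093454836;

// Residual sum of squares given current shape and labels. Only the branch
// choice depends on the label, and only for observations past c.
static double rss(const NumericVector &y, const NumericVector &t,
                  const IntegerVector &id0, const IntegerVector &labels,
                  double alpha, double beta, double delta, double c) {
  double ss = 0.0;
  int N = y.size();
  for (int j = 0; j < N; ++j) {
    double mu;
    if (labels[id0[j]] == 1 && t[j] > c)
      mu = (alpha - delta * c) + (beta + delta) * t[j];
    else
      mu = alpha + beta * t[j];
    double r = y[j] - mu;
    ss += r * r;
  }
  return ss;
}

static double log_prior_alpha(double a, double sd) {
  return R::dnorm(a, 0.0, sd, 1);
}
static double log_prior_beta(double b, double sd) {
  return R::dnorm(b, 0.0, sd, 1);
}
// Half-normal on the negative reals with the given scale.
static double log_prior_delta(double d, double scale) {
  if (d >= 0) return R_NegInf;
  return M_LN2 + R::dnorm(d / scale, 0.0, 1.0, 1) - std::log(scale);
}
static double log_prior_tau(double tau, double shape, double rate) {
  if (tau <= 0) return R_NegInf;
  return R::dgamma(tau, shape, 1.0 / rate, 1);
}

// [[Rcpp::export(name = ".cp_chain_cpp")]]
List cp_chain_cpp(NumericVector y, NumericVector t, IntegerVector id0,
                  int n, double c, double p_r,
                  int iterations, int burn_in, int thin,
                  double alpha, double beta, double delta, double tau,
                  IntegerVector labels_init,
                  NumericVector base_scales,   // alpha, beta, delta, tau
                  NumericVector prior_pars,    // sd_a, sd_b, scale_d, shape_t, rate_t
                  double f,                    // proposal dispersion factor f(n)
                  LogicalVector fixed,         // alpha, beta, delta, tau
                  bool delta_hastings) {
  int N = y.size();
  IntegerVector labels = clone(labels_init);
  int n_keep = (iterations - burn_in) / thin;
  NumericVector da(n_keep), db(n_keep), dd(n_keep), dt(n_keep);
  NumericVector label_sum(n);
  NumericVector acc(4);
  double sd_a = prior_pars[0], sd_b = prior_pars[1], sc_d = prior_pars[2];
  double sh_t = prior_pars[3], rt_t = prior_pars[4];

  double ss = rss(y, t, id0, labels, alpha, beta, delta, c);

  // Per-individual observation index ranges (ids must be grouped).
  std::vector<int> i_start(n, -1), i_end(n, -1);
  for (int j = 0; j < N; ++j) {
    if (i_start[id0[j]] < 0) i_start[id0[j]] = j;
    i_end[id0[j]] = j + 1;
  }

  int kept = 0;
  for (int s = 1; s <= iterations; ++s) {
    // alpha | .
    if (!fixed[0]) {
      double prop = R::rnorm(alpha, f * base_scales[0]);
      double ss_p = rss(y, t, id0, labels, prop, beta, delta, c);
      double la = log_prior_alpha(prop, sd_a) - log_prior_alpha(alpha, sd_a)
                - 0.5 * tau * (ss_p - ss);
      if (std::log(R::runif(0, 1)) < la) { alpha = prop; ss = ss_p; acc[0] += 1; }
    }
    // beta | .
    if (!fixed[1]) {
      double prop = R::rnorm(beta, f * base_scales[1]);
      double ss_p = rss(y, t, id0, labels, alpha, prop, delta, c);
      double la = log_prior_beta(prop, sd_b) - log_prior_beta(beta, sd_b)
                - 0.5 * tau * (ss_p - ss);
      if (std::log(R::runif(0, 1)) < la) { beta = prop; ss = ss_p; acc[1] += 1; }
    }
    // delta | . : delta' = delta * X, X ~ LogNormal(0, f); Hastings
    // correction q(d|d')/q(d'|d) = |d'|/|d| = X.
    if (!fixed[2]) {
      double lx = R::rnorm(0.0, f * base_scales[2]);
      double prop = delta * std::exp(lx);
      double ss_p = rss(y, t, id0, labels, alpha, beta, prop, c);
      double la = log_prior_delta(prop, sc_d) - log_prior_delta(delta, sc_d)
                - 0.5 * tau * (ss_p - ss);
      if (delta_hastings) la += lx;
      if (std::log(R::runif(0, 1)) < la) { delta = prop; ss = ss_p; acc[2] += 1; }
    }
    // tau | . : Gaussian random walk; tau' <= 0 rejected via zero prior.
    if (!fixed[3]) {
      double prop = R::rnorm(tau, f * base_scales[3]);
      if (prop > 0) {
        double la = log_prior_tau(prop, sh_t, rt_t) - log_prior_tau(tau, sh_t, rt_t)
                  + 0.5 * N * (std::log(prop) - std::log(tau))
                  - 0.5 * (prop - tau) * ss;
        if (std::log(R::runif(0, 1)) < la) { tau = prop; acc[3] += 1; }
      }
    }
    // labels | . : exact Gibbs from the full conditional. Only the residual
    // sums under each branch matter; observations at t <= c cancel.
    for (int i = 0; i < n; ++i) {
      double ss0 = 0.0, ss1 = 0.0;
      for (int j = i_start[i]; j < i_end[i]; ++j) {
        if (t[j] > c) {
          double r0 = y[j] - (alpha + beta * t[j]);
          double r1 = y[j] - ((alpha - delta * c) + (beta + delta) * t[j]);
          ss0 += r0 * r0;
          ss1 += r1 * r1;
        }
      }
      double p1;
      if (p_r <= 0.0) p1 = 0.0;
      else if (p_r >= 1.0) p1 = 1.0;
      else {
        // log odds of r_i = 1
        double lo = std::log(p_r) - std::log1p(-p_r)
                  - 0.5 * tau * (ss1 - ss0);
        p1 = 1.0 / (1.0 + std::exp(-lo));
      }
      labels[i] = (R::runif(0, 1) < p1) ? 1 : 0;
    }
    ss = rss(y, t, id0, labels, alpha, beta, delta, c);

    if (s > burn_in && (s - burn_in) % thin == 0) {
      da[kept] = alpha; db[kept] = beta; dd[kept] = delta; dt[kept] = tau;
      for (int i = 0; i < n; ++i) label_sum[i] += labels[i];
      ++kept;
    }
  }

  for (int i = 0; i < n; ++i) label_sum[i] /= n_keep;
  for (int k = 0; k < 4; ++k)
    acc[k] = fixed[k] ? NA_REAL : acc[k] / iterations;

  return List::create(
    _["alpha"] = da, _["beta"] = db, _["delta"] = dd, _["tau"] = dt,
    _["label_prob"] = label_sum, _["acceptance"] = acc);
}
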