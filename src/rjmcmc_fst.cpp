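// Reversible-jump MCMC for the Bayesian F_ST outlier model.
//
// Biallelic counts a_ij of n_ij reads in population j at locus i follow a
// beta-binomial (Dirichlet-multinomial) distribution around an ancestral
// frequency p_i with locus-by-population differentiation
//   logit F_ST(i,j) = delta_i * alpha_i + beta_j,
// i.e. theta_ij = (1 - F) / F = exp(-(delta_i * alpha_i + beta_j)).
// The locus effect alpha_i is switched in and out of the model by a
// reversible-jump move with prior odds `prior_odds` for the neutral model;
// its posterior inclusion frequency is the posterior probability that the
// locus departs from neutrality. Uses R's RNG, so results are reproducible
// under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double loglik_one(double a, double n, double p, double theta) {
  if (n <= 0.0) return 0.0;
  double tp = theta * p, tq = theta * (1.0 - p);
  // guard absorbing frequencies: likelihood defined by the limit
  if (tp <= 0.0) return (a <= 0.0) ? 0.0 : R_NegInf;
  if (tq <= 0.0) return (a >= n) ? 0.0 : R_NegInf;
  return R::lbeta(a + tp, n - a + tq) - R::lbeta(tp, tq);
}

// [[Rcpp::export(name = ".rjmcmc_fst")]]
List rjmcmc_fst(NumericMatrix alt, NumericMatrix tot,
                double prior_odds,
                int burn_in, int n_samples, int thinning,
                double alpha_prior_sd, double beta_prior_mean,
                double beta_prior_sd, double rj_sd) {
  const int I = alt.nrow(), J = alt.ncol();
  const double log_prior_odds = std::log(prior_odds);

  std::vector<double> p(I), alpha(I, 0.0);
  std::vector<int> delta(I, 0);
  std::vector<double> beta(J, beta_prior_mean);
  NumericMatrix L(I, J);       // cached per-cell log-likelihood
  std::vector<double> rowL(I); // cached per-locus sums

  // initial ancestral frequencies: pooled empirical, kept off the boundary
  for (int i = 0; i < I; ++i) {
    double a = 0.0, n = 0.0;
    for (int j = 0; j < J; ++j) { a += alt(i, j); n += tot(i, j); }
    p[i] = (a + 1.0) / (n + 2.0);
  }

  auto theta_of = [&](int i, int j) {
    return std::exp(-(delta[i] * alpha[i] + beta[j]));
  };
  auto refresh_row = [&](int i) {
    double s = 0.0;
    for (int j = 0; j < J; ++j) {
      L(i, j) = loglik_one(alt(i, j), tot(i, j), p[i], theta_of(i, j));
      s += L(i, j);
    }
    rowL[i] = s;
  };
  for (int i = 0; i < I; ++i) refresh_row(i);

  double sd_p = 0.2, sd_a = 0.5, sd_b = 0.1;
  long acc_p = 0, try_p = 0, acc_a = 0, try_a = 0, acc_b = 0, try_b = 0,
       acc_rj = 0, try_rj = 0;
  // acceptance counters after adaptation only
  long acc_p2 = 0, try_p2 = 0, acc_b2 = 0, try_b2 = 0;

  std::vector<double> pp(I, 0.0), alpha_sum(I, 0.0);
  std::vector<double> beta_sum(J, 0.0);
  int retained = 0;

  const int total_iter = burn_in + n_samples * thinning;
  std::vector<double> cand(J);

  for (int it = 0; it < total_iter; ++it) {
    const bool adapting = it < burn_in;

    // --- ancestral frequencies (reflected random walk on [0,1]) ---
    for (int i = 0; i < I; ++i) {
      double prop = p[i] + R::norm_rand() * sd_p;
      while (prop < 0.0 || prop > 1.0) {
        if (prop < 0.0) prop = -prop;
        if (prop > 1.0) prop = 2.0 - prop;
      }
      double newsum = 0.0;
      for (int j = 0; j < J; ++j) {
        cand[j] = loglik_one(alt(i, j), tot(i, j), prop, theta_of(i, j));
        newsum += cand[j];
      }
      ++try_p; if (!adapting) ++try_p2;
      if (std::log(R::unif_rand()) < newsum - rowL[i]) {
        p[i] = prop;
        for (int j = 0; j < J; ++j) L(i, j) = cand[j];
        rowL[i] = newsum;
        ++acc_p; if (!adapting) ++acc_p2;
      }
    }

    // --- locus effects (random walk, included loci only) ---
    for (int i = 0; i < I; ++i) {
      if (!delta[i]) continue;
      double prop = alpha[i] + R::norm_rand() * sd_a;
      double newsum = 0.0;
      for (int j = 0; j < J; ++j) {
        double th = std::exp(-(prop + beta[j]));
        cand[j] = loglik_one(alt(i, j), tot(i, j), p[i], th);
        newsum += cand[j];
      }
      double logr = newsum - rowL[i] +
        R::dnorm(prop, 0.0, alpha_prior_sd, 1) -
        R::dnorm(alpha[i], 0.0, alpha_prior_sd, 1);
      ++try_a;
      if (std::log(R::unif_rand()) < logr) {
        alpha[i] = prop;
        for (int j = 0; j < J; ++j) L(i, j) = cand[j];
        rowL[i] = newsum;
        ++acc_a;
      }
    }

    // --- reversible jump: toggle inclusion of each locus effect ---
    for (int i = 0; i < I; ++i) {
      ++try_rj;
      if (!delta[i]) {
        double prop = R::norm_rand() * rj_sd;  // independence birth proposal
        double newsum = 0.0;
        for (int j = 0; j < J; ++j) {
          double th = std::exp(-(prop + beta[j]));
          cand[j] = loglik_one(alt(i, j), tot(i, j), p[i], th);
          newsum += cand[j];
        }
        double logr = newsum - rowL[i] +
          R::dnorm(prop, 0.0, alpha_prior_sd, 1) -
          R::dnorm(prop, 0.0, rj_sd, 1) - log_prior_odds;
        if (std::log(R::unif_rand()) < logr) {
          delta[i] = 1; alpha[i] = prop;
          for (int j = 0; j < J; ++j) L(i, j) = cand[j];
          rowL[i] = newsum;
          ++acc_rj;
        }
      } else {
        double newsum = 0.0;
        for (int j = 0; j < J; ++j) {
          double th = std::exp(-beta[j]);
          cand[j] = loglik_one(alt(i, j), tot(i, j), p[i], th);
          newsum += cand[j];
        }
        double logr = newsum - rowL[i] +
          R::dnorm(alpha[i], 0.0, rj_sd, 1) -
          R::dnorm(alpha[i], 0.0, alpha_prior_sd, 1) + log_prior_odds;
        if (std::log(R::unif_rand()) < logr) {
          delta[i] = 0; alpha[i] = 0.0;
          for (int j = 0; j < J; ++j) L(i, j) = cand[j];
          rowL[i] = newsum;
          ++acc_rj;
        }
      }
    }

    // --- population effects ---
    for (int j = 0; j < J; ++j) {
      double prop = beta[j] + R::norm_rand() * sd_b;
      double newsum = 0.0, oldsum = 0.0;
      NumericVector col(I);
      for (int i = 0; i < I; ++i) {
        double th = std::exp(-(delta[i] * alpha[i] + prop));
        col[i] = loglik_one(alt(i, j), tot(i, j), p[i], th);
        newsum += col[i];
        oldsum += L(i, j);
      }
      double logr = newsum - oldsum +
        R::dnorm(prop, beta_prior_mean, beta_prior_sd, 1) -
        R::dnorm(beta[j], beta_prior_mean, beta_prior_sd, 1);
      ++try_b; if (!adapting) ++try_b2;
      if (std::log(R::unif_rand()) < logr) {
        beta[j] = prop;
        for (int i = 0; i < I; ++i) {
          rowL[i] += col[i] - L(i, j);
          L(i, j) = col[i];
        }
        ++acc_b; if (!adapting) ++acc_b2;
      }
    }

    // --- proposal adaptation during burn-in ---
    if (adapting && (it + 1) % 50 == 0) {
      auto tune = [](double &sd, long &acc, long &tries) {
        if (tries > 0) {
          double rate = (double)acc / tries;
          if (rate < 0.25) sd *= 0.8;
          else if (rate > 0.45) sd *= 1.25;
        }
        acc = 0; tries = 0;
      };
      tune(sd_p, acc_p, try_p);
      tune(sd_a, acc_a, try_a);
      tune(sd_b, acc_b, try_b);
      if (sd_p > 0.5) sd_p = 0.5;
    }

    // --- record thinned samples after burn-in ---
    if (!adapting && (it - burn_in + 1) % thinning == 0) {
      for (int i = 0; i < I; ++i) {
        pp[i] += delta[i];
        alpha_sum[i] += delta[i] * alpha[i];
      }
      for (int j = 0; j < J; ++j) beta_sum[j] += beta[j];
      ++retained;
    }
  }

  NumericVector pp_out(I), alpha_out(I), beta_out(J);
  for (int i = 0; i < I; ++i) {
    pp_out[i] = pp[i] / retained;
    alpha_out[i] = alpha_sum[i] / retained;
  }
  for (int j = 0; j < J; ++j) beta_out[j] = beta_sum[j] / retained;

  return List::create(
    _["pp"] = pp_out, _["alpha"] = alpha_out, _["beta"] = beta_out,
    _["retained"] = retained,
    _["acceptance"] = NumericVector::create(
      _["p"] = try_p2 ? (double)acc_p2 / try_p2 : NA_REAL,
      _["beta"] = try_b2 ? (double)acc_b2 / try_b2 : NA_REAL,
      _["rj"] = try_rj ? (double)acc_rj / try_rj : NA_REAL));
}
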