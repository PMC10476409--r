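#' Bayesian F(ST) outlier detection by reversible-jump MCMC
#'
#' Fits the Bayesian differentiation model used for F(ST) outlier scans:
#' population allele counts follow a Dirichlet-multinomial (beta-binomial for
#' biallelic loci) distribution around an ancestral frequency, with
#' locus-by-population differentiation decomposed on the logit scale into a
#' locus effect alpha_i and a population effect beta_j,
#' `logit F_ST(i,j) = alpha_i + beta_j`. A reversible-jump move switches each
#' locus effect in and out of the model with prior odds `prior_odds` in
#' favour of the neutral (no locus effect) model; the posterior probability
#' of selection at a locus is the posterior inclusion frequency of its alpha.
#'
#' The q-value of a locus is the mean of (1 - posterior probability) over
#' all loci with posterior probability at least its own — the expected false
#' discovery proportion if every locus at least as extreme were declared an
#' outlier. A locus is flagged as an outlier when its q-value is below
#' `1 / retained samples`, the finite-sample reading of "q-value of zero".
#'
#' @param alt,total Numeric matrices (loci x populations) of alternate and
#'   total allele counts; in a pooled design each replicate pool is one
#'   population.
#' @param prior_odds Prior odds for neutrality (default 1000; higher is more
#'   stringent).
#' @param mcmc List of MCMC settings: `burn_in`, `samples` (retained),
#'   `thinning`, `seed`.
#' @param alpha_prior_sd Prior SD of the locus effect (N(0, sd) when
#'   included).
#' @param beta_prior_mean,beta_prior_sd Gaussian prior of the population
#'   effects.
#' @param rj_sd SD of the independence proposal used by the reversible-jump
#'   birth move.
#' @return Object of class `fst_outlier_result`: a list with `loci` (data
#'   frame: `site_id`, `pp`, `alpha`, `q_value`, `outlier`), `beta`,
#'   `acceptance`, `retained`, `prior_odds` and the settings used.
#'   Acceptance rates outside \[0.1, 0.6\] after adaptation are reported as
#'   warnings (the reversible-jump rate is excluded: it is legitimately tiny
#'   when most loci are neutral at high prior odds).
#' @export
bayescan_outliers <- function(alt, total, prior_odds = 1000,
                              mcmc = list(burn_in = 1000, samples = 2000,
                                          thinning = 5, seed = 1),
                              alpha_prior_sd = 1, beta_prior_mean = -1,
                              beta_prior_sd = 1.8, rj_sd = 2) {
  alt <- as.matrix(alt); total <- as.matrix(total)
  if (!identical(dim(alt), dim(total))) stop("alt/total dimensions differ")
  if (ncol(alt) < 2L) stop("need at least two populations")
  if (any(alt < 0) || any(alt > total)) stop("alt counts must lie in [0, total]")
  if (prior_odds <= 0) stop("`prior_odds` must be positive")
  defaults <- list(burn_in = 1000, samples = 2000, thinning = 5, seed = 1)
  mcmc <- utils::modifyList(defaults, mcmc)
  set.seed(mcmc$seed)
  fit <- .rjmcmc_fst(alt, total, prior_odds,
                     as.integer(mcmc$burn_in), as.integer(mcmc$samples),
                     as.integer(mcmc$thinning),
                     alpha_prior_sd, beta_prior_mean, beta_prior_sd, rj_sd)
  for (mv in c("p", "beta")) {
    rate <- fit$acceptance[[mv]]
    if (!is.na(rate) && (rate < 0.1 || rate > 0.6)) {
      warning(sprintf(
        "MCMC acceptance rate for '%s' updates is %.2f (outside [0.1, 0.6]); consider longer adaptation",
        mv, rate))
    }
  }
  q <- posterior_q_values(fit$pp)
  loci <- data.frame(
    site_id = if (!is.null(rownames(alt))) rownames(alt) else as.character(seq_len(nrow(alt))),
    pp = fit$pp, alpha = fit$alpha, q_value = q,
    outlier = q < 1 / fit$retained)
  structure(list(loci = loci, beta = fit$beta, acceptance = fit$acceptance,
                 retained = fit$retained, prior_odds = prior_odds,
                 mcmc = mcmc),
            class = "fst_outlier_result")
}

#' @export
print.fst_outlier_result <- function(x, ...) {
  cat(sprintf("fst_outlier_result: %d loci, %d outliers (prior odds %g, %d retained samples)\n",
              nrow(x$loci), sum(x$loci$outlier), x$prior_odds, x$retained))
  invisible(x)
}

# q-value of a locus: mean of (1 - pp) over all loci with pp >= its own,
# ties included. Non-decreasing in (1 - pp) by construction.
posterior_q_values <- function(pp) {
  ord <- order(pp, decreasing = TRUE)
  sorted <- pp[ord]
  q_sorted <- cumsum(1 - sorted) / seq_along(sorted)
  # propagate over ties: every tied locus gets the value at the last tie
  last_of_tie <- rev(!duplicated(rev(sorted)))
  idx <- rev(cummin(rev(ifelse(last_of_tie, seq_along(sorted), length(sorted)))))
  q_sorted <- q_sorted[idx]
  out <- numeric(length(pp))
  out[ord] <- q_sorted
  out
}
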