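#' One generation of Wright-Fisher viability selection
#'
#' Deterministic selection on genotype viabilities (1+s, 1+hs, 1 for the
#' RR/RS/SS genotypes under Hardy-Weinberg proportions) followed by binomial
#' sampling of 2N gametes. Vectorized over loci: `p`, `s` and `h` may be
#' vectors of equal length (scalars recycle).
#'
#' @param p Current resistant-allele frequencies.
#' @param N Census size (breeding females); 2N gametes are sampled.
#' @param s Selection coefficient(s); 0 gives pure drift.
#' @param h Dominance of the resistant allele in viability.
#' @return Next-generation frequencies, same length as `p`.
#' @keywords internal
wf_step <- function(p, N, s = 0, h = 0.5) {
  w_rr <- 1 + s
  w_rs <- 1 + h * s
  num <- p^2 * w_rr + p * (1 - p) * w_rs
  wbar <- p^2 * w_rr + 2 * p * (1 - p) * w_rs + (1 - p)^2
  p_sel <- ifelse(wbar > 0, num / wbar, p)
  rbinom(length(p), 2L * N, p_sel) / (2 * N)
}

#' Simulate a Wright-Fisher allele-frequency trajectory
#'
#' Forward simulation of a single biallelic locus in a closed population of
#' `N` breeding females under per-generation viability selection: genotypes
#' survive with relative viabilities 1+s (RR), 1+hs (RS) and 1 (SS), and the
#' next generation is formed by binomially sampling 2N gametes from the
#' post-selection frequency. Frequencies 0 and 1 are absorbing.
#'
#' @param p0 Founder frequency of the resistant allele, in \[0, 1\].
#' @param N Census size (number of breeding females), at least 1.
#' @param s Selection coefficient (0 = neutral drift).
#' @param h Dominance coefficient of the resistant allele.
#' @param generations Number of generations to simulate.
#' @param seed Optional integer seed; given the seed the trajectory is
#'   fully reproducible.
#' @return Numeric vector of `generations + 1` frequencies starting at `p0`.
#' @examples
#' simulate_wright_fisher_locus(0.47, 300, s = 8, h = 0.6,
#'                              generations = 9, seed = 1)
#' @export
simulate_wright_fisher_locus <- function(p0, N, s = 0, h = 0.5,
                                         generations = 17, seed = NULL) {
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 < 0 || p0 > 1) {
    stop("`p0` must be a single frequency in [0, 1]")
  }
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("`N` must be a positive census size")
  }
  if (generations < 0) stop("`generations` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  traj <- numeric(generations + 1L)
  traj[1L] <- p0
  p <- p0
  if (generations > 0) {
    for (t in seq_len(generations)) {
      p <- wf_step(p, N, s, h)
      traj[t + 1L] <- p
    }
  }
  traj
}

#' Simulate many replicate Wright-Fisher trajectories at once
#'
#' Matrix-valued companion of [simulate_wright_fisher_locus()]: `n` replicate
#' populations evolve independently from the same founder frequency.
#'
#' @inheritParams simulate_wright_fisher_locus
#' @param n Number of replicate populations.
#' @return Matrix with `n` rows and `generations + 1` columns.
#' @export
simulate_wright_fisher_replicates <- function(n, p0, N, s = 0, h = 0.5,
                                              generations = 17, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rep(p0, n)
  out <- matrix(0, nrow = n, ncol = generations + 1L)
  out[, 1L] <- p
  if (generations > 0) {
    for (t in seq_len(generations)) {
      p <- wf_step(p, N, s, h)
      out[, t + 1L] <- p
    }
  }
  out
}
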