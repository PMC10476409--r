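#' Mortality proportion with a Wald 95% confidence interval
#'
#' Bioassay mortality is summarized as p = dead/exposed with the
#' normal-approximation (Wald) interval p +/- 1.96 sqrt(p(1-p)/n), clipped
#' to \[0, 1\]. At p = 0 or 1 the interval degenerates to a point, as the
#' Wald formula does.
#'
#' @param dead Number of dead individuals.
#' @param exposed Number exposed (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with `proportion`, `lower`, `upper`, `exposed`.
#'   Vectorized over `dead`/`exposed`.
#' @export
mortality_ci <- function(dead, exposed, conf_level = 0.95) {
  if (any(exposed <= 0)) stop("`exposed` must be positive")
  if (any(dead < 0 | dead > exposed)) stop("`dead` must lie in [0, exposed]")
  p <- dead / exposed
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(p * (1 - p) / exposed)
  data.frame(proportion = p,
             lower = pmax(0, p - half),
             upper = pmin(1, p + half),
             exposed = exposed)
}

# Two-sided Fisher exact p for a 2x2 table, by the conventional definition:
# the sum of probabilities of all tables (with the observed margins) no more
# likely than the observed one. A relative slack of 1e-7 guards against
# floating-point ties, matching stats::fisher.test.
fisher_exact_2x2 <- function(d1, e1, d2, e2) {
  m <- d1 + d2
  k <- max(0L, m - e2):min(e1, m)
  probs <- dhyper(k, e1, e2, m)
  obs <- dhyper(d1, e1, e2, m)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  min(1, p)
}

#' Compare two mortality proportions with Fisher's exact test
#'
#' Exact two-sided p-value for the 2x2 dead/alive x line table, defined as
#' the total probability of tables no more likely than the observed one under
#' the hypergeometric null.
#'
#' @param a,b Length-2 vectors `c(dead, exposed)` for the two groups.
#' @return The two-sided p-value in (0, 1\].
#' @examples
#' compare_mortality(c(90, 100), c(50, 100))
#' @export
compare_mortality <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  if (a[2] + b[2] == 0) stop("both groups are empty")
  if (any(c(a, b) < 0) || a[1] > a[2] || b[1] > b[2]) {
    stop("dead counts must lie in [0, exposed]")
  }
  fisher_exact_2x2(a[1], a[2], b[1], b[2])
}

#' Genotype and resistant-allele frequencies at the monitored locus
#'
#' @param x Either a character vector of genotypes (`RR`/`RS`/`SS`), e.g. a
#'   slice of a genotype table, or a named length-3 count vector
#'   `c(RR = , RS = , SS = )`.
#' @return List with `f_RR`, `f_RS`, `f_SS`, `f_R` (resistant-allele
#'   frequency, = f(RR) + f(RS)/2) and `n`.
#' @examples
#' genotype_frequencies(c(RR = 7, RS = 14, SS = 9))
#' @export
genotype_frequencies <- function(x) {
  counts <- genotype_counts(x)
  n <- sum(counts)
  if (n < 1) stop("need at least one individual")
  f <- counts / n
  list(f_RR = unname(f["RR"]), f_RS = unname(f["RS"]), f_SS = unname(f["SS"]),
       f_R = unname((2 * counts["RR"] + counts["RS"]) / (2 * n)), n = n)
}

genotype_counts <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 3L)
    if (is.null(names(x))) names(x) <- c("RR", "RS", "SS")
    if (any(x < 0)) stop("genotype counts must be non-negative")
    return(x[c("RR", "RS", "SS")])
  }
  bad <- setdiff(unique(x), c("RR", "RS", "SS"))
  if (length(bad)) stop("unknown genotype symbol(s): ", paste(bad, collapse = ", "))
  table(factor(x, levels = c("RR", "RS", "SS")))
}

#' Compare genotype distributions between two samples (Pearson Chi2)
#'
#' Plain Pearson Chi-squared test (no continuity correction) on the 2 x k
#' genotype table; genotype classes empty in both samples are dropped first,
#' so the degrees of freedom equal the number of non-empty classes minus 1.
#' Small expected counts trigger a message, not an error.
#'
#' @param a,b Genotype count triples (named `RR`, `RS`, `SS`) or genotype
#'   character vectors.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
compare_genotype_frequencies <- function(a, b) {
  ca <- genotype_counts(a); cb <- genotype_counts(b)
  if (sum(ca) == 0 || sum(cb) == 0) stop("both samples must be non-empty")
  tab <- rbind(as.numeric(ca), as.numeric(cb))
  colnames(tab) <- c("RR", "RS", "SS")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  res <- withCallingHandlers(
    chisq.test(tab, correct = FALSE),
    warning = function(w) {
      if (grepl("approximation", conditionMessage(w))) {
        message("Chi2: some expected counts are small; approximation may be rough")
        invokeRestart("muffleWarning")
      }
    })
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Summarize bioassay and genotype monitoring per generation
#'
#' Produces per-line, per-generation mortality estimates with Wald intervals,
#' Fisher-exact comparisons of each selected line against the control at the
#' same generation, genotype/allele frequencies, and Chi2 comparisons of each
#' line's genotype distribution against the control at generation 0.
#'
#' @param bioassay Bioassay table (`line`, `generation`, `insecticide`,
#'   `exposed`, `dead`).
#' @param genotypes Genotype table (`generation`, `line`, `individual`,
#'   `genotype`).
#' @param control Name of the unselected control line.
#' @return List with data frames `mortality` and `kdr`.
#' @export
phenotype_summary <- function(bioassay, genotypes, control = "control") {
  mort <- cbind(bioassay,
                mortality_ci(bioassay$dead, bioassay$exposed)[c("proportion", "lower", "upper")])
  mort$p_vs_control <- NA_real_
  for (i in seq_len(nrow(mort))) {
    if (mort$line[i] == control) next
    ref <- mort[mort$line == control & mort$generation == mort$generation[i] &
                  mort$insecticide == mort$insecticide[i], , drop = FALSE]
    if (nrow(ref)) {
      mort$p_vs_control[i] <- compare_mortality(
        c(mort$dead[i], mort$exposed[i]), c(ref$dead[1], ref$exposed[1]))
    }
  }
  base <- genotypes[genotypes$line == control &
                      genotypes$generation == min(genotypes$generation), ]
  kdr <- do.call(rbind, lapply(
    split(genotypes, genotypes[c("generation", "line")], drop = TRUE),
    function(g) {
      fr <- genotype_frequencies(g$genotype)
      cmp <- compare_genotype_frequencies(g$genotype, base$genotype)
      data.frame(line = g$line[1], generation = g$generation[1],
                 n = fr$n, f_RR = fr$f_RR, f_RS = fr$f_RS, f_SS = fr$f_SS,
                 f_R = fr$f_R, chi2 = cmp$statistic, df = cmp$df,
                 p_vs_g0 = cmp$p_value)
    }))
  rownames(kdr) <- NULL
  kdr <- kdr[order(kdr$line, kdr$generation), ]
  list(mortality = mort, kdr = kdr)
}
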