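#' Variant filter thresholds
#'
#' Hard quality filters applied to called transcript variants before the
#' selection scans: homopolymer context, per-sample coverage window, minimum
#' variant-supporting reads, base quality, caller confidence and strand bias,
#' plus the minimum between-line frequency shift defining the polymorphism
#' screen. Confidence and strand-bias values are treated as opaque scores on
#' the scale the caller reported.
#'
#' @param max_hrun Maximum homopolymer run length at/adjacent to the site.
#' @param min_depth,max_depth Coverage window, evaluated per sample: a record
#'   must satisfy it in every sample entering the analysis.
#' @param min_alt_reads Minimum reads supporting the variant allele (in the
#'   best-supported sample).
#' @param min_base_quality Minimum mean base quality.
#' @param min_confidence Minimum variant confidence score.
#' @param max_strand_bias Maximum strand-bias score.
#' @param min_delta Minimum absolute between-line frequency difference for
#'   the polymorphism screen (see [select_polymorphic()]).
#' @return A list of thresholds, class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_hrun = 4, min_depth = 30, max_depth = 5000,
                              min_alt_reads = 2, min_base_quality = 20,
                              min_confidence = 200, max_strand_bias = 25,
                              min_delta = 0.05) {
  th <- list(max_hrun = max_hrun, min_depth = min_depth, max_depth = max_depth,
             min_alt_reads = min_alt_reads,
             min_base_quality = min_base_quality,
             min_confidence = min_confidence,
             max_strand_bias = max_strand_bias, min_delta = min_delta)
  if (any(unlist(th) < 0)) stop("thresholds must be non-negative")
  if (th$min_depth > th$max_depth) stop("min_depth must not exceed max_depth")
  structure(th, class = "filter_thresholds")
}

#' Quality-filter a variant table
#'
#' A record is kept iff its homopolymer run length is at most `max_hrun`
#' (runs longer than that, and sites adjacent to them, are annotated with the
#' run length and rejected), its total depth lies within
#' \[`min_depth`, `max_depth`\] in every sample, at least `min_alt_reads`
#' reads support the variant allele, and base quality, confidence and strand
#' bias pass their thresholds. Only substitutions and indels are retained.
#' Rules are conjunctive, so the retained set is independent of the order
#' they are applied in; each rule's rejection count is tallied independently.
#'
#' @param vt A [variant_table()].
#' @param thresholds A [filter_thresholds()].
#' @return List with `variants` (the filtered table), `rejections` (named
#'   per-rule counts), `n_input` and `n_kept`.
#' @export
filter_variants <- function(vt, thresholds = filter_thresholds()) {
  stopifnot(inherits(vt, "variant_table"))
  th <- thresholds
  s <- vt$sites
  if (anyNA(s[c("bq", "vcs", "sb", "hrun")])) {
    stop("missing quality annotation (BQ/VCS/SB/HRUN) on some records")
  }
  depth <- vt$ref_depth + vt$alt_depth
  depth[s$multiallelic, ] <- depth[s$multiallelic, , drop = FALSE] +
    ifelse(is.na(vt$alt2_depth[s$multiallelic, , drop = FALSE]), 0L,
           vt$alt2_depth[s$multiallelic, , drop = FALSE])
  pass <- cbind(
    type = s$type %in% c("substitution", "indel"),
    homopolymer = s$hrun <= th$max_hrun,
    coverage = rowSums(depth >= th$min_depth & depth <= th$max_depth) == ncol(depth),
    alt_support = apply(vt$alt_depth, 1L, max) >= th$min_alt_reads,
    base_quality = s$bq >= th$min_base_quality,
    confidence = s$vcs >= th$min_confidence,
    strand_bias = s$sb <= th$max_strand_bias
  )
  keep <- rowSums(pass) == ncol(pass)
  rejections <- colSums(!pass)
  list(variants = subset_variants(vt, keep), rejections = rejections,
       n_input = nrow(s), n_kept = sum(keep))
}

#' Per-sample and per-line alternate-allele frequencies
#'
#' f = alt / (ref + alt) per sample, missing where the site has zero depth in
#' that sample; line means average the non-missing replicate pools. Loci for
#' which a whole line is missing are counted and reported.
#'
#' @param vt A [variant_table()].
#' @param design Data frame with `sample`, `line`, `replicate` matching the
#'   table's samples.
#' @return List of class `frequency_table`: `freq` (records x samples),
#'   `line_means` (records x lines), `design`, and `n_line_missing`, the
#'   per-line count of loci with no usable replicate.
#' @export
allele_frequencies <- function(vt, design) {
  stopifnot(inherits(vt, "variant_table"))
  design <- design[match(vt$samples, design$sample), , drop = FALSE]
  if (anyNA(design$sample)) stop("design must cover every sample in the table")
  depth <- vt$ref_depth + vt$alt_depth
  f <- ifelse(depth > 0, vt$alt_depth / depth, NA_real_)
  dimnames(f) <- list(vt$sites$site_id, vt$samples)
  lines <- unique(design$line)
  line_means <- vapply(lines, function(l) {
    cols <- which(design$line == l)
    rowMeans(f[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(f)))
  if (is.null(dim(line_means))) {
    line_means <- matrix(line_means, nrow = 1,
                         dimnames = list(vt$sites$site_id[1], lines))
  }
  line_means[is.nan(line_means)] <- NA_real_
  n_missing <- colSums(is.na(line_means))
  structure(list(freq = f, line_means = line_means, design = design,
                 n_line_missing = n_missing),
            class = "frequency_table")
}

#' Biallelic polymorphic SNP screen
#'
#' Keeps biallelic records whose line-mean allele frequency differs from the
#' control line by at least `min_delta` (inclusive) in at least one selected
#' line.
#'
#' @param vt A filtered [variant_table()].
#' @param freqs The matching [allele_frequencies()] result.
#' @param control Name of the control line.
#' @param min_delta Minimum |line mean - control mean| (default 0.05).
#' @return List with `variants` (the polymorphic subset), `index` (logical
#'   over input records) and `max_delta` (per kept record).
#' @export
select_polymorphic <- function(vt, freqs, control = "control",
                               min_delta = 0.05) {
  lm <- freqs$line_means
  if (!(control %in% colnames(lm))) stop("control line not in frequency table")
  selected <- setdiff(colnames(lm), control)
  delta <- abs(lm[, selected, drop = FALSE] - lm[, control])
  max_delta <- apply(delta, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  keep <- !vt$sites$multiallelic & !is.na(max_delta) & max_delta >= min_delta
  list(variants = subset_variants(vt, keep), index = keep,
       max_delta = max_delta[keep])
}

#' Replicate-frequency-shift test for differential SNPs
#'
#' Compares each locus's allele frequency between one selected line and the
#' control across replicate pools with a two-sided pooled-variance Student
#' t-test (df = n1 + n2 - 2), Benjamini-Hochberg corrected across loci. A
#' locus is flagged as a differential SNP when the mean frequency shift is at
#' least `delta_threshold` in either direction and the adjusted p-value is at
#' most `p_threshold`. When the within-group variance is exactly zero the
#' limiting p-value is used (0 if the means differ, 1 otherwise). Loci with
#' fewer than two usable replicates on either side are excluded and counted.
#'
#' @param freqs An [allele_frequencies()] result.
#' @param selected,control Line names to contrast.
#' @param delta_threshold Minimum |mean frequency shift| (default 0.5).
#' @param p_threshold Maximum BH-adjusted p (default 0.001).
#' @param welch Use Welch's unequal-variance t instead of the pooled form.
#' @return Data frame per locus: `site_id`, `delta_f`, `t`, `df`, `p`,
#'   `padj`, `differential`; attribute `n_excluded` counts dropped loci.
#' @export
differential_snp_test <- function(freqs, selected, control = "control",
                                  delta_threshold = 0.5, p_threshold = 0.001,
                                  welch = FALSE) {
  stopifnot(inherits(freqs, "frequency_table"))
  x <- freqs$freq[, freqs$design$line == selected, drop = FALSE]
  y <- freqs$freq[, freqs$design$line == control, drop = FALSE]
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- apply(x, 1L, var, na.rm = TRUE)
  v2 <- apply(y, 1L, var, na.rm = TRUE)
  ok <- n1 >= 2L & n2 >= 2L
  delta <- m1 - m2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  tstat <- ifelse(se2 > 0, delta / sqrt(se2), ifelse(delta == 0, 0, Inf * sign(delta)))
  p <- ifelse(se2 > 0, 2 * pt(-abs(tstat), df), ifelse(delta == 0, 1, 0))
  tstat[!ok] <- NA; p[!ok] <- NA; delta[!ok] <- NA
  padj <- rep(NA_real_, length(p))
  padj[ok] <- bh_adjust(p[ok])
  out <- data.frame(site_id = rownames(freqs$freq), delta_f = delta,
                    t = tstat, df = ifelse(ok, df, NA), p = p, padj = padj,
                    differential = !is.na(padj) & abs(delta) >= delta_threshold &
                      padj <= p_threshold)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Moment estimator of F(ST) at one locus
#'
#' Two-allele, multi-population estimator from the decomposition of the
#' frequency variance: with sample-size weights w_j, F(ST) =
#' sum_j w_j (p_j - pbar)^2 / (pbar (1 - pbar)), clipped to \[0, 1\]; 0 when
#' the pooled frequency is monomorphic. A diagnostic companion to the
#' Bayesian outlier model, not a substitute for it.
#'
#' @param alt,total Vectors of alternate and total allele counts, one entry
#'   per population.
#' @return F(ST) in \[0, 1\].
#' @export
fst_estimate <- function(alt, total) {
  stopifnot(length(alt) == length(total))
  use <- total > 0
  if (sum(use) < 2L) stop("need at least two populations with non-zero totals")
  alt <- alt[use]; total <- total[use]
  if (any(alt < 0 | alt > total)) stop("alt counts must lie in [0, total]")
  p <- alt / total
  w <- total / sum(total)
  pbar <- sum(w * p)
  den <- pbar * (1 - pbar)
  if (den == 0) return(0)
  min(1, max(0, sum(w * (p - pbar)^2) / den))
}

#' Build per-pool allele-count matrices for one contrast
#'
#' Each replicate pool of the selected and control lines becomes one
#' population; read counts are used directly as allele counts. Optionally the
#' counts are downscaled to an effective pool size of `2 * pool_size`
#' chromosomes, since read depth can exceed the number of chromosomes in the
#' pool.
#'
#' @param vt A [variant_table()] (typically the polymorphic subset).
#' @param design Sample design (`sample`, `line`, `replicate`).
#' @param selected,control Line names to contrast.
#' @param effective_pool Apply the effective-pool-size downscaling.
#' @param pool_size Individuals per pool (used only when `effective_pool`).
#' @return List with integer matrices `alt` and `total` (loci x pools) and
#'   the pool sample names.
#' @export
contrast_allele_counts <- function(vt, design, selected, control = "control",
                                   effective_pool = FALSE, pool_size = 30) {
  design <- design[match(vt$samples, design$sample), , drop = FALSE]
  cols <- which(design$line %in% c(selected, control))
  if (!length(cols)) stop("no samples for the requested contrast")
  alt <- vt$alt_depth[, cols, drop = FALSE]
  total <- alt + vt$ref_depth[, cols, drop = FALSE]
  if (effective_pool) {
    n_eff <- pmin(total, 2L * pool_size)
    alt <- ifelse(total > 0, as.integer(round(alt * n_eff / total)), 0L)
    total <- n_eff
  }
  rownames(alt) <- rownames(total) <- vt$sites$site_id
  list(alt = alt, total = total, samples = vt$samples[cols])
}
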