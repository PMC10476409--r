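#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over genes with positive
#' counts in every sample, of the ratio of the gene's count to its geometric
#' mean across samples. Factors are returned as such, with no re-centering,
#' so multiplying one sample's counts by c multiplies its factor by c.
#'
#' @param counts A [count_matrix()] or a plain numeric matrix (genes x
#'   samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  log_geomean <- rowMeans(log(m))
  use <- is.finite(log_geomean)
  if (!any(use)) stop("no gene has positive counts in all samples")
  sf <- apply(m[use, , drop = FALSE], 2L, function(col) {
    exp(median(log(col) - log_geomean[use]))
  })
  sf
}

#' Coverage filter: genes expressed in every replicate
#'
#' A gene is retained iff its raw coverage, count x 1000 / length, reaches
#' `min_rate` reads per kb in every sample (the bound is inclusive).
#'
#' @param cm A [count_matrix()].
#' @param min_rate Minimum reads/kb required in all samples (default 4).
#' @return Character vector of retained gene identifiers.
#' @export
filter_by_coverage <- function(cm, min_rate = 4) {
  stopifnot(inherits(cm, "count_matrix"))
  rate <- cm$counts * 1000 / cm$lengths
  rownames(cm$counts)[rowSums(rate >= min_rate) == ncol(cm$counts)]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: monotone and capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Vectorized one-way ANOVA + Tukey HSD contrasts on a matrix of responses
# (rows = genes). Returns per-row F statistic, ANOVA p, and for each requested
# pair of groups the Tukey HSD p from the studentized-range distribution with
# the pooled within-group df. Rows with zero within-group variance follow the
# limiting behaviour: p = 1 when the contrasted means are equal, else p = 0.
anova_tukey_rows <- function(x, groups, pairs) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n_tot <- length(groups)
  idx <- split(seq_along(groups), groups)
  n_g <- lengths(idx)
  if (any(n_g < 2L)) stop("need at least 2 replicates in every group")
  means <- vapply(idx, function(j) rowMeans(x[, j, drop = FALSE]),
                  numeric(nrow(x)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1, dimnames = list(NULL, names(idx)))
  grand <- rowMeans(x)
  ssb <- as.vector(means^2 %*% n_g) - n_tot * grand^2
  sst <- rowSums(x^2) - n_tot * grand^2
  ssw <- pmax(0, sst - ssb)
  df_b <- k - 1L
  df_w <- n_tot - k
  msw <- ssw / df_w
  f <- ifelse(msw > 0, (ssb / df_b) / msw,
              ifelse(ssb > 1e-12, Inf, 0))
  p_f <- ifelse(is.finite(f), pf(f, df_b, df_w, lower.tail = FALSE),
                0)
  p_f[f == 0 & msw == 0] <- 1
  tukey <- lapply(pairs, function(pr) {
    d <- abs(means[, pr[1]] - means[, pr[2]])
    se <- sqrt(msw / 2 * unname(1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    q <- ifelse(se > 0, d / se, Inf)
    p <- ifelse(se > 0, ptukey(q, k, df_w, lower.tail = FALSE),
                ifelse(d > 1e-12, 0, 1))
    p
  })
  names(tukey) <- vapply(pairs, paste, "", collapse = ".")
  list(f = f, p_anova = p_f, tukey = tukey, df_w = df_w,
       means = means)
}

#' Differential transcription between selected lines and the control
#'
#' Counts are normalized by median-of-ratios size factors; each gene is
#' tested with a one-way ANOVA across lines on log2(normalized + 1), followed
#' by Tukey HSD contrasts of each selected line against the control, with
#' Benjamini-Hochberg correction applied per contrast across all tested
#' genes. Fold-changes are ratios of normalized (non-log) group means, > 1
#' meaning over-transcription in the selected line.
#'
#' @param cm A [count_matrix()], typically pre-filtered with
#'   [filter_by_coverage()].
#' @param control Name of the control line.
#' @return Data frame with one row per (gene, contrast): `gene_id`, `line`,
#'   `fc`, `log2fc`, `f_stat`, `p_anova`, `p`, `padj`. Size factors are
#'   attached as attribute `size_factors`.
#' @export
differential_transcription <- function(cm, control = "control") {
  stopifnot(inherits(cm, "count_matrix"))
  lines <- unique(cm$samples$line)
  if (!(control %in% lines)) stop("control line '", control, "' not in design")
  if (length(lines) < 2L) stop("need at least two lines")
  reps <- table(cm$samples$line)
  if (any(reps < 2L)) stop("need at least 2 replicates per line")
  sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2L, sf, "/")
  logn <- log2(norm + 1)
  selected <- setdiff(lines, control)
  pairs <- lapply(selected, function(s) c(s, control))
  at <- anova_tukey_rows(logn, cm$samples$line, pairs)
  # group means on the normalized (non-log) scale for fold-changes
  idx <- split(seq_len(ncol(norm)), cm$samples$line)
  raw_means <- vapply(idx, function(j) rowMeans(norm[, j, drop = FALSE]),
                      numeric(nrow(norm)))
  if (is.null(dim(raw_means))) {
    raw_means <- matrix(raw_means, nrow = 1, dimnames = list(NULL, names(idx)))
  }
  out <- do.call(rbind, lapply(seq_along(selected), function(i) {
    s <- selected[i]
    fc <- ifelse(raw_means[, control] > 0, raw_means[, s] / raw_means[, control],
                 ifelse(raw_means[, s] > 0, Inf, 1))
    p <- at$tukey[[i]]
    data.frame(gene_id = rownames(cm$counts), line = s,
               fc = fc, log2fc = log2(fc),
               f_stat = at$f, p_anova = at$p_anova,
               p = p, padj = bh_adjust(p))
  }))
  rownames(out) <- NULL
  attr(out, "size_factors") <- sf
  out
}

#' Call differentially transcribed genes and partition them across lines
#'
#' A gene is called `over` in a contrast when its fold-change is at least
#' `fc_threshold` and its adjusted p-value at most `p_threshold`; `under`
#' when the fold-change is at most `1/fc_threshold` at the same p bound
#' (1.5-fold in either direction). Both bounds are inclusive. The overlap
#' partition splits called genes per direction into line-specific and shared
#' sets.
#'
#' @param de Result of [differential_transcription()].
#' @param fc_threshold Fold-change bound (default 1.5).
#' @param p_threshold Adjusted-p bound (default 0.005).
#' @return List with `calls` (the input plus a `call` column) and
#'   `partition`, a per-direction list of line-specific and shared gene sets.
#' @export
call_de <- function(de, fc_threshold = 1.5, p_threshold = 0.005) {
  stopifnot(all(c("gene_id", "line", "fc", "padj") %in% names(de)))
  call <- rep("none", nrow(de))
  sig <- !is.na(de$padj) & de$padj <= p_threshold
  call[sig & de$fc >= fc_threshold] <- "over"
  call[sig & de$fc <= 1 / fc_threshold] <- "under"
  de$call <- call
  lines <- unique(de$line)
  partition <- lapply(c(over = "over", under = "under"), function(dir) {
    sets <- lapply(lines, function(l) de$gene_id[de$line == l & de$call == dir])
    names(sets) <- lines
    shared <- if (length(sets) > 1L) Reduce(intersect, sets) else character(0)
    specific <- lapply(sets, setdiff, y = shared)
    names(specific) <- paste0("specific_", lines)
    c(specific, list(shared = shared))
  })
  list(calls = de, partition = partition)
}

#' Term over-representation by one-sided Fisher exact test
#'
#' For each annotation term, tests whether the gene list contains more term
#' members than expected from the universe (hypergeometric upper tail). Terms
#' with fewer than `min_genes` list members are suppressed regardless of
#' significance.
#'
#' @param gene_list Character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param universe Character vector of all detected genes.
#' @param term_map Data frame with columns `term` and `gene`.
#' @param min_genes Minimum number of list genes a term must hit (default 5).
#' @param p_threshold Enrichment call threshold (strict, default 0.05).
#' @return Data frame with one row per reported term: `term`, `n_list`,
#'   `n_universe`, `fold_enrichment`, `p`, `enriched`.
#' @export
enrich_terms <- function(gene_list, universe, term_map, min_genes = 5,
                         p_threshold = 0.05) {
  if (!length(universe)) stop("`universe` is empty")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (length(setdiff(gene_list, universe))) {
    stop("`gene_list` must be a subset of `universe`")
  }
  empty <- data.frame(term = character(0), n_list = integer(0),
                      n_universe = integer(0), fold_enrichment = numeric(0),
                      p = numeric(0), enriched = logical(0))
  if (!length(gene_list)) return(empty)
  term_map <- term_map[term_map$gene %in% universe, , drop = FALSE]
  n_u <- length(universe)
  n_l <- length(gene_list)
  rows <- lapply(split(term_map$gene, term_map$term), function(genes) {
    genes <- unique(genes)
    k_univ <- length(genes)
    k_list <- sum(genes %in% gene_list)
    if (k_list < min_genes) return(NULL)
    p <- phyper(k_list - 1, k_univ, n_u - k_univ, n_l, lower.tail = FALSE)
    data.frame(n_list = k_list, n_universe = k_univ,
               fold_enrichment = (k_list / n_l) / (k_univ / n_u), p = p)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(empty)
  out <- cbind(term = names(rows)[keep], do.call(rbind, rows[keep]))
  out$enriched <- out$p < p_threshold
  rownames(out) <- NULL
  out[order(out$p), ]
}

#' Candidate-family panel of differentially transcribed genes
#'
#' Restricts DE calls to the gene families classically screened for
#' insecticide resistance (see [candidate_families()]) and reports the
#' per-line log2 fold-changes of every candidate gene called in at least one
#' line.
#'
#' @param calls The `calls` element of [call_de()].
#' @param models A [gene_model_set()] providing family tags.
#' @return Data frame with `gene_id`, `family`, `line`, `fc`, `log2fc`,
#'   `call`, restricted to candidate-family genes called in some line.
#' @export
candidate_panel <- function(calls, models) {
  stopifnot(inherits(models, "gene_model_set"))
  fam <- setNames(models$genes$family, models$genes$gene_id)
  calls$family <- unname(fam[calls$gene_id])
  called_genes <- unique(calls$gene_id[calls$call != "none"])
  keep <- calls$gene_id %in% called_genes &
    calls$family %in% candidate_families()
  out <- calls[keep, c("gene_id", "family", "line", "fc", "log2fc", "call")]
  out <- out[order(out$family, out$gene_id, out$line), ]
  rownames(out) <- NULL
  out
}

#' Heat-map style figure of the candidate panel
#'
#' @param panel Result of [candidate_panel()].
#' @param file Optional output path (written with `ggplot2::ggsave`).
#' @return The ggplot object, invisibly.
#' @export
plot_candidate_panel <- function(panel, file = NULL) {
  if (!nrow(panel)) stop("empty candidate panel")
  panel$star <- ifelse(panel$call != "none", "*", "")
  gp <- ggplot2::ggplot(panel, ggplot2::aes(
    x = .data$line, y = .data$gene_id, fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::facet_grid(family ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC")
  if (!is.null(file)) ggplot2::ggsave(file, gp, width = 5,
                                      height = 2 + 0.12 * length(unique(panel$gene_id)))
  invisible(gp)
}
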