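#' Per-gene proportions of differential and outlier SNPs
#'
#' Aggregates the polymorphic SNPs of one contrast per host gene: the
#' proportion of differential SNPs (replicate frequency-shift test) and of
#' Bayesian F(ST) outlier SNPs among the gene's polymorphic SNPs, plotted at
#' the gene's center coordinate. Genes without polymorphic SNPs are omitted.
#' The "high" flags mark proportions strictly above `high_threshold`.
#'
#' @param diff Result of [differential_snp_test()] for the contrast.
#' @param outliers An `fst_outlier_result` for the same loci (or a subset:
#'   loci missing from it contribute no outlier evidence).
#' @param assignment SNP-to-gene assignment from [annotate_effects()].
#' @param models A [gene_model_set()].
#' @param high_threshold Proportion above which the high flag is set
#'   (strict; default 0.20).
#' @return Data frame of class `scan_rows`, one row per gene carrying
#'   polymorphic SNPs: `gene_id`, `chrom`, `center`, `n_polymorphic`,
#'   `n_differential`, `n_outlier`, `prop_differential`, `prop_outlier`,
#'   `dual_evidence`, `high_differential`, `high_outlier`, `family`.
#' @export
per_gene_proportions <- function(diff, outliers, assignment, models,
                                 high_threshold = 0.20) {
  stopifnot(inherits(models, "gene_model_set"))
  gene_of <- setNames(assignment$gene_id, assignment$site_id)
  unknown <- setdiff(stats::na.omit(unname(gene_of[diff$site_id])),
                     models$genes$gene_id)
  if (length(unknown)) stop("SNP mapped to unknown gene: ", unknown[1])
  d <- data.frame(site_id = diff$site_id,
                  gene_id = unname(gene_of[diff$site_id]),
                  differential = diff$differential %in% TRUE)
  out_flag <- setNames(outliers$loci$outlier, outliers$loci$site_id)
  d$outlier <- unname(out_flag[d$site_id]) %in% TRUE
  d <- d[!is.na(d$gene_id), , drop = FALSE]
  if (!nrow(d)) {
    return(structure(data.frame(), class = c("scan_rows", "data.frame")))
  }
  agg <- do.call(rbind, lapply(split(d, d$gene_id), function(x) {
    data.frame(gene_id = x$gene_id[1], n_polymorphic = nrow(x),
               n_differential = sum(x$differential),
               n_outlier = sum(x$outlier))
  }))
  g <- models$genes
  m <- match(agg$gene_id, g$gene_id)
  agg$chrom <- g$chrom[m]
  agg$center <- (g$start[m] + g$end[m]) / 2
  agg$prop_differential <- agg$n_differential / agg$n_polymorphic
  agg$prop_outlier <- agg$n_outlier / agg$n_polymorphic
  agg$dual_evidence <- agg$n_differential >= 1L & agg$n_outlier >= 1L
  agg$high_differential <- agg$prop_differential > high_threshold
  agg$high_outlier <- agg$prop_outlier > high_threshold
  agg$family <- g$family[m]
  agg <- agg[order(agg$chrom, agg$center),
             c("gene_id", "chrom", "center", "n_polymorphic",
               "n_differential", "n_outlier", "prop_differential",
               "prop_outlier", "dual_evidence", "high_differential",
               "high_outlier", "family")]
  rownames(agg) <- NULL
  structure(agg, class = c("scan_rows", "data.frame"))
}

#' Dual-evidence genes and their cross-contrast intersection
#'
#' A dual-evidence gene carries at least one differential SNP and at least
#' one F(ST) outlier SNP in the same contrast. With selection acting on
#' different loci in each selected line, the intersection across contrasts is
#' expected to be (near) empty.
#'
#' @param rows_by_contrast Named list of [per_gene_proportions()] results,
#'   one per contrast.
#' @return List with `per_contrast` (named list of gene-id vectors),
#'   `shared` (intersection across all contrasts) and `shared_candidates`
#'   (its candidate-family subset).
#' @export
dual_evidence_genes <- function(rows_by_contrast) {
  sets <- lapply(rows_by_contrast, function(r) {
    if (!nrow(r)) character(0) else sort(r$gene_id[r$dual_evidence])
  })
  shared <- if (length(sets)) sort(Reduce(intersect, sets)) else character(0)
  fams <- do.call(rbind, lapply(rows_by_contrast, function(r) {
    if (nrow(r)) r[c("gene_id", "family")] else NULL
  }))
  shared_cand <- if (length(shared) && !is.null(fams)) {
    fam <- fams$family[match(shared, fams$gene_id)]
    shared[fam %in% candidate_families()]
  } else character(0)
  list(per_contrast = sets, shared = shared, shared_candidates = shared_cand)
}

#' Mirrored genome-scan figure
#'
#' Per-chromosome scatter of per-gene selection-signature proportions at gene
#' centers: differential-SNP proportions on the upper axis, F(ST)-outlier
#' proportions mirrored on the lower axis. Symbol size is proportional to the
#' number of polymorphic SNPs in the gene, candidate-family genes are drawn
#' as triangles, and genes whose proportion exceeds the high threshold are
#' colour-marked. Axis ticks are placed every 10 Mb.
#'
#' @param rows A [per_gene_proportions()] result.
#' @param title Optional plot title.
#' @param file Optional output file (SVG/PNG/PDF by extension, via
#'   `ggplot2::ggsave`).
#' @return The ggplot object, invisibly.
#' @export
plot_genome_scan <- function(rows, title = NULL, file = NULL) {
  if (!nrow(rows)) stop("no genes to plot")
  upper <- data.frame(rows, y = rows$prop_differential, axis = "differential",
                      high = rows$high_outlier)
  lower <- data.frame(rows, y = -rows$prop_outlier, axis = "outlier",
                      high = rows$high_differential)
  dat <- rbind(upper, lower)
  dat$candidate <- dat$family %in% candidate_families()
  gp <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$center, y = .data$y, size = .data$n_polymorphic,
    shape = .data$candidate, colour = .data$high)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-0.2, 0.2), linetype = "dashed",
                        linewidth = 0.2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::scale_x_continuous(
      breaks = function(lim) seq(0, max(lim), by = 1e7),
      labels = function(x) sprintf("%g", x / 1e6)) +
    ggplot2::labs(x = "position (Mb)",
                  y = "outlier prop.  <-  ->  differential prop.",
                  title = title, size = "polymorphic SNPs",
                  shape = "candidate family", colour = "high with other approach") +
    ggplot2::theme_bw()
  if (!is.null(file)) ggplot2::ggsave(file, gp, width = 10, height = 4)
  invisible(gp)
}

#' Collate a full-run summary report
#'
#' Gathers the counts every stage produced (genes tested and called per line,
#' SNPs filtered / polymorphic / differential / outlier, dual-evidence and
#' shared genes) together with the thresholds, configuration and seeds used,
#' and — when simulation truth is available — a recovery table marking every
#' truly selected locus and planted DE gene as detected or missed.
#'
#' @param pipeline Result of [run_selection_scan()].
#' @param truth Optional truth ledger from a [simulate_experiment()] bundle.
#' @return A list (class `scan_report`) serializable to JSON with
#'   [write_report()].
#' @export
report <- function(pipeline, truth = NULL) {
  pl <- pipeline
  de_counts <- lapply(setNames(pl$contrasts, pl$contrasts), function(ct) {
    calls <- pl$de$calls[pl$de$calls$line == ct, , drop = FALSE]
    list(over = sum(calls$call == "over"), under = sum(calls$call == "under"))
  })
  rep_list <- list(
    generated = list(config = unclass(pl$config_echo),
                     thresholds = pl$thresholds),
    transcriptome = list(
      genes_total = pl$n_genes_total, genes_detected = pl$n_genes_detected,
      de_calls = de_counts),
    variants = list(
      snps_input = pl$filter$n_input, snps_filtered = pl$filter$n_kept,
      rejections = as.list(pl$filter$rejections),
      snps_polymorphic = nrow(pl$polymorphic$variants$sites),
      differential = lapply(pl$diff, function(d) sum(d$differential, na.rm = TRUE)),
      outliers = lapply(pl$outliers, function(o) sum(o$loci$outlier))),
    scan = list(
      dual_evidence = lapply(pl$dual$per_contrast, length),
      shared = length(pl$dual$shared),
      shared_candidates = length(pl$dual$shared_candidates))
  )
  if (!is.null(truth)) {
    poly_ids <- pl$polymorphic$variants$sites$site_id
    sel <- truth$selected_loci
    rec_loci <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
      line <- sel$line[i]
      d <- pl$diff[[line]]
      o <- pl$outliers[[line]]
      data.frame(line = line, site_id = sel$site_id[i],
                 polymorphic = sel$site_id[i] %in% poly_ids,
                 differential = isTRUE(d$differential[match(sel$site_id[i], d$site_id)]),
                 outlier = isTRUE(o$loci$outlier[match(sel$site_id[i], o$loci$site_id)]))
    }))
    de <- truth$de_genes
    rec_de <- if (nrow(de)) {
      calls <- pl$de$calls
      data.frame(line = de$line, gene_id = de$gene, fc = de$fc,
                 detected = mapply(function(l, g) {
                   any(calls$line == l & calls$gene_id == g & calls$call != "none")
                 }, de$line, de$gene))
    } else NULL
    rep_list$recovery <- list(selected_loci = rec_loci, de_genes = rec_de)
  }
  structure(rep_list, class = "scan_report")
}

#' @rdname report
#' @param x A `scan_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @export
print.scan_report <- function(x, ...) {
  cat("Selection-scan report\n")
  cat(sprintf("  genes: %d total, %d detected\n",
              x$transcriptome$genes_total, x$transcriptome$genes_detected))
  for (ct in names(x$transcriptome$de_calls)) {
    cat(sprintf("  DE (%s): %d over, %d under\n", ct,
                x$transcriptome$de_calls[[ct]]$over,
                x$transcriptome$de_calls[[ct]]$under))
  }
  cat(sprintf("  SNPs: %d input, %d pass filters, %d polymorphic\n",
              x$variants$snps_input, x$variants$snps_filtered,
              x$variants$snps_polymorphic))
  for (ct in names(x$variants$differential)) {
    cat(sprintf("  %s: %d differential, %d outliers, %d dual-evidence genes\n",
                ct, x$variants$differential[[ct]], x$variants$outliers[[ct]],
                x$scan$dual_evidence[[ct]]))
  }
  cat(sprintf("  shared dual-evidence genes: %d (%d candidate-family)\n",
              x$scan$shared, x$scan$shared_candidates))
  invisible(x)
}
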