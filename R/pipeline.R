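#' Run the full selection-scan pipeline on a data bundle
#'
#' End-to-end analysis of one experiment: coverage filter and differential
#' transcription on the counts; quality filters, polymorphism screen, effect
#' annotation, replicate frequency-shift test and Bayesian F(ST) outlier
#' detection on the variants; then gene-level aggregation and dual-evidence
#' intersection across the selected-vs-control contrasts.
#'
#' @param bundle A [simulate_experiment()] result, or any list with elements
#'   `counts` ([count_matrix()]), `variants` ([variant_table()]), `models`
#'   ([gene_model_set()]), `genome` (`DNAStringSet`) and `design`.
#' @param control Name of the control line (default `"control"`).
#' @param de_fc,de_p DE call thresholds (fold-change, adjusted p).
#' @param snp_delta,snp_p Differential-SNP thresholds (|mean shift|,
#'   adjusted p).
#' @param thresholds Variant [filter_thresholds()].
#' @param prior_odds Prior odds for neutrality in the Bayesian outlier model.
#' @param mcmc MCMC settings passed to [bayescan_outliers()] (`seed` is
#'   combined with the contrast name so each chain has its own stream).
#' @param bayescan_max_loci Optional cap on the number of polymorphic loci
#'   entering the Bayesian stage; when exceeded, a seeded subsample of loci
#'   is analysed and the remaining loci carry no outlier evidence.
#' @return A list with every intermediate product (`de`, `filter`,
#'   `polymorphic`, `effects`, `diff`, `outliers`, `scan_rows`, `dual`, ...).
#' @export
run_selection_scan <- function(bundle, control = "control",
                               de_fc = 1.5, de_p = 0.005,
                               snp_delta = 0.5, snp_p = 0.001,
                               thresholds = filter_thresholds(),
                               prior_odds = 1000,
                               mcmc = list(burn_in = 500, samples = 2000,
                                           thinning = 1, seed = 1),
                               bayescan_max_loci = Inf) {
  cm <- bundle$counts
  design <- bundle$design
  lines <- unique(design$line)
  contrasts <- setdiff(lines, control)

  detected <- filter_by_coverage(cm)
  de <- call_de(differential_transcription(subset_genes(cm, detected),
                                           control = control),
                fc_threshold = de_fc, p_threshold = de_p)

  filt <- filter_variants(bundle$variants, thresholds)
  freqs_all <- allele_frequencies(filt$variants, design)
  poly <- select_polymorphic(filt$variants, freqs_all, control = control,
                             min_delta = thresholds$min_delta)
  freqs <- allele_frequencies(poly$variants, design)
  effects <- annotate_effects(poly$variants, bundle$models, bundle$genome)

  diff <- list(); outliers <- list(); rows <- list()
  for (ct in contrasts) {
    diff[[ct]] <- differential_snp_test(freqs, selected = ct,
                                        control = control,
                                        delta_threshold = snp_delta,
                                        p_threshold = snp_p)
    cc <- contrast_allele_counts(poly$variants, design, selected = ct,
                                 control = control)
    idx <- seq_len(nrow(cc$alt))
    if (nrow(cc$alt) > bayescan_max_loci) {
      set.seed(derive_seed(mcmc$seed %||% 1, "bayescan-subsample", ct))
      idx <- sort(sample(nrow(cc$alt), bayescan_max_loci))
    }
    mc <- mcmc
    mc$seed <- derive_seed(mcmc$seed %||% 1, "bayescan", ct)
    outliers[[ct]] <- bayescan_outliers(cc$alt[idx, , drop = FALSE],
                                        cc$total[idx, , drop = FALSE],
                                        prior_odds = prior_odds, mcmc = mc)
    rows[[ct]] <- per_gene_proportions(diff[[ct]], outliers[[ct]], effects,
                                       bundle$models)
  }
  dual <- dual_evidence_genes(rows)

  list(config_echo = bundle$config, control = control, contrasts = contrasts,
       n_genes_total = nrow(cm$counts), n_genes_detected = length(detected),
       detected_genes = detected, de = de, filter = filt,
       polymorphic = poly, freqs = freqs, effects = effects, diff = diff,
       outliers = outliers, scan_rows = rows, dual = dual,
       thresholds = list(de_fc = de_fc, de_p = de_p, snp_delta = snp_delta,
                         snp_p = snp_p, prior_odds = prior_odds,
                         filters = unclass(thresholds)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
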