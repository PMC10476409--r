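make_cm <- function(counts, lengths = NULL, design = NULL) {
  if (is.null(lengths)) lengths <- setNames(rep(1000, nrow(counts)), rownames(counts))
  if (is.null(design)) {
    design <- data.frame(sample = colnames(counts),
                         line = sub("_R\\d+$", "", colnames(counts)),
                         replicate = as.integer(sub(".*_R", "", colnames(counts))))
  }
  count_matrix(counts, lengths, design)
}

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(100, 10, 4, 200, 20, 8), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a_R1", "a_R2")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  same <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), paste0("b_R", 1:3)))
  expect_equal(unname(size_factors(same)), rep(1, 3))

  # relative scale equivariance: multiplying one sample by c multiplies the
  # ratio of its factor to any other sample's factor by c (the geometric-mean
  # reference itself absorbs c^(1/n))
  m2 <- m; m2[, 2] <- m2[, 2] * 5
  sf2 <- size_factors(m2)
  expect_equal(sf2[2] / sf2[1], (sf[2] / sf[1]) * 5)
  expect_equal(size_factors(m * 3), sf)  # invariant to a common scale

  # invariance to gene and sample permutation
  set.seed(1)
  big <- matrix(rpois(300, 50) + 1, 50, 6,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  perm <- size_factors(big[sample(50), sample(6)])
  expect_equal(perm[colnames(big)], size_factors(big))

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "no gene")
})

test_that("size factors agree with the DESeq2 reference estimator", {
  set.seed(7)
  m <- matrix(rnbinom(600, mu = 80, size = 5), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("coverage filter keeps genes at >= 4 reads/kb in every sample", {
  counts <- rbind(g1 = c(4, 4, 4, 4), g2 = c(4, 3, 4, 4), g3 = c(2, 2, 2, 2))
  colnames(counts) <- c("a_R1", "a_R2", "b_R1", "b_R2")
  cm <- make_cm(counts, lengths = c(g1 = 1000, g2 = 1000, g3 = 500))
  kept <- filter_by_coverage(cm)
  expect_true("g1" %in% kept)     # exactly 4 reads/kb, boundary inclusive
  expect_false("g2" %in% kept)    # one sample below: universal quantifier
  expect_true("g3" %in% kept)     # 2 reads / 0.5 kb = 4 reads/kb
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("vectorized ANOVA and Tukey HSD match stats::aov and TukeyHSD", {
  x <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  # hand computation: group means 2,3,11; grand 16/3
  ssb <- 3 * sum((c(2, 3, 11) - 16 / 3)^2)
  ssw <- sum((x - rep(c(2, 3, 11), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  at <- evoselect:::anova_tukey_rows(matrix(x, 1), g,
                                     list(c("a", "c"), c("b", "c")))
  expect_equal(at$f, f_hand)
  fit <- aov(x ~ g)
  expect_equal(at$f, unname(summary(fit)[[1]]$`F value`[1]))
  tk <- TukeyHSD(fit)$g
  expect_equal(at$tukey[[1]], unname(tk["c-a", "p adj"]), tolerance = 1e-8)
  expect_equal(at$tukey[[2]], unname(tk["c-b", "p adj"]), tolerance = 1e-8)

  # several random designs
  set.seed(3)
  for (i in 1:10) {
    y <- rnorm(12)
    gg <- rep(c("a", "b", "c"), each = 4)
    at2 <- evoselect:::anova_tukey_rows(matrix(y, 1), gg,
                                        list(c("a", "c"), c("b", "c")))
    fit2 <- aov(y ~ gg)
    tk2 <- TukeyHSD(fit2)$gg
    expect_equal(at2$tukey[[1]], unname(tk2["c-a", "p adj"]), tolerance = 1e-6)
    expect_equal(at2$tukey[[2]], unname(tk2["c-b", "p adj"]), tolerance = 1e-6)
  }
})

test_that("identical groups yield F = 0 and no DE calls", {
  counts <- matrix(rep(c(50L, 80L, 120L), each = 12), 3, 12, byrow = TRUE)
  rownames(counts) <- paste0("g", 1:3)
  colnames(counts) <- paste0(rep(c("control", "s1", "s2"), each = 4), "_R", 1:4)
  cm <- make_cm(counts)
  de <- differential_transcription(cm, control = "control")
  expect_true(all(de$f_stat == 0))
  expect_true(all(de$p == 1))
  expect_true(all(call_de(de)$calls$call == "none"))
})

test_that("planted two-fold changes are estimated near 2 over 200 genes", {
  cfg <- sim_config(n_genes = 2000, n_snps = 50, nb_dispersion = 0.05,
                    seed = 21)
  baseline <- setNames(rep(2000, 2000), sprintf("GENE%05d", 1:2000))
  planted <- data.frame(line = "sel1", gene = sprintf("GENE%05d", 1:200),
                        fc = 2)
  lens <- setNames(rep(1500, 2000), names(baseline))
  expr <- simulate_expression_counts(cfg, baseline, planted, lens, seed = 9)
  de <- differential_transcription(expr$cm, control = "control")
  fc_planted <- de$fc[de$line == "sel1" & de$gene_id %in% planted$gene]
  expect_true(median(fc_planted) > 1.8 && median(fc_planted) < 2.2)
})

test_that("DE calls respect both thresholds inclusively and partition overlaps", {
  de <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g1", "g5"),
    line = c("s1", "s1", "s1", "s1", "s2", "s2"),
    fc = c(1.5, 1.4, 0.6, 3.0, 2.0, 1 / 1.5),
    padj = c(0.005, 1e-9, 0.001, 0.5, 0.001, 0.005))
  out <- call_de(de)
  expect_equal(out$calls$call,
               c("over", "none", "under", "none", "over", "under"))
  expect_equal(out$partition$over$shared, "g1")
  expect_equal(out$partition$over$specific_s1, character(0))
  expect_equal(out$partition$under$specific_s1, "g3")
  expect_equal(out$partition$under$specific_s2, "g5")
})

test_that("term enrichment equals the hypergeometric tail and applies min_genes", {
  universe <- paste0("g", 1:100)
  term_map <- data.frame(term = "T1", gene = paste0("g", 1:10))
  gene_list <- paste0("g", c(1:5, 50:54))  # 5 of 10 term genes in a list of 10
  out <- enrich_terms(gene_list, universe, term_map, min_genes = 5)
  p_expect <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) / choose(100, 10)
  expect_equal(out$p, p_expect)
  expect_equal(out$n_list, 5)
  expect_true(out$enriched)

  # a term hit by only 4 list genes is suppressed regardless of p
  few <- enrich_terms(paste0("g", c(1:4, 50:55)), universe, term_map)
  expect_equal(nrow(few), 0)
  expect_equal(nrow(enrich_terms(character(0), universe, term_map)), 0)
  expect_error(enrich_terms("nope", universe, term_map), "subset")
  expect_error(enrich_terms("g1", character(0), term_map), "empty")
})

test_that("candidate panel reports called candidate-family genes with log2 FC", {
  models <- tiny_models()  # GA is P450, GB is other
  calls <- data.frame(
    gene_id = c("GA", "GB", "GA", "GB"),
    line = c("s1", "s1", "s2", "s2"),
    fc = c(2.2, 3.0, 1.0, 1.0),
    log2fc = log2(c(2.2, 3.0, 1.0, 1.0)),
    padj = c(0.001, 0.001, 0.9, 0.9),
    call = c("over", "over", "none", "none"))
  panel <- candidate_panel(calls, models)
  expect_setequal(unique(panel$gene_id), "GA")  # GB is not a candidate family
  expect_equal(panel$log2fc[panel$line == "s1"], log2(2.2), tolerance = 1e-9)
  expect_equal(round(panel$log2fc[panel$line == "s1"], 2), 1.14)
  none <- candidate_panel(transform(calls, call = "none"), models)
  expect_equal(nrow(none), 0)
})

test_that("weak 1.2-fold changes stay below the call thresholds", {
  cfg <- sim_config(n_snps = 200, seed = 55, de_fc_range = c(1.2, 1.2))
  b <- simulate_experiment(cfg)
  de <- call_de(differential_transcription(
    subset_genes(b$counts, filter_by_coverage(b$counts)),
    control = "control"))
  tr <- b$truth$de_genes
  called <- mapply(function(l, g) {
    any(de$calls$line == l & de$calls$gene_id == g & de$calls$call != "none")
  }, tr$line, tr$gene)
  expect_lte(mean(called), 0.1)
})
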