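test_that("Wright-Fisher boundaries are absorbing and inputs validated", {
  expect_equal(simulate_wright_fisher_locus(0, 300, s = 5, generations = 10,
                                            seed = 1),
               rep(0, 11))
  expect_equal(simulate_wright_fisher_locus(1, 300, s = 0, generations = 10,
                                            seed = 1),
               rep(1, 11))
  expect_length(simulate_wright_fisher_locus(0.5, 10, generations = 0), 1L)
  expect_error(simulate_wright_fisher_locus(1.2, 300), "\\[0, 1\\]")
  expect_error(simulate_wright_fisher_locus(0.5, 0), "positive")
  expect_error(simulate_wright_fisher_locus(0.5, 10, generations = -1),
               "non-negative")
})

test_that("neutral drift is a martingale with binomial variance", {
  m <- simulate_wright_fisher_replicates(2000, 0.5, 300, s = 0,
                                         generations = 17, seed = 41)
  final <- m[, 18]
  se <- sd(final) / sqrt(length(final))
  expect_lt(abs(mean(final) - 0.5), 3 * se)

  one <- simulate_wright_fisher_replicates(5000, 0.3, 300, s = 0,
                                           generations = 1, seed = 42)
  v <- var(one[, 2])
  expect_lt(abs(v / (0.3 * 0.7 / 600) - 1), 0.15)
})

test_that("default target-site selection sweeps from 0.47 past 0.9 by G7", {
  m <- simulate_wright_fisher_replicates(500, 0.47, 300, s = 8, h = 0.6,
                                         generations = 7, seed = 43)
  expect_gte(mean(m[, 8] >= 0.9), 0.9)
})

test_that("trajectories are reproducible and respect the mortality window", {
  cfg <- small_config(seed = 13)
  b1 <- simulate_experiment(cfg)
  b2 <- simulate_experiment(cfg)
  expect_identical(b1$truth$trajectories, b2$truth$trajectories)
  expect_identical(b1$counts$counts, b2$counts$counts)
  expect_identical(b1$variants$sites, b2$variants$sites)
  expect_identical(b1$variants$alt_depth, b2$variants$alt_depth)

  mort <- b1$truth$mortality
  expect_true(all(mort$mortality >= cfg$target_mortality_range[1]))
  expect_true(all(mort$mortality <= cfg$target_mortality_range[2]))
  expect_setequal(unique(mort$line), c("sel1", "sel2"))
  expect_equal(nrow(mort), 2 * cfg$n_generations)

  # genotype frequencies sum to one at every monitored generation
  for (l in cfg$line_names) {
    tr <- b1$truth$trajectories[[l]]
    expect_true(all(tr >= 0 & tr <= 1))
    expect_equal(ncol(tr), cfg$n_generations + 1L)
  }
})

test_that("zero generations leaves every line at the founder state", {
  cfg <- small_config(seed = 3, n_generations = 0)
  b <- simulate_experiment(cfg)
  for (l in cfg$line_names) {
    expect_equal(b$truth$trajectories[[l]][, 1], b$truth$founder_freq)
    expect_equal(ncol(b$truth$trajectories[[l]]), 1L)
  }
})

test_that("skipped generations evolve by drift only in selected lines", {
  cfg <- small_config(seed = 8, skip_generations = c(3L, 4L))
  b <- simulate_experiment(cfg)
  expect_false(any(b$truth$mortality$generation %in% c(3L, 4L)))
  expect_equal(nrow(b$truth$mortality), 2 * (cfg$n_generations - 2L))
})

test_that("expression counts recover planted fold-changes as dispersion shrinks", {
  cfg <- sim_config(n_genes = 150, n_snps = 50, nb_dispersion = 1e-4, seed = 2)
  baseline <- setNames(rep(5000, 150), sprintf("GENE%05d", 1:150))
  planted <- data.frame(line = "sel1", gene = names(baseline)[1:40], fc = 2)
  lens <- setNames(rep(1200, 150), names(baseline))
  expr <- simulate_expression_counts(cfg, baseline, planted, lens, seed = 6)
  norm <- sweep(expr$cm$counts, 2, expr$lib_factors[colnames(expr$cm$counts)], "/")
  sel <- rowMeans(norm[1:40, expr$cm$samples$line == "sel1"])
  ctl <- rowMeans(norm[1:40, expr$cm$samples$line == "control"])
  expect_true(all(sel / ctl > 1.9 & sel / ctl < 2.1))

  # same seed, byte-identical counts
  expr2 <- simulate_expression_counts(cfg, baseline, planted, lens, seed = 6)
  expect_identical(expr$cm$counts, expr2$cm$counts)
})

test_that("pooled allele counts couple depth to host-gene expression", {
  cfg <- small_config(seed = 17)
  b <- simulate_experiment(cfg)
  genic <- !is.na(b$snps$host_gene)
  for (j in c(1, 7)) {
    host_counts <- b$counts$counts[b$snps$host_gene[genic], j]
    depth <- (b$variants$ref_depth + b$variants$alt_depth)[genic, j]
    expect_gte(cor(host_counts, depth, method = "spearman"), 0.8)
  }
})

test_that("a fixed-absent allele never yields alternate reads", {
  cfg <- small_config(seed = 19)
  gm <- simulate_gene_models(cfg)
  snps <- simulate_snp_table(cfg, gm)
  baseline <- setNames(rep(500, cfg$n_genes), gm$models$genes$gene_id)
  de <- data.frame(line = character(0), gene = character(0), fc = numeric(0))
  expr <- simulate_expression_counts(cfg, baseline, de, gm$tx_length)
  zero <- matrix(0, nrow(snps), cfg$n_lines,
                 dimnames = list(NULL, cfg$line_names))
  vt <- sample_pooled_allele_counts(cfg, snps, zero, expr, baseline)
  expect_true(all(vt$alt_depth == 0L))
  one <- zero + 1
  vt1 <- sample_pooled_allele_counts(cfg, snps, one, expr, baseline)
  biallelic <- !snps$multiallelic
  expect_true(all(vt1$ref_depth[biallelic, ] == 0L))
})

test_that("the target-site locus is genotyped but not callable from RNA-seq", {
  cfg <- small_config(seed = 23)
  b <- simulate_experiment(cfg)
  expect_lte(b$truth$baseline_mean[b$truth$target_gene], 3)
  filt <- filter_variants(b$variants)
  expect_false(b$truth$target_site_id %in% filt$variants$sites$site_id)
  # while the genotype table still monitors it through individual genotyping
  g17 <- b$genotypes[b$genotypes$line == "sel1" &
                       b$genotypes$generation == max(b$genotypes$generation), ]
  expect_equal(nrow(g17), 30L)
  expect_gt(genotype_frequencies(g17$genotype)$f_R, 0.9)
})

test_that("founder genotype monitoring reflects the configured 47% frequency", {
  cfg <- sim_config(n_genes = 80, n_snps = 400, seed = 29)
  b <- simulate_experiment(cfg)
  g0 <- b$genotypes[b$genotypes$generation == 0, ]
  f0 <- genotype_frequencies(g0$genotype)$f_R
  expect_lt(abs(f0 - 0.47), 3 * sqrt(0.47 * 0.53 / (2 * nrow(g0))))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(pool_size = 400), "census_size")
  expect_error(sim_config(census_size = 200, n_replicate_pools = 8,
                          pool_size = 30), "without replacement")
  expect_error(sim_config(founder_target_freq = 1.3), "frequency")
  expect_error(sim_config(target_mortality_range = c(0.7, 0.5)), "increasing")
  expect_error(sim_config(planted_de = data.frame(line = "sel1", gene = "g",
                                                  fc = -2)), "positive")
  expect_error(sim_config(de_fc_range = c(2, 1)), "non-decreasing")
})
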