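test_that("variant filters apply every quoted boundary exactly", {
  dp <- function(total) matrix(as.integer(total - 10L), 1, 4)
  al <- matrix(10L, 1, 4)
  keep1 <- function(vt) filter_variants(vt)$n_kept == 1L

  expect_false(keep1(make_vt(pos = 1L, ref_depth = dp(29), alt_depth = al)))
  expect_true(keep1(make_vt(pos = 1L, ref_depth = dp(30), alt_depth = al)))
  expect_true(keep1(make_vt(pos = 1L, ref_depth = dp(5000), alt_depth = al)))
  expect_false(keep1(make_vt(pos = 1L, ref_depth = dp(5001), alt_depth = al)))

  two_alt <- make_vt(pos = 1L, ref_depth = matrix(58L, 1, 4),
                     alt_depth = matrix(2L, 1, 4))
  expect_true(keep1(two_alt))
  one_alt <- make_vt(pos = 1L, ref_depth = matrix(59L, 1, 4),
                     alt_depth = matrix(1L, 1, 4))
  expect_false(keep1(one_alt))

  expect_true(keep1(make_vt(pos = 1L, bq = 20)))
  expect_false(keep1(make_vt(pos = 1L, bq = 19.9)))
  expect_true(keep1(make_vt(pos = 1L, vcs = 200)))
  expect_false(keep1(make_vt(pos = 1L, vcs = 199)))
  expect_true(keep1(make_vt(pos = 1L, sb = 25)))
  expect_false(keep1(make_vt(pos = 1L, sb = 26)))
  expect_true(keep1(make_vt(pos = 1L, hrun = 4)))
  expect_false(keep1(make_vt(pos = 1L, hrun = 5)))
})

test_that("filter rejections are tallied per rule and order-independent", {
  vt <- make_vt(pos = c(1L, 2L, 3L, 4L),
                bq = c(35, 10, 35, 35), sb = c(5, 5, 40, 5),
                hrun = c(1, 1, 1, 6))
  res <- filter_variants(vt)
  expect_equal(res$n_kept, 1L)
  expect_equal(unname(res$rejections[c("base_quality", "strand_bias",
                                       "homopolymer")]),
               c(1, 1, 1))
  # conjunctive rules: applying any single rule then the rest retains the
  # same records as the full filter
  pre <- subset_variants(vt, vt$sites$sb <= 25)
  expect_equal(filter_variants(pre)$variants$sites$site_id,
               res$variants$sites$site_id)
  pre2 <- subset_variants(vt, vt$sites$hrun <= 4)
  expect_equal(filter_variants(pre2)$variants$sites$site_id,
               res$variants$sites$site_id)
})

test_that("allele frequencies handle zero depth and average replicates", {
  vt <- make_vt(pos = c(1L, 2L),
                ref_depth = rbind(c(30L, 30L, 24L, 21L), c(0L, 30L, 30L, 30L)),
                alt_depth = rbind(c(10L, 10L, 6L, 9L), c(0L, 10L, 10L, 10L)))
  design <- two_line_design()
  fr <- allele_frequencies(vt, design)
  expect_equal(unname(fr$freq[1, 1]), 0.25)
  expect_true(is.na(fr$freq[2, 1]))
  expect_equal(unname(fr$line_means[1, "sel1"]), 0.25)
  expect_equal(unname(fr$line_means[1, "control"]), mean(c(0.2, 0.3)))
})

test_that("polymorphism screen is inclusive at 5% and excludes multi-allelic", {
  mk <- function(sel_f, multi = FALSE) {
    ref <- matrix(as.integer(round(100 * (1 - c(sel_f, sel_f, 0.5, 0.5)))), 1)
    alt <- matrix(as.integer(round(100 * c(sel_f, sel_f, 0.5, 0.5))), 1)
    make_vt(pos = 1L, alt = if (multi) "C,G" else "C", multiallelic = multi,
            ref_depth = ref, alt_depth = alt)
  }
  design <- two_line_design()
  for (case in list(list(f = 0.55, expect = TRUE),   # delta exactly 0.05
                    list(f = 0.54, expect = FALSE))) {
    vt <- mk(case$f)
    fr <- allele_frequencies(vt, design)
    out <- select_polymorphic(vt, fr, control = "control")
    expect_equal(nrow(out$variants$sites) == 1L, case$expect)
  }
  tri <- mk(0.9, multi = TRUE)
  fr <- allele_frequencies(tri, design)
  expect_equal(nrow(select_polymorphic(tri, fr)$variants$sites), 0L)
})

test_that("differential SNP test matches the pooled t formula and its limits", {
  x <- c(0.1, 0.2, 0.15, 0.25); y <- c(0.8, 0.7, 0.9, 0.75)
  freq <- rbind(c(x, y), c(y, y), c(rep(0, 4), rep(1, 4)))
  design <- two_line_design(n_rep = 4)
  vt <- make_vt(pos = 1:3,
                ref_depth = matrix(as.integer(round(100 * (1 - freq))), 3),
                alt_depth = matrix(as.integer(round(100 * freq)), 3))
  fr <- allele_frequencies(vt, design)
  res <- differential_snp_test(fr, selected = "sel1", control = "control")

  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t[1], t_hand)
  expect_equal(res$p[1], 2 * pt(-abs(t_hand), 6))
  expect_equal(unname(t.test(x, y, var.equal = TRUE)$p.value), res$p[1])

  expect_equal(res$t[2], 0)             # identical frequency vectors
  expect_equal(res$p[2], 1)
  expect_false(res$differential[2])

  expect_equal(res$p[3], 0)             # zero pooled variance, |delta| = 1
  expect_equal(res$delta_f[3], -1)
  expect_true(res$differential[3])
})

test_that("loci with fewer than two usable replicates are excluded and counted", {
  ref <- rbind(c(0L, 0L, 0L, 30L, 30L, 30L, 30L, 30L),
               matrix(30L, 2, 8))
  alt <- rbind(c(0L, 0L, 0L, 10L, 10L, 10L, 10L, 10L),
               matrix(10L, 2, 8))
  vt <- make_vt(pos = 1:3, ref_depth = ref, alt_depth = alt)
  fr <- allele_frequencies(vt, two_line_design(n_rep = 4))
  res <- differential_snp_test(fr, "sel1")
  expect_true(is.na(res$p[1]))
  expect_equal(attr(res, "n_excluded"), 1L)
  expect_false(res$differential[1])
})

test_that("F_ST moment estimator matches its defining algebra", {
  expect_equal(fst_estimate(c(10, 10), c(20, 20)), 0)
  expect_equal(fst_estimate(c(20, 0), c(20, 20)), 1)
  # frequencies 0.2 / 0.8 with equal sizes: var = 0.09, pbar(1-pbar) = 0.25
  expect_equal(fst_estimate(c(2, 8), c(10, 10)), 0.36)
  for (n1 in c(3, 8, 12)) {
    for (a1 in 0:n1) {
      for (a2 in 0:6) {
        expect_equal(fst_estimate(c(a1, a2), c(n1, 6)),
                     brute_fst(c(a1, a2), c(n1, 6)))
      }
    }
  }
  expect_error(fst_estimate(5, 10), "two populations")
})

test_that("Bayesian outlier model flags a planted locus and is reproducible", {
  set.seed(5)
  I <- 120
  tot <- matrix(rpois(I * 8, 70), I, 8)
  p <- matrix(rep(runif(I, 0.2, 0.8), 8), I, 8)
  p[1, ] <- c(rep(0.95, 4), rep(0.05, 4))
  alt <- matrix(rbinom(I * 8, as.vector(tot), as.vector(p)), I, 8)
  rownames(alt) <- rownames(tot) <- paste0("L", seq_len(I))
  mc <- list(burn_in = 300, samples = 600, thinning = 1, seed = 3)
  # short adaptation: the convergence heuristic must speak up, never silently
  expect_warning(res <- bayescan_outliers(alt, tot, prior_odds = 1000,
                                          mcmc = mc),
                 "acceptance rate")
  expect_gt(res$loci$pp[1], 0.99)
  expect_true(res$loci$outlier[1])
  expect_lt(sum(res$loci$outlier[-1]), 3)

  res2 <- suppressWarnings(bayescan_outliers(alt, tot, prior_odds = 1000,
                                             mcmc = mc))
  expect_identical(res$loci, res2$loci)        # deterministic given seed

  # higher prior odds for neutrality cannot flag more loci (matched seeds)
  res_lo <- suppressWarnings(bayescan_outliers(alt, tot, prior_odds = 10,
                                               mcmc = mc))
  expect_lte(sum(res$loci$outlier), sum(res_lo$loci$outlier))
})

test_that("posterior q-values are non-decreasing in 1 - pp", {
  pp <- c(1, 0.9, 0.9, 0.4, 0.05, 0, 0.7)
  q <- evoselect:::posterior_q_values(pp)
  ord <- order(1 - pp)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_equal(q[1], mean(1 - 1))      # the top locus: mean over itself
  expect_equal(q[pp == 0.9][1], q[pp == 0.9][2])  # ties share a q-value
})

test_that("effective-pool downscaling caps totals at twice the pool size", {
  vt <- make_vt(pos = 1:2, ref_depth = matrix(300L, 2, 4),
                alt_depth = matrix(100L, 2, 4))
  cc <- contrast_allele_counts(vt, two_line_design(), selected = "sel1",
                               effective_pool = TRUE, pool_size = 30)
  expect_true(all(cc$total <= 60))
  expect_equal(unname(cc$alt[1, 1]), 15L)  # 100/400 of 60
})

test_that("effect annotation classifies every window and codon case", {
  models <- tiny_models()
  genome <- tiny_genome()
  mk <- function(pos, ref, alt, type = "substitution") {
    data.frame(chrom = "2R", pos = pos, ref = ref, alt = alt, type = type,
               multiallelic = FALSE)
  }
  cases <- rbind(
    mk(5106L, "A", "C"),   # GGA -> GGC, synonymous
    mk(5107L, "G", "A"),   # GCT -> ACT, non-synonymous
    mk(5112L, "G", "A"),   # TGG -> TGA, stop gained
    mk(5103L, "G", "T"),   # ATG -> ATT, start lost
    mk(5799L, "A", "C"),   # TAA -> TCA, stop lost
    mk(12895L, "T", "C"),  # minus strand: GGA -> GGG, synonymous
    mk(5601L, "A", "AGT", type = "indel"),    # 2 bp insertion: frameshift
    mk(5604L, "AAAA", "A", type = "indel"),   # 3 bp deletion: in-frame
    mk(5050L, "A", "G"),   # 5' UTR
    mk(5900L, "A", "G"),   # 3' UTR
    mk(12100L, "A", "G"),  # minus-strand 3' UTR feature
    mk(5401L, "A", "G"),   # first intron base: essential splice
    mk(5405L, "A", "G"),   # 5 bp into the intron: splice site
    mk(5450L, "A", "G"),   # mid-intron
    mk(4990L, "A", "G"),   # 11 bp 5' of GeneA: near-gene
    mk(4000L, "A", "G"),   # 1001 bp 5' of plus-strand gene: upstream
    mk(3502L, "A", "G"),   # 1499 bp 5': still upstream
    mk(6200L, "A", "G"),   # 200 bp 3' of GeneA: downstream
    mk(6050L, "A", "G"),   # 50 bp 3' of GeneA: near-gene beats downstream
    mk(9000L, "A", "G"))   # 3000 bp from either gene: intergenic
  eff <- annotate_effects(cases, models, genome)
  expect_equal(eff$effect, c(
    "synonymous-coding", "non-synonymous-coding", "stop-gained", "start-lost",
    "stop-lost", "synonymous-coding", "frameshift-coding",
    "non-synonymous-coding", "5'-UTR", "3'-UTR", "3'-UTR",
    "essential-splice-site", "splice-site", "intronic", "near-gene",
    "upstream", "upstream", "downstream", "near-gene", "intergenic"))
  expect_equal(eff$gene_id[1], "GA")
  expect_equal(eff$gene_id[6], "GB")
  expect_true(is.na(eff$gene_id[20]))

  wrong_ref <- mk(5106L, "C", "G")
  expect_error(annotate_effects(wrong_ref, models, genome), "inconsistent")
  expect_error(annotate_effects(mk(5106L, "A", "C"), models, genome = NULL),
               "genome")
})
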