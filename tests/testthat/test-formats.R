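test_that("count matrix TSV round-trips and rejects malformed counts", {
  counts <- matrix(c(3L, 8L, 0L, 12L), 2,
                   dimnames = list(c("g1", "g2"), c("a_R1", "a_R2")))
  cm <- count_matrix(counts, c(g1 = 1500, g2 = 900),
                     data.frame(sample = c("a_R1", "a_R2"), line = "a",
                                replicate = 1:2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, path)
  back <- read_counts(path)
  expect_identical(back$counts, cm$counts)
  expect_identical(back$lengths, cm$lengths)
  expect_identical(back$samples, cm$samples)

  # a literal 2x2 fixture parses to the expected integers
  lines <- c("gene_id\tlength\tx_R1\tx_R2", "gA\t1000\t5\t7", "gB\t500\t0\t2")
  fx <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, fx)
  parsed <- read_counts(fx)
  expect_equal(as.vector(parsed$counts), c(5L, 0L, 7L, 2L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlength\tx_R1", "gA\t1000\t3.7"), bad)
  expect_error(read_counts(bad), "3\\.7.*gA.*x_R1")
})

test_that("count matrix constructor enforces its invariants", {
  m <- matrix(1L, 2, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  d <- data.frame(sample = c("s1", "s2"), line = "a", replicate = 1:2)
  expect_error(count_matrix(m, c(g1 = 1, g1 = 1), d), "duplicate gene")
  m2 <- matrix(-1L, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_error(count_matrix(m2, c(g1 = 100), d), "non-negative")
  m3 <- matrix(1L, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_error(count_matrix(m3, c(g1 = 0), d), "positive")
})

test_that("VCF round-trips depths, annotations and multi-allelic flags", {
  vt <- make_vt(pos = c(100L, 200L, 300L),
                ref = c("A", "T", "G"), alt = c("C", "A,G", "GTT"),
                type = c("substitution", "substitution", "indel"),
                multiallelic = c(FALSE, TRUE, FALSE),
                ref_depth = matrix(c(30L, 40L, 50L), 3, 4),
                alt_depth = matrix(c(10L, 15L, 20L), 3, 4),
                alt2_depth = matrix(c(NA, 5L, NA), 3, 4))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  back <- read_vcf(path)
  expect_equal(back$sites$pos, vt$sites$pos)          # 1-based preserved
  expect_equal(back$sites$alt, vt$sites$alt)
  expect_equal(back$sites$multiallelic, c(FALSE, TRUE, FALSE))
  expect_equal(unname(back$ref_depth[1, 1]), 30L)
  expect_equal(unname(back$alt_depth[1, 1]), 10L)
  expect_equal(unname(back$alt2_depth[2, 1]), 5L)
  expect_equal(back$sites$bq, vt$sites$bq)
  expect_equal(back$sites$hrun, vt$sites$hrun)
  expect_equal(back$sites$type, vt$sites$type)
})

test_that("VCF reader enforces its dialect", {
  noheader <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", "2R\t5\t."),
             noheader)
  expect_error(read_vcf(noheader), "##fileformat")

  vt <- make_vt(pos = c(10L, 20L))
  ok <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, ok)
  txt <- readLines(ok)
  broken <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(txt, "2R\t99\tbroken"), broken)
  expect_error(read_vcf(broken), "line 12")

  noad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "2R\t10\t.\tA\tC\t.\t.\t.\tGT\t0/1"), noad)
  expect_error(read_vcf(noad), "AD")
})

test_that("GFF3 round-trips gene models and defaults missing families", {
  models <- tiny_models()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff(models, path)
  back <- read_gff(path)
  ord <- function(m) {
    g <- m$genes[order(m$genes$gene_id), ]
    rownames(g) <- NULL
    g
  }
  expect_equal(ord(back), ord(models))
  fe <- back$features[order(back$features$gene_id, back$features$start), ]
  fe0 <- models$features[order(models$features$gene_id, models$features$start), ]
  rownames(fe) <- rownames(fe0) <- NULL
  expect_equal(fe, fe0)

  # one-gene file without family attribute -> family "other"
  minimal <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "2R\t.\tgene\t101\t400\t.\t+\t.\tID=gX",
               "2R\t.\tmRNA\t101\t400\t.\t+\t.\tID=gX.t1;Parent=gX",
               "2R\t.\tCDS\t101\t400\t.\t+\t0\tParent=gX.t1"), minimal)
  one <- read_gff(minimal)
  expect_equal(one$genes$family, "other")
  expect_equal(one$features$type, "CDS")
  expect_equal(one$features$end - one$features$start + 1L, 300L)
})

test_that("genes with CDS length not divisible by 3 are dropped with a warning", {
  genes <- data.frame(gene_id = c("ok", "badcds"), chrom = "2R",
                      start = c(1L, 1000L), end = c(500L, 1500L),
                      strand = "+", family = "other")
  features <- data.frame(gene_id = c("ok", "badcds"), type = "CDS",
                         start = c(10L, 1010L), end = c(309L, 1310L))
  expect_warning(m <- gene_model_set(genes, features), "badcds")
  expect_equal(m$genes$gene_id, "ok")
})

test_that("YAML configuration loads and validates", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_genes = 50, n_snps = 200, pool_size = 10,
                        census_size = 100, seed = 4), path)
  cfg <- load_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 50L)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pool_size = 400, census_size = 300), bad)
  expect_error(load_config(bad), "census_size")

  unknown <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_gene = 10), unknown)
  expect_error(load_config(unknown), "unknown configuration field")
})

test_that("bioassay, genotype and term tables validate on read", {
  bio <- data.frame(line = "a", generation = 1L, insecticide = "x",
                    exposed = 100L, dead = 40L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_bioassay(bio, p)
  expect_equal(read_bioassay(p), bio)
  bad <- transform(bio, dead = 120L)
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_bioassay(p), "exposed")

  gt <- data.frame(generation = 0L, line = "a", individual = "i1",
                   genotype = "RQ")
  g <- withr::local_tempfile(fileext = ".tsv")
  write.table(gt, g, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(g), "unknown genotype")

  tm <- data.frame(term = c("T1", "T1", "T2"), gene = c("g1", "g2", "g1"))
  t <- withr::local_tempfile(fileext = ".tsv")
  write.table(tm, t, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_terms(t), tm)
})
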