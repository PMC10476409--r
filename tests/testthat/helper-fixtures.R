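# Small configurations -------------------------------------------------------

small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 60, n_snps = 300, seed = seed, ...)
}

drift_config <- function(seed = 1, n_genes = 2000, n_snps = 10000, ...) {
  sim_config(n_genes = n_genes, n_snps = n_snps, seed = seed,
             n_selected_per_line = 0, n_de_over = 0, n_de_under = 0,
             target_s = 0, target_h = 0, ...)
}

# Hand-built two-gene model fixture with a fully controlled genome ------------
#
# GeneA (+, P450): 5'UTR 5001-5100, CDS 5101-5400, intron 5401-5500,
#                  CDS 5501-5800, 3'UTR 5801-6000.
# GeneB (-, other): 3'UTR 12001-12300, CDS 12301-12900, 5'UTR 12901-13000.
tiny_models <- function() {
  genes <- data.frame(
    gene_id = c("GA", "GB"), chrom = "2R",
    start = c(5001L, 12001L), end = c(6000L, 13000L),
    strand = c("+", "-"), family = c("P450", "other"))
  features <- data.frame(
    gene_id = c("GA", "GA", "GA", "GA", "GB", "GB", "GB"),
    type = c("five_prime_UTR", "CDS", "CDS", "three_prime_UTR",
             "three_prime_UTR", "CDS", "five_prime_UTR"),
    start = c(5001L, 5101L, 5501L, 5801L, 12001L, 12301L, 12901L),
    end = c(5100L, 5400L, 5800L, 6000L, 12300L, 12900L, 13000L))
  gene_model_set(genes, features)
}

tiny_genome <- function() {
  base <- rep("A", 20000L)
  set_codon <- function(at, codon) base[at:(at + 2L)] <<- strsplit(codon, "")[[1]]
  set_codon(5101L, "ATG")  # GeneA start codon
  set_codon(5104L, "GGA")  # Gly codon (codon 2)
  set_codon(5107L, "GCT")  # Ala codon (codon 3)
  set_codon(5110L, "TGG")  # Trp codon (codon 4)
  set_codon(5798L, "TAA")  # GeneA terminal stop
  set_codon(12898L, "CAT") # GeneB start codon (revcomp ATG)
  set_codon(12895L, "TCC") # GeneB codon 2 = revcomp -> GGA (Gly)
  set_codon(12301L, "TTA") # GeneB terminal stop (revcomp TAA)
  Biostrings::DNAStringSet(c(`2R` = paste(base, collapse = "")))
}

# Variant-table builder with all-passing annotations by default --------------

make_vt <- function(chrom = "2R", pos, ref = "A", alt = "C",
                    type = "substitution", multiallelic = FALSE,
                    bq = 35, vcs = 500, sb = 5, hrun = 1,
                    ref_depth = NULL, alt_depth = NULL, alt2_depth = NULL,
                    n_samples = 4) {
  n <- length(pos)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      type = type, multiallelic = multiallelic,
                      bq = bq, vcs = vcs, sb = sb, hrun = hrun)
  if (is.null(ref_depth)) {
    ref_depth <- matrix(60L, n, n_samples)
  }
  if (is.null(alt_depth)) {
    alt_depth <- matrix(20L, n, ncol(ref_depth))
  }
  colnames(ref_depth) <- colnames(alt_depth) <-
    paste0("s", seq_len(ncol(ref_depth)))
  if (!is.null(alt2_depth)) colnames(alt2_depth) <- colnames(ref_depth)
  variant_table(sites, ref_depth, alt_depth, alt2_depth)
}

two_line_design <- function(n_rep = 2, lines = c("sel1", "control")) {
  d <- expand.grid(replicate = seq_len(n_rep), line = lines,
                   stringsAsFactors = FALSE)
  d$sample <- paste0("s", seq_len(nrow(d)))
  d[, c("sample", "line", "replicate")]
}

# Independent brute-force oracles ---------------------------------------------

# BH step-up from its definition: adjusted p of the i-th order statistic is
# min over j >= i of m * p_(j) / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, probabilities from log-factorial products
brute_fisher <- function(d1, e1, d2, e2) {
  m <- d1 + d2
  n_alive <- (e1 - d1) + (e2 - d2)
  logp_table <- function(k) {
    lchoose(e1, k) + lchoose(e2, m - k) - lchoose(e1 + e2, m)
  }
  ks <- max(0, m - e2):min(e1, m)
  probs <- exp(vapply(ks, logp_table, numeric(1)))
  obs <- exp(logp_table(d1))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# F_ST from the same definition, computed through the E[p^2] identity
brute_fst <- function(alt, total) {
  p <- alt / total
  w <- total / sum(total)
  pbar <- sum(w * p)
  den <- pbar * (1 - pbar)
  if (den == 0) return(0)
  min(1, max(0, (sum(w * p^2) - pbar^2) / den))
}

# minimal inputs for the gene-level aggregation stage
scan_inputs <- function(n_per_gene = c(GA = 10, GB = 4),
                        n_diff = c(GA = 3, GB = 1),
                        n_out = c(GA = 1, GB = 0)) {
  models <- tiny_models()
  sites <- character(0); gene <- character(0)
  diff_flag <- logical(0); out_flag <- logical(0)
  for (g in names(n_per_gene)) {
    ids <- sprintf("2R:%d", seq_len(n_per_gene[[g]]) +
                     ifelse(g == "GA", 5000L, 12300L))
    sites <- c(sites, ids); gene <- c(gene, rep(g, n_per_gene[[g]]))
    diff_flag <- c(diff_flag, seq_len(n_per_gene[[g]]) <= n_diff[[g]])
    out_flag <- c(out_flag, seq_len(n_per_gene[[g]]) <= n_out[[g]])
  }
  diff <- data.frame(site_id = sites, delta_f = 0.6, t = 5, df = 6,
                     p = 0.001, padj = 0.001, differential = diff_flag)
  outl <- list(loci = data.frame(site_id = sites, pp = 1, alpha = 1,
                                 q_value = ifelse(out_flag, 0, 0.5),
                                 outlier = out_flag))
  assignment <- data.frame(site_id = sites, chrom = "2R", pos = 1,
                           gene_id = gene, effect = "synonymous-coding")
  list(models = models, diff = diff, outliers = outl, assignment = assignment)
}
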