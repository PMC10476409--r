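#' Generate synthetic gene models and chromosome sequences
#'
#' Lays genes out contiguously on five chromosome arms with random strand,
#' a 5' UTR, one to three CDS exons separated by short introns, and a 3' UTR.
#' Random chromosome sequences are patched so every CDS starts with ATG and
#' ends with a stop codon. A small fraction of genes is tagged with the
#' candidate families of the resistance literature.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this sub-stream.
#' @return List with `models` (a [gene_model_set()]), `genome` (named
#'   `DNAStringSet`) and `tx_length` (named transcript lengths in bp).
#' @export
simulate_gene_models <- function(config, seed = derive_seed(config$seed, "models")) {
  set.seed(seed)
  n <- config$n_genes
  arms <- c("2R", "2L", "3R", "3L", "X")
  arm_of <- arms[ceiling(seq_len(n) / ceiling(n / length(arms)))]
  fam_probs <- c(P450 = 0.010, esterase = 0.005, transferase = 0.007,
                 `ABC-transporter` = 0.005, cuticle = 0.012, redox = 0.004,
                 `nervous-receptor` = 0.004)
  family <- sample(c(names(fam_probs), "other"), n, replace = TRUE,
                   prob = c(fam_probs, 1 - sum(fam_probs)))
  gid <- sprintf("GENE%05d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  utr5 <- sample(120:250, n, replace = TRUE)
  utr3 <- sample(200:400, n, replace = TRUE)
  n_ex <- sample(1:3, n, replace = TRUE)
  cds_len <- 3L * sample(100:500, n, replace = TRUE)
  gap <- sample(1000:8000, n, replace = TRUE)  # leaves true intergenic space
  seg_gene <- vector("list", n); seg_start <- vector("list", n)
  seg_end <- vector("list", n); seg_type <- vector("list", n)
  gstart <- integer(n); gend <- integer(n)
  cursor <- setNames(rep(2000L, length(arms)), arms)
  for (i in seq_len(n)) {
    arm <- arm_of[i]
    k <- n_ex[i]
    w <- rep(cds_len[i] %/% k, k); w[k] <- w[k] + cds_len[i] - sum(w)
    intr <- if (k > 1L) sample(60:120, k - 1L, replace = TRUE) else integer(0)
    left_utr <- if (strand[i] == "+") utr5[i] else utr3[i]
    right_utr <- if (strand[i] == "+") utr3[i] else utr5[i]
    exon_w <- if (strand[i] == "+") w else rev(w)
    widths <- c(left_utr, exon_w[1L],
                if (k > 1L) as.vector(rbind(intr, exon_w[-1L])), right_utr)
    types <- c(if (strand[i] == "+") "five_prime_UTR" else "three_prime_UTR",
               "CDS",
               if (k > 1L) as.vector(rbind("intron", rep("CDS", k - 1L))),
               if (strand[i] == "+") "three_prime_UTR" else "five_prime_UTR")
    starts <- cursor[arm] + c(0L, cumsum(widths))[seq_along(widths)]
    ends <- starts + widths - 1L
    keep <- types != "intron"
    seg_gene[[i]] <- rep(gid[i], sum(keep))
    seg_start[[i]] <- unname(starts[keep]); seg_end[[i]] <- unname(ends[keep])
    seg_type[[i]] <- types[keep]
    gstart[i] <- cursor[arm]; gend[i] <- ends[length(ends)]
    cursor[arm] <- gend[i] + gap[i]
  }
  genes <- data.frame(gene_id = gid, chrom = arm_of, start = gstart,
                      end = gend, strand = strand, family = family)
  feats <- data.frame(gene_id = unlist(seg_gene), type = unlist(seg_type),
                      start = unlist(seg_start), end = unlist(seg_end))
  tx_len <- setNames(utr5 + cds_len + utr3, gid)
  # chromosome sequences as per-base vectors, with start/stop codons patched
  base_vecs <- lapply(arms, function(a) {
    sample(c("A", "C", "G", "T"), cursor[a] + 2000L, replace = TRUE)
  })
  names(base_vecs) <- arms
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  first_seg <- cds[!duplicated(cds$gene_id), , drop = FALSE]
  last_seg <- cds[!duplicated(cds$gene_id, fromLast = TRUE), , drop = FALSE]
  fs <- first_seg$start[match(gid, first_seg$gene_id)]
  le <- last_seg$end[match(gid, last_seg$gene_id)]
  for (i in seq_len(n)) {
    arm <- arm_of[i]
    if (strand[i] == "+") {
      base_vecs[[arm]][fs[i]:(fs[i] + 2L)] <- c("A", "T", "G")
      base_vecs[[arm]][(le[i] - 2L):le[i]] <- c("T", "A", "A")
    } else {
      base_vecs[[arm]][(le[i] - 2L):le[i]] <- c("C", "A", "T")   # rc(ATG)
      base_vecs[[arm]][fs[i]:(fs[i] + 2L)] <- c("T", "T", "A")  # rc(TAA)
    }
  }
  genome <- Biostrings::DNAStringSet(
    vapply(base_vecs, paste, character(1), collapse = ""))
  list(models = gene_model_set(genes, feats), genome = genome,
       tx_length = tx_len)
}

#' Place synthetic SNP loci on the genome
#'
#' Most loci fall inside or near a host gene (their read depth will track its
#' expression); a configurable fraction is intergenic. Roughly 5% of loci
#' are short indels and 1% triallelic.
#'
#' @param config A [sim_config()].
#' @param gm Result of [simulate_gene_models()].
#' @param seed Integer seed for this sub-stream.
#' @return Data frame with one row per locus: `chrom`, `pos`, `ref`, `alt`,
#'   `type`, `multiallelic`, `host_gene` (NA for intergenic), `in_span`.
#' @export
simulate_snp_table <- function(config, gm,
                               seed = derive_seed(config$seed, "snps")) {
  set.seed(seed)
  n <- config$n_snps
  genes <- gm$models$genes
  genome_chr <- vapply(as.character(names(gm$genome)), function(a)
    as.character(gm$genome[[a]]), character(1))
  arm_len <- nchar(genome_chr)
  n_inter <- round(config$frac_intergenic * n)
  n_genic <- n - n_inter
  host <- sample(nrow(genes), n_genic, replace = TRUE)
  in_span <- runif(n_genic) < 0.85
  pos <- integer(n_genic)
  span_w <- genes$end - genes$start + 1L
  pos[in_span] <- genes$start[host[in_span]] +
    sapply(span_w[host[in_span]], function(w) sample.int(w, 1L)) - 1L
  off <- sample(1:1200, sum(!in_span), replace = TRUE)
  side <- sample(c(-1L, 1L), sum(!in_span), replace = TRUE)
  pos[!in_span] <- ifelse(side < 0, genes$start[host[!in_span]] - off,
                          genes$end[host[!in_span]] + off)
  chrom <- genes$chrom[host]
  host_gene <- genes$gene_id[host]
  # intergenic loci: sampled uniformly from the complement of gene windows
  ig_chrom <- character(0); ig_pos <- integer(0)
  if (n_inter > 0) {
    arms_gr <- GenomicRanges::GRanges(
      names(arm_len), IRanges::IRanges(2L, unname(arm_len) - 1L))
    gr_genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(pmax(1L, genes$start - 1500L), genes$end + 1500L))
    free <- GenomicRanges::setdiff(arms_gr, gr_genes)
    if (length(free)) {
      w <- GenomicRanges::width(free)
      seg <- sample(length(free), n_inter, replace = TRUE, prob = w)
      ig_pos <- GenomicRanges::start(free)[seg] +
        floor(runif(n_inter) * w[seg])
      ig_chrom <- as.character(GenomicRanges::seqnames(free))[seg]
    }
  }
  n_inter <- length(ig_pos)
  chrom <- c(chrom, ig_chrom)
  pos <- as.integer(c(pos, ig_pos))
  host_gene <- c(host_gene, rep(NA_character_, n_inter))
  in_span <- c(in_span, rep(FALSE, n_inter))
  pos <- pmax(pos, 2L)
  # deduplicate positions deterministically by nudging clashes
  key <- paste0(chrom, ":", pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos[dup] <- pos[dup] + 1L
    key <- paste0(chrom, ":", pos)
  }
  ref <- substring(genome_chr[chrom], pos, pos)
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  type <- rep("substitution", n)
  is_indel <- runif(n) < 0.05
  del <- is_indel & runif(n) < 0.5
  ins_len <- sample(1:3, n, replace = TRUE)
  for (i in which(is_indel)) {
    if (del[i]) {
      ref[i] <- substring(genome_chr[chrom[i]], pos[i], pos[i] + ins_len[i])
      alt[i] <- substring(ref[i], 1L, 1L)
    } else {
      ref[i] <- substring(genome_chr[chrom[i]], pos[i], pos[i])
      alt[i] <- paste0(ref[i], paste(sample(bases, ins_len[i], replace = TRUE),
                                     collapse = ""))
    }
    type[i] <- "indel"
  }
  multi <- runif(n) < 0.01 & !is_indel
  for (i in which(multi)) {
    alt[i] <- paste(c(alt[i], sample(setdiff(bases, c(ref[i], alt[i])), 1L)),
                    collapse = ",")
  }
  out <- data.frame(chrom = chrom, pos = pos, ref = unname(ref),
                    alt = unname(alt), type = type, multiallelic = multi,
                    host_gene = host_gene, in_span = in_span)
  rownames(out) <- NULL
  out
}

# pick target-site locus, line-specific selected loci and planted DE genes,
# conditioned on host-gene baseline expression
plan_experiment <- function(config, snps, baseline, seed) {
  set.seed(seed)
  sel_lines <- config$line_names[-1L]
  b_host <- baseline[snps$host_gene]
  cand <- which(!is.na(snps$host_gene) & snps$in_span &
                  snps$type == "substitution" & !snps$multiallelic)
  # target-site analogue hosted in a weakly expressed gene (as for a sodium
  # channel in whole adults): its SNP never reaches callable coverage
  low <- cand[b_host[cand] <= 3]
  if (length(low)) {
    target <- if (length(low) == 1L) low else sample(low, 1L)
  } else {
    target <- if (length(cand) == 1L) cand else sample(cand, 1L)
    baseline[snps$host_gene[target]] <- 1.5
  }
  target_gene <- snps$host_gene[target]
  selected <- data.frame(line = sel_lines, locus = target,
                         s = config$target_s, h = config$target_h)
  # line-specific selected loci hosted in well-expressed genes whose pooled
  # read depth stays inside the callable coverage window, disjoint across lines
  strong <- cand[b_host[cand] >= 150 & b_host[cand] <= 3000 &
                   snps$host_gene[cand] != target_gene]
  strong <- strong[!duplicated(snps$host_gene[strong])]  # one per gene
  strong <- strong[sample.int(length(strong))]
  used <- 0L
  if (!is.null(config$selected_loci)) {
    selected <- rbind(selected, config$selected_loci)
  } else {
    for (l in sel_lines) {
      take <- min(config$n_selected_per_line, length(strong) - used)
      if (take > 0) {
        selected <- rbind(selected, data.frame(
          line = l, locus = strong[used + seq_len(take)],
          s = runif(take, 0.8, 1.5), h = 0.8))
        used <- used + take
      }
    }
  }
  # planted DE genes among detectably expressed genes, disjoint across lines
  if (!is.null(config$planted_de)) {
    de <- config$planted_de
  } else {
    sel_hosts <- unique(snps$host_gene[selected$locus])
    pool <- setdiff(names(baseline)[baseline >= 150], c(sel_hosts, target_gene))
    pool <- pool[sample.int(length(pool))]
    de <- NULL; taken <- 0L
    for (l in sel_lines) {
      n_o <- min(config$n_de_over, max(0L, length(pool) - taken))
      over <- pool[taken + seq_len(n_o)]; taken <- taken + n_o
      n_u <- min(config$n_de_under, max(0L, length(pool) - taken))
      under <- pool[taken + seq_len(n_u)]; taken <- taken + n_u
      lo <- log10(config$de_fc_range[1]); hi <- log10(config$de_fc_range[2])
      de <- rbind(de,
                  if (n_o) data.frame(line = l, gene = over,
                                      fc = 10^runif(n_o, lo, hi)),
                  if (n_u) data.frame(line = l, gene = under,
                                      fc = 1 / 10^runif(n_u, lo, hi)))
    }
    if (is.null(de)) de <- data.frame(line = character(0), gene = character(0),
                                      fc = numeric(0))
  }
  list(selected_loci = selected, planted_de = de, target_locus = target,
       target_gene = target_gene, baseline = baseline)
}

# per-generation exposure calibration: survival of genotype g is
# min(1, c * w_g) with viabilities w = (1+s, 1+hs, 1); c is solved so the
# expected mortality hits the centre of the target window
calibrate_exposure <- function(geno_freq, s, h, target_mortality) {
  w <- c(1 + s, 1 + h * s, 1)
  f <- function(cc) sum(geno_freq * pmin(1, cc * w)) - (1 - target_mortality)
  if (f(1) < 0) return(NA_real_)  # even no-kill dose exceeds target mortality
  stats::uniroot(f, c(1e-12, 1), tol = 1e-10)$root
}

#' Simulate allele-frequency trajectories for every locus and line
#'
#' The control line evolves by drift only. In each selected line the
#' target-site locus goes through the explicit census cycle each generation:
#' Hardy-Weinberg genotype counts, an insecticide exposure whose intensity is
#' re-calibrated so expected mortality sits at the centre of the target
#' window (survival of genotype g is min(1, c w_g)), binomial survival per
#' genotype redrawn until realized mortality falls inside the window (the
#' experimenter adjusts the dose otherwise), then binomial gamete sampling
#' from the survivors. Other planted loci evolve under standard
#' Wright-Fisher viability selection; all remaining loci drift.
#'
#' @param config A [sim_config()].
#' @param snps SNP table from [simulate_snp_table()].
#' @param plan Planting plan (internal; see [simulate_experiment()]).
#' @return List with `founder`, `trajectories` (one loci x (generations+1)
#'   matrix per line) and `mortality` (realized per-generation records).
#' @keywords internal
simulate_trajectories <- function(config, snps, plan) {
  n <- nrow(snps)
  N <- config$census_size
  gens <- config$n_generations
  target_mid <- mean(config$target_mortality_range)
  set.seed(derive_seed(config$seed, "founder"))
  founder <- pmin(0.98, pmax(0.02, rbeta(n, 0.8, 0.8)))
  founder[plan$target_locus] <- config$founder_target_freq
  own <- plan$selected_loci[plan$selected_loci$locus != plan$target_locus, , drop = FALSE]
  set.seed(derive_seed(config$seed, "founder-selected"))
  if (nrow(own)) founder[own$locus] <- runif(nrow(own), 0.15, 0.35)

  traj <- list(); mortality <- NULL
  for (li in seq_len(config$n_lines)) {
    line <- config$line_names[li]
    set.seed(derive_seed(config$seed, "wf", line))
    s_vec <- rep(0, n); h_vec <- rep(0.5, n)
    if (li > 1L) {
      rows <- plan$selected_loci[plan$selected_loci$line == line, , drop = FALSE]
      s_vec[rows$locus] <- rows$s; h_vec[rows$locus] <- rows$h
    }
    P <- matrix(0, n, gens + 1L)
    P[, 1L] <- founder
    p <- founder
    for (t in seq_len(gens)) {
      skip <- t %in% config$skip_generations
      st <- if (li > 1L && !skip) s_vec else rep(0, n)
      p_new <- wf_step(p, N, st, h_vec)
      if (li > 1L && !skip) {
        # explicit census cycle at the target-site locus
        tl <- plan$target_locus
        pt <- p[tl]
        geno <- as.vector(rmultinom(1L, N, c(pt^2, 2 * pt * (1 - pt), (1 - pt)^2)))
        cc <- calibrate_exposure(geno / N, config$target_s, config$target_h,
                                 target_mid)
        if (is.na(cc)) {
          stop("exposure calibration failed for line ", line,
               " at generation ", t)
        }
        surv_p <- pmin(1, cc * c(1 + config$target_s,
                                 1 + config$target_h * config$target_s, 1))
        ok <- FALSE
        for (attempt in 1:50) {
          surv <- rbinom(3L, geno, surv_p)
          realized <- 1 - sum(surv) / N
          if (realized >= config$target_mortality_range[1] &&
              realized <= config$target_mortality_range[2] && sum(surv) > 0) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("no exposure achieved the mortality window for line ",
                      line, " at generation ", t)
        mortality <- rbind(mortality, data.frame(
          line = line, generation = t, exposed = N,
          dead = N - sum(surv), mortality = realized))
        p_surv <- (2 * surv[1] + surv[2]) / (2 * sum(surv))
        p_new[tl] <- rbinom(1L, 2L * N, p_surv) / (2 * N)
      }
      p <- p_new
      P[, t + 1L] <- p
    }
    traj[[line]] <- P
  }
  list(founder = founder, trajectories = traj, mortality = mortality)
}

#' Simulate RNA-seq counts with planted fold-changes
#'
#' Gene baselines span roughly four orders of magnitude (log-uniform), so a
#' realistic fraction of genes fails the reads/kb coverage filter. Counts are
#' negative-binomial with dispersion `nb_dispersion` around
#' baseline x fold-change x library factor; library sizes vary +/-30%
#' across samples.
#'
#' @param config A [sim_config()].
#' @param baseline Named vector of baseline mean counts per gene.
#' @param planted_de Data frame (`line`, `gene`, `fc`).
#' @param tx_length Named transcript lengths (bp).
#' @param seed Sub-stream seed.
#' @return List with `cm` (a [count_matrix()]) and `lib_factors`.
#' @export
simulate_expression_counts <- function(config, baseline, planted_de, tx_length,
                                       seed = derive_seed(config$seed, "expr")) {
  set.seed(seed)
  samples <- expand.grid(replicate = seq_len(config$n_replicate_pools),
                         line = config$line_names,
                         stringsAsFactors = FALSE)[, c("line", "replicate")]
  samples$sample <- paste0(samples$line, "_R", samples$replicate)
  lib <- runif(nrow(samples), 0.7, 1.3)
  names(lib) <- samples$sample
  genes <- names(baseline)
  fc <- matrix(1, length(genes), config$n_lines,
               dimnames = list(genes, config$line_names))
  if (nrow(planted_de)) {
    for (k in seq_len(nrow(planted_de))) {
      fc[planted_de$gene[k], planted_de$line[k]] <- planted_de$fc[k]
    }
  }
  counts <- matrix(0L, length(genes), nrow(samples),
                   dimnames = list(genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline * fc[, samples$line[j]] * lib[j]
    counts[, j] <- if (config$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      rpois(length(mu), mu)
    }
  }
  cm <- count_matrix(counts, tx_length[genes], samples)
  list(cm = cm, lib_factors = lib)
}

#' Sample pooled allele counts coupled to host-gene expression
#'
#' For each replicate pool, `pool_size` individuals are drawn without
#' replacement from the line's final census (hypergeometric sampling of
#' chromosomes), giving the pool allele frequency. Read depth at a locus is
#' Poisson with mean proportional to the host gene's expression in that
#' sample (scaled so a median-expression gene yields `mean_depth`);
#' intergenic loci get a fixed floor depth. Alternate reads are binomial in
#' the pool frequency. Quality annotations are drawn from passing
#' distributions except for a configurable fraction of records given one
#' failing value.
#'
#' @param config A [sim_config()].
#' @param snps SNP table from [simulate_snp_table()].
#' @param final_freq Matrix loci x lines of final-generation frequencies.
#' @param expr Result of [simulate_expression_counts()].
#' @param baseline Named baseline means (for the depth scale).
#' @param protect_loci Integer indices of loci exempt from the random
#'   filter-failing annotation draws (the planted truth loci: corruption
#'   models caller artifacts at arbitrary records, and assigning it to the
#'   focal loci would make them unrecoverable by construction).
#' @param seed Sub-stream seed.
#' @return A [variant_table()] covering every pool sample.
#' @export
sample_pooled_allele_counts <- function(config, snps, final_freq, expr,
                                        baseline, protect_loci = integer(0),
                                        seed = derive_seed(config$seed, "pools")) {
  n <- nrow(snps)
  N2 <- 2L * config$census_size
  k2 <- 2L * config$pool_size
  med_b <- median(baseline)
  norm_expr <- sweep(expr$cm$counts, 2L, expr$lib_factors[colnames(expr$cm$counts)], "/")
  samples <- expr$cm$samples
  ref_d <- alt_d <- alt2_d <- matrix(NA_integer_, n, nrow(samples),
                                     dimnames = list(NULL, samples$sample))
  for (j in seq_len(nrow(samples))) {
    line <- samples$line[j]
    set.seed(derive_seed(config$seed, "pool", line, samples$replicate[j]))
    K <- round(final_freq[, line] * N2)
    pool_alt <- rhyper(n, K, N2 - K, k2)
    pool_f <- pool_alt / k2
    host_row <- match(snps$host_gene, rownames(norm_expr))
    host_expr <- norm_expr[cbind(host_row, j)]
    depth_mean <- config$mean_depth * host_expr / med_b
    depth_mean[is.na(depth_mean)] <- config$intergenic_depth
    depth <- rpois(n, depth_mean)
    alt <- rbinom(n, depth, pool_f)
    alt2 <- ifelse(snps$multiallelic, rbinom(n, depth - alt, 0.05), NA_integer_)
    ref <- depth - alt - ifelse(is.na(alt2), 0L, alt2)
    ref_d[, j] <- ref; alt_d[, j] <- alt; alt2_d[, j] <- as.integer(alt2)
  }
  set.seed(derive_seed(config$seed, "pool-qc"))
  sites <- snps[c("chrom", "pos", "ref", "alt", "type", "multiallelic")]
  sites$bq <- round(pmin(40, pmax(20, rnorm(n, 34, 2.5))), 1)
  sites$vcs <- round(pmax(200, rnorm(n, 600, 120)), 1)
  sites$sb <- round(pmin(25, rexp(n, 1 / 8)), 2)
  sites$hrun <- sample(0:3, n, replace = TRUE)
  n_fail <- round(config$qc_fail_fraction * n)
  eligible <- setdiff(seq_len(n), protect_loci)
  n_fail <- min(n_fail, length(eligible))
  if (n_fail > 0) {
    fail <- eligible[sample.int(length(eligible), n_fail)]
    rule <- sample(4L, n_fail, replace = TRUE)
    sites$bq[fail[rule == 1L]] <- round(runif(sum(rule == 1L), 5, 19.9), 1)
    sites$vcs[fail[rule == 2L]] <- round(runif(sum(rule == 2L), 20, 199), 1)
    sites$sb[fail[rule == 3L]] <- round(runif(sum(rule == 3L), 25.1, 80), 2)
    sites$hrun[fail[rule == 4L]] <- sample(5:8, sum(rule == 4L), replace = TRUE)
  }
  variant_table(sites, ref_d, alt_d, alt2_d)
}

monitoring_generations <- function(n_generations,
                                   at = c(0L, 2L, 7L, 9L, 17L)) {
  sort(unique(pmin(at, n_generations)))
}

#' Simulate a complete selection experiment
#'
#' Runs the founder-to-final-generation selection loop for every line and emits
#' every input the analysis consumes — gene models and chromosome sequences,
#' expression counts, pooled variant allele depths, per-generation genotype
#' monitoring tables and bioassay records — together with the ground-truth
#' ledger (trajectories, planted selected loci and fold-changes, realized
#' mortality). Fully reproducible: the same configuration (including its
#' seed) yields a byte-identical bundle.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_bundle`: a list with `config`, `models`,
#'   `genome`, `snps`, `counts`, `variants`, `genotypes`, `bioassay`,
#'   `design`, `truth`.
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  gm <- simulate_gene_models(config)
  snps <- simulate_snp_table(config, gm)
  set.seed(derive_seed(config$seed, "baselines"))
  baseline <- setNames(10^runif(config$n_genes, 0, 4), gm$models$genes$gene_id)
  plan <- plan_experiment(config, snps, baseline,
                          derive_seed(config$seed, "planting"))
  baseline <- plan$baseline
  dyn <- simulate_trajectories(config, snps, plan)
  expr <- simulate_expression_counts(config, baseline, plan$planted_de,
                                     gm$tx_length)
  final_freq <- vapply(dyn$trajectories, function(m) m[, ncol(m)],
                       numeric(nrow(snps)))
  variants <- sample_pooled_allele_counts(config, snps, final_freq, expr,
                                          baseline,
                                          protect_loci = unique(plan$selected_loci$locus))

  # individual genotypes at the monitored target-site locus
  set.seed(derive_seed(config$seed, "genotypes"))
  gens_geno <- monitoring_generations(config$n_generations)
  genotypes <- do.call(rbind, lapply(config$line_names, function(line) {
    do.call(rbind, lapply(gens_geno, function(g) {
      p <- dyn$trajectories[[line]][plan$target_locus, g + 1L]
      cnt <- as.vector(rmultinom(1L, 30L, c(p^2, 2 * p * (1 - p), (1 - p)^2)))
      data.frame(generation = g, line = line,
                 individual = sprintf("%s_G%d_%02d", line, g, seq_len(30L)),
                 genotype = rep(c("RR", "RS", "SS"), cnt))
    }))
  }))
  rownames(genotypes) <- NULL

  # bioassay monitoring at the dose calibrated on the founder population
  set.seed(derive_seed(config$seed, "bioassay"))
  p0 <- config$founder_target_freq
  hwe0 <- c(p0^2, 2 * p0 * (1 - p0), (1 - p0)^2)
  c0 <- calibrate_exposure(hwe0, config$target_s, config$target_h,
                           mean(config$target_mortality_range))
  surv0 <- pmin(1, c0 * c(1 + config$target_s,
                          1 + config$target_h * config$target_s, 1))
  gens_bio <- monitoring_generations(config$n_generations,
                                     c(0L, 2L, 5L, 7L, 9L, 11L, 13L, 17L))
  sel_lines <- config$line_names[-1L]
  bio <- NULL
  for (ins in seq_along(sel_lines)) {
    insecticide <- paste0("insecticide_", ins)
    for (line in c(config$line_names[1L], sel_lines[ins])) {
      for (g in gens_bio) {
        p <- dyn$trajectories[[line]][plan$target_locus, g + 1L]
        hwe <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
        mort <- min(1, max(0, 1 - sum(hwe * surv0)))
        exposed <- 100L
        bio <- rbind(bio, data.frame(
          line = line, generation = g, insecticide = insecticide,
          exposed = exposed, dead = rbinom(1L, exposed, mort)))
      }
    }
  }
  rownames(bio) <- NULL

  site_id <- paste0(snps$chrom, ":", snps$pos)
  sel <- plan$selected_loci
  truth <- list(
    founder_freq = dyn$founder,
    trajectories = dyn$trajectories,
    selected_loci = data.frame(
      line = sel$line, locus = sel$locus, site_id = site_id[sel$locus],
      host_gene = snps$host_gene[sel$locus], s = sel$s, h = sel$h,
      founder_freq = dyn$founder[sel$locus],
      final_freq = mapply(function(l, i) dyn$trajectories[[l]][i, config$n_generations + 1L],
                          sel$line, sel$locus)),
    de_genes = plan$planted_de,
    target_locus = plan$target_locus,
    target_site_id = site_id[plan$target_locus],
    target_gene = plan$target_gene,
    mortality = dyn$mortality,
    baseline_mean = baseline,
    lib_factors = expr$lib_factors)
  structure(list(config = config, models = gm$models, genome = gm$genome,
                 snps = snps, counts = expr$cm, variants = variants,
                 genotypes = genotypes, bioassay = bio,
                 design = expr$cm$samples, truth = truth),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle: %d genes, %d SNPs, %d lines x %d pools (seed %d)\n",
              x$config$n_genes, x$config$n_snps, x$config$n_lines,
              x$config$n_replicate_pools, x$config$seed))
  invisible(x)
}

#' Write a simulation bundle to disk
#'
#' Emits `counts.tsv`, `design.tsv`, `variants.vcf`, `genes.gff3`,
#' `genome.fa`, `genotypes.tsv`, `bioassay.tsv` and `truth.json` under `dir`.
#'
#' @param bundle A [simulate_experiment()] result.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(bundle$counts, file.path(dir, "counts.tsv"))
  write_design(bundle$design, file.path(dir, "design.tsv"))
  write_vcf(bundle$variants, file.path(dir, "variants.vcf"))
  write_gff(bundle$models, file.path(dir, "genes.gff3"))
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  write_genotypes(bundle$genotypes, file.path(dir, "genotypes.tsv"))
  write_bioassay(bundle$bioassay, file.path(dir, "bioassay.tsv"))
  truth <- bundle$truth
  truth$trajectories <- lapply(truth$trajectories, function(m) round(m, 6))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(dir)
}
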