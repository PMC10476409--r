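#' Effect classes recognized by the annotator
#'
#' @return Character vector of the 15 effect classes, in precedence order
#'   (coding > UTR > splice > intronic > near-gene > upstream/downstream >
#'   intergenic).
#' @export
effect_classes <- function() {
  c("synonymous-coding", "non-synonymous-coding", "start-lost", "stop-gained",
    "stop-lost", "frameshift-coding", "splice-site", "essential-splice-site",
    "5'-UTR", "3'-UTR", "upstream", "downstream", "near-gene", "intronic",
    "intergenic")
}

#' Annotate variant effects against gene models
#'
#' Assigns each variant to at most one gene — the gene whose span boundary is
#' nearest among all genes whose 1500 bp windows cover it, ties resolved to
#' the leftmost gene on the chromosome — and classifies its effect with the
#' precedence coding > UTR > splice > intronic > near-gene >
#' upstream/downstream > intergenic:
#' \itemize{
#' \item substitutions inside a CDS are classified by codon substitution
#'   under the standard genetic code, strand-aware (synonymous /
#'   non-synonymous / start-lost / stop-gained / stop-lost);
#' \item indels inside a CDS whose length change is not a multiple of 3 are
#'   `frameshift-coding` (in-frame indels are reported non-synonymous);
#' \item the first/last 2 bp of an intron are `essential-splice-site`, intron
#'   positions within 8 bp of an exon-intron boundary are `splice-site`;
#' \item sites within 100 bp of the gene span are `near-gene` (this window
#'   takes precedence over upstream/downstream where they overlap);
#' \item sites within 1500 bp of the gene start (5' side, strand-aware) are
#'   `upstream`, within 1500 bp of the gene end `downstream`;
#' \item everything else is `intergenic`.
#' }
#'
#' @param vt A [variant_table()] (or a data frame with `chrom`, `pos`, `ref`,
#'   `alt`, `type`).
#' @param models A [gene_model_set()].
#' @param genome Named `Biostrings::DNAStringSet` of chromosome sequences,
#'   required to classify coding substitutions. A reference allele that
#'   contradicts the genome sequence raises an error.
#' @param flank_window,near_window,splice_window,essential_window Window
#'   sizes in bp (defaults 1500, 100, 8, 2).
#' @return Data frame with `site_id`, `chrom`, `pos`, `gene_id` (NA for
#'   intergenic sites) and `effect`.
#' @export
annotate_effects <- function(vt, models, genome = NULL,
                             flank_window = 1500, near_window = 100,
                             splice_window = 8, essential_window = 2) {
  stopifnot(inherits(models, "gene_model_set"))
  sites <- if (inherits(vt, "variant_table")) vt$sites else vt
  if (is.null(sites$site_id)) sites$site_id <- paste0(sites$chrom, ":", sites$pos)
  g <- models$genes
  n <- nrow(sites)
  out <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                    pos = sites$pos, gene_id = NA_character_,
                    effect = "intergenic")
  if (!n || !nrow(g)) return(out)

  snp_gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  ext_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(1L, g$start - flank_window), g$end + flank_window))
  hits <- GenomicRanges::findOverlaps(snp_gr, ext_gr)
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  dist <- pmax(0L, g$start[gi] - sites$pos[qi], sites$pos[qi] - g$end[gi])
  # nearest gene boundary wins; ties to the leftmost gene on the chromosome
  ord <- order(qi, dist, g$start[gi])
  pick <- ord[!duplicated(qi[ord])]
  qi <- qi[pick]; gi <- gi[pick]; dist <- dist[pick]
  out$gene_id[qi] <- g$gene_id[gi]

  fe_split <- split(models$features, models$features$gene_id)
  introns <- gene_introns(models)
  introns_split <- split(introns, introns$gene_id)
  pos <- sites$pos[qi]
  strand <- g$strand[gi]
  effect <- rep(NA_character_, length(qi))

  inside <- dist == 0L
  # feature membership for sites inside the gene span
  for (k in which(inside)) {
    gid <- g$gene_id[gi[k]]
    gfe <- fe_split[[gid]]
    hit <- if (is.null(gfe)) gfe else gfe[gfe$start <= pos[k] & gfe$end >= pos[k], , drop = FALSE]
    if (!is.null(hit) && nrow(hit)) {
      effect[k] <- switch(hit$type[1L],
                          CDS = "CDS",
                          five_prime_UTR = "5'-UTR",
                          three_prime_UTR = "3'-UTR")
    } else {
      gint <- introns_split[[gid]]
      inin <- if (is.null(gint)) gint else gint[gint$start <= pos[k] & gint$end >= pos[k], , drop = FALSE]
      if (!is.null(inin) && nrow(inin)) {
        off <- min(pos[k] - inin$start[1L], inin$end[1L] - pos[k]) + 1L
        effect[k] <- if (off <= essential_window) "essential-splice-site"
                     else if (off <= splice_window) "splice-site"
                     else "intronic"
      } else {
        effect[k] <- "intronic"  # span position not covered by any feature
      }
    }
  }
  # flanking classes
  outside <- which(!inside)
  if (length(outside)) {
    five_side <- ifelse(pos[outside] < g$start[gi[outside]],
                        strand[outside] == "+", strand[outside] == "-")
    effect[outside] <- ifelse(dist[outside] <= near_window, "near-gene",
                       ifelse(five_side, "upstream", "downstream"))
  }

  # codon-level classification of CDS variants
  cds_idx <- which(effect == "CDS")
  if (length(cds_idx)) {
    is_sub <- sites$type[qi[cds_idx]] == "substitution"
    ind <- cds_idx[!is_sub]
    if (length(ind)) {
      ref_len <- nchar(sites$ref[qi[ind]])
      alt1 <- sub(",.*", "", sites$alt[qi[ind]])
      shift <- abs(ref_len - nchar(alt1)) %% 3L
      effect[ind] <- ifelse(shift != 0L, "frameshift-coding", "non-synonymous-coding")
    }
    subs <- cds_idx[is_sub]
    if (length(subs)) {
      if (is.null(genome)) {
        stop("`genome` sequences are required to classify coding substitutions")
      }
      effect[subs] <- classify_coding_subs(
        gene_id = g$gene_id[gi[subs]], pos = pos[subs],
        ref = sites$ref[qi[subs]],
        alt = sub(",.*", "", sites$alt[qi[subs]]),
        models = models, genome = genome)
    }
  }
  out$effect[qi] <- effect
  out
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# classify coding substitutions, vectorized by host gene
classify_coding_subs <- function(gene_id, pos, ref, alt, models, genome) {
  gc_tab <- Biostrings::GENETIC_CODE
  res <- character(length(gene_id))
  genes <- models$genes
  fe <- models$features[models$features$type == "CDS", , drop = FALSE]
  for (gid in unique(gene_id)) {
    sel <- which(gene_id == gid)
    grow <- genes[genes$gene_id == gid, , drop = FALSE]
    segs <- fe[fe$gene_id == gid, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    widths <- segs$end - segs$start + 1L
    total <- sum(widths)
    chrom_seq <- genome[[grow$chrom]]
    cds_fwd <- paste(vapply(seq_len(nrow(segs)), function(i) {
      as.character(XVector::subseq(chrom_seq, segs$start[i], segs$end[i]))
    }, character(1)), collapse = "")
    minus <- grow$strand == "-"
    cds_seq <- if (minus) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_fwd)))
    } else cds_fwd
    seg_of <- findInterval(pos[sel], segs$start)
    g_off <- cumsum(c(0L, widths))[seg_of] + (pos[sel] - segs$start[seg_of] + 1L)
    cds_pos <- if (minus) total - g_off + 1L else g_off
    ref_tx <- if (minus) comp_base(ref[sel]) else ref[sel]
    alt_tx <- if (minus) comp_base(alt[sel]) else alt[sel]
    have <- substring(cds_seq, cds_pos, cds_pos)
    if (any(toupper(have) != toupper(ref_tx))) {
      stop("reference allele inconsistent with gene-model sequence in ", gid)
    }
    codon_i <- (cds_pos - 1L) %/% 3L + 1L
    offset <- (cds_pos - 1L) %% 3L + 1L
    codon <- substring(cds_seq, 3L * codon_i - 2L, 3L * codon_i)
    mutant <- codon
    substr(mutant, offset, offset) <- alt_tx
    ref_aa <- unname(gc_tab[toupper(codon)])
    mut_aa <- unname(gc_tab[toupper(mutant)])
    cls <- ifelse(codon_i == 1L & toupper(codon) == "ATG" & toupper(mutant) != "ATG",
                  "start-lost",
           ifelse(ref_aa != "*" & mut_aa == "*", "stop-gained",
           ifelse(ref_aa == "*" & mut_aa != "*", "stop-lost",
           ifelse(ref_aa == mut_aa, "synonymous-coding", "non-synonymous-coding"))))
    res[sel] <- cls
  }
  res
}
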