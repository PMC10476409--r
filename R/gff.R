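#' Gene model set
#'
#' Gene coordinates plus transcript structure used for SNP effect annotation
#' and the gene-level genome scan. Coordinates are 1-based inclusive, as in
#' GFF3. Each gene carries a `family` tag classifying it into the candidate
#' families followed by the resistance literature (`P450`, `esterase`,
#' `transferase`, `ABC-transporter`, `cuticle`, `redox`, `nervous-receptor`)
#' or `other`.
#'
#' Genes whose CDS segments do not sum to a multiple of 3 are rejected with a
#' warning (the run continues without them).
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `family`.
#' @param features Data frame with columns `gene_id`, `type` (`CDS`,
#'   `five_prime_UTR` or `three_prime_UTR`), `start`, `end`.
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, features) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "family") %in% names(genes)),
            all(c("gene_id", "type", "start", "end") %in% names(features)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene identifiers")
  if (any(genes$start > genes$end)) stop("gene start must not exceed end")
  if (any(features$start > features$end)) stop("feature start must not exceed end")
  genes$family[is.na(genes$family) | genes$family == ""] <- "other"
  features <- features[order(features$gene_id, features$start), , drop = FALSE]
  # segment sanity per gene: inside the span, non-overlapping, CDS length % 3
  drop <- character(0)
  for (gid in unique(features$gene_id)) {
    fe <- features[features$gene_id == gid, , drop = FALSE]
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    if (!nrow(g)) stop("feature references unknown gene ", gid)
    if (any(fe$start < g$start) || any(fe$end > g$end)) {
      stop("feature outside gene span for ", gid)
    }
    if (nrow(fe) > 1L && any(fe$start[-1L] <= fe$end[-nrow(fe)])) {
      stop("overlapping feature segments for ", gid)
    }
    cds <- fe[fe$type == "CDS", , drop = FALSE]
    if (nrow(cds) && sum(cds$end - cds$start + 1L) %% 3L != 0L) {
      warning("CDS length of ", gid, " is not a multiple of 3; gene dropped")
      drop <- c(drop, gid)
    }
  }
  if (length(drop)) {
    genes <- genes[!genes$gene_id %in% drop, , drop = FALSE]
    features <- features[!features$gene_id %in% drop, , drop = FALSE]
  }
  rownames(genes) <- rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes on %d chromosome arms (%d candidate-family)\n",
              nrow(x$genes), length(unique(x$genes$chrom)),
              sum(x$genes$family != "other")))
  invisible(x)
}

#' Candidate gene families
#'
#' The gene families classically screened in insecticide-resistance studies:
#' detoxification enzymes (P450s, esterases, transferases), ABC transporters,
#' cuticle proteins, redox enzymes and nervous receptors.
#'
#' @return Character vector of family tags.
#' @export
candidate_families <- function() {
  c("P450", "esterase", "transferase", "ABC-transporter",
    "cuticle", "redox", "nervous-receptor")
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `CDS` and UTR features; the family tag is carried in
#' a `family` attribute on the gene feature.
#'
#' @param models A [gene_model_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff <- function(models, path) {
  stopifnot(inherits(models, "gene_model_set"))
  g <- models$genes; fe <- models$features
  tx_id <- paste0(g$gene_id, ".t1")
  gr_gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Parent = NA_character_, family = g$family)
  gr_mrna <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "mRNA", ID = tx_id, Parent = g$gene_id, family = NA_character_)
  gmap <- match(fe$gene_id, g$gene_id)
  # CDS phase: offset to the next codon start, in transcription order
  fe$phase <- NA_integer_
  for (gid in unique(fe$gene_id[fe$type == "CDS"])) {
    rows <- which(fe$gene_id == gid & fe$type == "CDS")
    rows <- rows[order(fe$start[rows])]
    if (g$strand[match(gid, g$gene_id)] == "-") rows <- rev(rows)
    cum <- cumsum(c(0L, fe$end[rows] - fe$start[rows] + 1L))
    fe$phase[rows] <- (3L - cum[seq_along(rows)] %% 3L) %% 3L
  }
  gr_feat <- GenomicRanges::GRanges(
    g$chrom[gmap], IRanges::IRanges(fe$start, fe$end), strand = g$strand[gmap],
    type = fe$type, ID = NA_character_, Parent = tx_id[gmap],
    family = NA_character_)
  S4Vectors::mcols(gr_gene)$phase <- NA_integer_
  S4Vectors::mcols(gr_mrna)$phase <- NA_integer_
  S4Vectors::mcols(gr_feat)$phase <- fe$phase
  gr <- c(gr_gene, gr_mrna, gr_feat)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features carrying `ID` (and optionally `family`) attributes,
#' with `CDS`/UTR features linked through `mRNA` parents (or directly to the
#' gene). A gene without a family attribute is tagged `other`.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_model_set()].
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  first_parent <- function(p) {
    if (is.null(p)) return(rep(NA_character_, length(gr)))
    vapply(as.list(p), function(x) if (length(x)) x[1] else NA_character_,
           character(1))
  }
  parent <- first_parent(meta$Parent)
  id <- as.character(meta$ID)
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features in GFF3 file")
  fam <- if ("family" %in% names(meta)) as.character(meta$family) else NA_character_
  genes <- data.frame(
    gene_id = id[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    family = if (length(fam) == length(gr)) fam[is_gene] else NA_character_)
  # map transcript ids to their gene
  tx2gene <- setNames(parent[type == "mRNA"], id[type == "mRNA"])
  is_feat <- type %in% c("CDS", "five_prime_UTR", "three_prime_UTR")
  fparent <- parent[is_feat]
  fgene <- ifelse(fparent %in% names(tx2gene), tx2gene[fparent], fparent)
  features <- data.frame(
    gene_id = unname(fgene), type = type[is_feat],
    start = GenomicRanges::start(gr)[is_feat],
    end = GenomicRanges::end(gr)[is_feat])
  gene_model_set(genes, features)
}

#' Intron segments implied by a gene model set
#'
#' Introns are the gaps between consecutive transcript feature segments
#' within each gene span.
#'
#' @param models A [gene_model_set()].
#' @return Data frame with columns `gene_id`, `start`, `end`.
#' @keywords internal
gene_introns <- function(models) {
  fe <- models$features
  out <- lapply(split(fe, fe$gene_id), function(x) {
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) < 2L) return(NULL)
    gaps <- which(x$start[-1L] > x$end[-nrow(x)] + 1L)
    if (!length(gaps)) return(NULL)
    data.frame(gene_id = x$gene_id[1L],
               start = x$end[gaps] + 1L, end = x$start[gaps + 1L] - 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), start = integer(0), end = integer(0))
  }
  rownames(out) <- NULL
  out
}
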