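#' Gene x sample count matrix
#'
#' Container for raw RNA-seq read counts plus the gene lengths needed by the
#' reads-per-kb coverage filter and the sample design (line, replicate).
#'
#' @param counts Integer matrix, genes in rows, samples in columns; both
#'   dimensions named.
#' @param lengths Named integer vector of gene lengths in bp (transcript
#'   length used for coverage).
#' @param samples Data frame with columns `sample`, `line`, `replicate`,
#'   one row per column of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene and sample names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample identifiers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  lengths <- as.numeric(lengths[rownames(counts)])
  names(lengths) <- rownames(counts)
  if (any(is.na(lengths))) stop("missing gene length for some genes")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  stopifnot(all(c("sample", "line", "replicate") %in% names(samples)))
  samples <- samples[match(colnames(counts), samples$sample),
                     c("sample", "line", "replicate"), drop = FALSE]
  if (any(is.na(samples$sample))) stop("every sample column needs a design row")
  rownames(samples) <- NULL
  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d lines)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$line))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to a set of genes
#'
#' @param cm A [count_matrix()].
#' @param genes Character vector of gene identifiers to retain.
#' @return A `count_matrix` restricted to `genes`.
#' @export
subset_genes <- function(cm, genes) {
  stopifnot(inherits(cm, "count_matrix"))
  missing <- setdiff(genes, rownames(cm$counts))
  if (length(missing)) stop("unknown gene(s): ", paste(head(missing), collapse = ", "))
  count_matrix(cm$counts[genes, , drop = FALSE], cm$lengths[genes], cm$samples)
}

#' Read / write a count matrix as TSV
#'
#' The file has a header row `gene_id`, `length`, then one column per sample;
#' counts must parse as non-negative integers (a fractional value is reported
#' with its gene and sample). Sample design is stored in a separate two-line
#' header-comment-free TSV, see [read_design()].
#'
#' @param path Path to a tab-separated file.
#' @param samples Optional design data frame (`sample`, `line`, `replicate`);
#'   when `NULL`, line and replicate are parsed from sample names of the form
#'   `line_R<k>`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, samples = NULL) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!all(c("gene_id", "length") %in% names(tab))) {
    stop("counts file must have `gene_id` and `length` columns")
  }
  sample_cols <- setdiff(names(tab), c("gene_id", "length"))
  if (!length(sample_cols)) stop("counts file has no sample columns")
  mat <- as.matrix(tab[, sample_cols, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(tab$gene_id, sample_cols)))
  bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer count '%s' at gene %s, sample %s",
                 mat[bad[1, 1], bad[1, 2]], tab$gene_id[bad[1, 1]],
                 sample_cols[bad[1, 2]]))
  }
  lengths <- as.numeric(tab$length)
  names(lengths) <- tab$gene_id
  if (is.null(samples)) samples <- design_from_names(sample_cols)
  count_matrix(num, lengths, samples)
}

#' @rdname read_counts
#' @param cm A [count_matrix()] to write.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- data.frame(gene_id = rownames(cm$counts),
                    length = unname(cm$lengths),
                    cm$counts, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

design_from_names <- function(sample_names) {
  parts <- regmatches(sample_names, regexec("^(.*)_R(\\d+)$", sample_names))
  if (any(lengths(parts) != 3L)) {
    stop("cannot parse line/replicate from sample names; supply `samples`")
  }
  data.frame(sample = sample_names,
             line = vapply(parts, `[`, "", 2L),
             replicate = as.integer(vapply(parts, `[`, "", 3L)))
}

#' Read / write a sample design table
#'
#' TSV with columns `sample`, `line`, `replicate`.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame with the three design columns.
#' @export
read_design <- function(path) {
  d <- read.delim(path, colClasses = c("character", "character", "integer"))
  stopifnot(all(c("sample", "line", "replicate") %in% names(d)))
  d
}

#' @rdname read_design
#' @param design Design data frame to write.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write bioassay records
#'
#' TSV with columns `line`, `generation`, `insecticide`, `exposed`, `dead`;
#' dead counts may not exceed exposed counts.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame of bioassay records.
#' @export
read_bioassay <- function(path) {
  d <- read.delim(path)
  stopifnot(all(c("line", "generation", "insecticide", "exposed", "dead") %in% names(d)))
  if (any(d$dead < 0 | d$dead > d$exposed)) {
    stop("dead counts must lie in [0, exposed]")
  }
  d
}

#' @rdname read_bioassay
#' @param bioassay Bioassay data frame to write.
#' @export
write_bioassay <- function(bioassay, path) {
  write.table(bioassay, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an individual genotype table
#'
#' TSV with columns `generation`, `line`, `individual`, `genotype`
#' (RR/RS/SS at the monitored target-site locus).
#'
#' @param path Path to a tab-separated file.
#' @return Data frame of individual genotypes.
#' @export
read_genotypes <- function(path) {
  d <- read.delim(path, colClasses = c("integer", "character", "character", "character"))
  stopifnot(all(c("generation", "line", "individual", "genotype") %in% names(d)))
  bad <- setdiff(unique(d$genotype), c("RR", "RS", "SS"))
  if (length(bad)) stop("unknown genotype symbol(s): ", paste(bad, collapse = ", "))
  d
}

#' @rdname read_genotypes
#' @param genotypes Genotype data frame to write.
#' @export
write_genotypes <- function(genotypes, path) {
  write.table(genotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a term-to-gene annotation map
#'
#' Two-column TSV (`term`, `gene`); the mapping is many-to-many.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame with columns `term` and `gene`.
#' @export
read_terms <- function(path) {
  d <- read.delim(path, colClasses = "character")
  stopifnot(all(c("term", "gene") %in% names(d)))
  unique(d[, c("term", "gene")])
}
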