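#' Per-sample variant allele-depth table
#'
#' Holds the transcript variants the polymorphism stage consumes: one row per
#' record with 1-based position, reference and alternate allele(s), variant
#' type, and the quality annotations carried over from the caller (mean base
#' quality `bq`, variant confidence score `vcs`, strand-bias score `sb`,
#' homopolymer run length `hrun`), plus per-sample reference and alternate
#' read depths. Multi-allelic records are kept but flagged; their first two
#' alternate alleles round-trip through VCF (`alt_depth`/`alt2_depth`), and
#' the biallelic screen excludes them later.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`, `type`
#'   (`substitution` or `indel`), `multiallelic`, `bq`, `vcs`, `sb`, `hrun`.
#' @param ref_depth,alt_depth Integer matrices (records x samples) of
#'   reference- and first-alternate-supporting read depths.
#' @param alt2_depth Optional matrix of second-alternate depths (NA where
#'   biallelic).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, ref_depth, alt_depth, alt2_depth = NULL) {
  req <- c("chrom", "pos", "ref", "alt", "type", "multiallelic",
           "bq", "vcs", "sb", "hrun")
  stopifnot(all(req %in% names(sites)))
  ref_depth <- as.matrix(ref_depth); alt_depth <- as.matrix(alt_depth)
  if (nrow(sites) != nrow(ref_depth) || !identical(dim(ref_depth), dim(alt_depth))) {
    stop("depth matrices must have one row per record and matching samples")
  }
  if (is.null(colnames(ref_depth))) stop("depth matrices must have sample names")
  if (any(ref_depth < 0, na.rm = TRUE) || any(alt_depth < 0, na.rm = TRUE)) {
    stop("depths must be non-negative")
  }
  if (any(sites$pos < 1)) stop("positions are 1-based and must be >= 1")
  if (any(sites$ref == sites$alt)) stop("alternate allele equal to reference")
  if (!all(sites$type %in% c("substitution", "indel"))) {
    stop("variant type must be 'substitution' or 'indel'")
  }
  sites$site_id <- if (nrow(sites)) paste0(sites$chrom, ":", sites$pos) else character(0)
  rownames(sites) <- NULL
  if (is.null(alt2_depth)) {
    alt2_depth <- matrix(NA_integer_, nrow(ref_depth), ncol(ref_depth),
                         dimnames = dimnames(ref_depth))
  }
  structure(list(sites = sites, ref_depth = ref_depth, alt_depth = alt_depth,
                 alt2_depth = as.matrix(alt2_depth),
                 samples = colnames(ref_depth)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d records x %d samples (%d multi-allelic)\n",
              nrow(x$sites), length(x$samples), sum(x$sites$multiallelic)))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a variant table by record index
#'
#' @param vt A [variant_table()].
#' @param idx Integer or logical index over records.
#' @return The subset `variant_table`.
#' @export
subset_variants <- function(vt, idx) {
  stopifnot(inherits(vt, "variant_table"))
  variant_table(vt$sites[idx, , drop = FALSE],
                vt$ref_depth[idx, , drop = FALSE],
                vt$alt_depth[idx, , drop = FALSE],
                vt$alt2_depth[idx, , drop = FALSE])
}

#' Write a variant table as VCF 4.2
#'
#' Annotations are emitted as INFO keys `TYPE`, `BQ`, `VCS`, `SB`, `HRUN`;
#' per-sample allele depths as FORMAT `AD` (reference first, then each
#' alternate allele). Positions are written 1-based, exactly as stored.
#'
#' @param vt A [variant_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  s <- vt$sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=evoselect",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type (substitution or indel)\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality at site\">",
    "##INFO=<ID=VCS,Number=1,Type=Float,Description=\"Variant confidence score\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias score\">",
    "##INFO=<ID=HRUN,Number=1,Type=Integer,Description=\"Homopolymer run length at site\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref, alt...)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")
  )
  info <- sprintf("TYPE=%s;BQ=%g;VCS=%g;SB=%g;HRUN=%d",
                  s$type, s$bq, s$vcs, s$sb, as.integer(s$hrun))
  ad <- matrix("", nrow(s), length(vt$samples))
  for (j in seq_along(vt$samples)) {
    ad[, j] <- ifelse(s$multiallelic & !is.na(vt$alt2_depth[, j]),
                      paste(vt$ref_depth[, j], vt$alt_depth[, j],
                            vt$alt2_depth[, j], sep = ","),
                      paste(vt$ref_depth[, j], vt$alt_depth[, j], sep = ","))
  }
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", ".", info, "AD",
                apply(ad, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF 4.2 file into a variant table
#'
#' Uses `vcfR` for parsing. Per-sample allele depths must be present in the
#' FORMAT `AD` field; the INFO keys `TYPE`, `BQ`, `VCS`, `SB` and `HRUN` are
#' consumed when present (`TYPE` is inferred from allele lengths otherwise).
#' Multi-allelic records are preserved and flagged. 1-based positions are
#' preserved as is.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "##fileformat")) {
    stop("not a VCF file: missing ##fileformat header line")
  }
  check_vcf_shape(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- colnames(vcf@gt)[1]
  if (is.na(vcf@gt[1, 1]) || !("AD" %in% strsplit(vcf@gt[1, "FORMAT"], ":")[[1]])) {
    stop("FORMAT field AD (allele depths) is required")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad_split <- strsplit(as.vector(ad), ",", fixed = TRUE)
  nall <- lengths(ad_split)
  getk <- function(k) {
    v <- vapply(ad_split, function(x) if (length(x) >= k) x[k] else NA_character_,
                character(1))
    matrix(suppressWarnings(as.integer(v)), nrow = nrow(ad),
           dimnames = dimnames(ad))
  }
  ref_depth <- getk(1); alt_depth <- getk(2); alt2_depth <- getk(3)
  if (anyNA(ref_depth) || anyNA(alt_depth)) {
    stop("malformed AD entry (fewer than two allele depths)")
  }
  num_info <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  }
  type <- vcfR::extract.info(vcf, element = "TYPE")
  alt1 <- vapply(strsplit(fix[, "ALT"], ",", fixed = TRUE), `[`, "", 1L)
  if (all(is.na(type))) {
    type <- ifelse(nchar(fix[, "REF"]) == nchar(alt1) & nchar(alt1) == 1L,
                   "substitution", "indel")
  }
  sites <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], type = type,
    multiallelic = grepl(",", fix[, "ALT"], fixed = TRUE),
    bq = num_info("BQ"), vcs = num_info("VCS"), sb = num_info("SB"),
    hrun = as.integer(num_info("HRUN"))
  )
  variant_table(sites, ref_depth, alt_depth, alt2_depth)
}

check_vcf_shape <- function(path) {
  lines <- readLines(path)
  data_start <- which(startsWith(lines, "#CHROM"))
  if (!length(data_start)) stop("malformed VCF: no #CHROM header line")
  nfield <- length(strsplit(lines[data_start[1]], "\t", fixed = TRUE)[[1]])
  body <- lines[-seq_len(data_start[1])]
  body <- body[nzchar(body)]
  counts <- vapply(strsplit(body, "\t", fixed = TRUE), length, integer(1))
  bad <- which(counts != nfield)
  if (length(bad)) {
    stop(sprintf("malformed VCF record at line %d: expected %d fields, found %d",
                 data_start[1] + bad[1], nfield, counts[bad[1]]))
  }
  invisible(TRUE)
}
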