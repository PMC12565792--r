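#' Construct a genotype matrix object
#'
#' The central data container of the package: a samples-by-SNPs diploid dosage
#' matrix (count of alternate alleles, 0/1/2, `NA` = missing) together with
#' per-SNP chromosome, position and allele metadata. Only biallelic SNPs are
#' admitted; within each chromosome positions must be strictly increasing.
#'
#' @param dosage integer matrix, samples x SNPs, entries in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of unique sample identifiers (rows).
#' @param chrom character vector of per-SNP chromosome names (columns).
#' @param pos integer vector of 1-based per-SNP positions.
#' @param ref,alt single-character reference/alternate alleles per SNP.
#' @param chrom_table optional data frame with columns `name`, `length_bp`
#'   giving chromosome lengths (see [read_chrom_table()]).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids, chrom, pos,
                            ref = NULL, alt = NULL, chrom_table = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  m <- ncol(dosage)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  gm <- structure(
    list(
      sample_ids = as.character(sample_ids),
      chrom = as.character(chrom),
      pos = as.integer(pos),
      ref = as.character(ref),
      alt = as.character(alt),
      dosage = dosage,
      chrom_table = chrom_table
    ),
    class = "genotype_matrix"
  )
  rownames(gm$dosage) <- gm$sample_ids
  validate_genotype_matrix(gm)
  gm
}

#' Validate the invariants of a genotype matrix
#'
#' Checks dosage codes, dimension agreement, uniqueness of sample ids, and
#' strictly increasing positions within each chromosome. Called by the
#' constructor; exported so tests and readers can assert the contract.
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly; stops on violation.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  if (nrow(d) != length(gm$sample_ids))
    stop("dosage rows must equal number of sample_ids")
  if (anyDuplicated(gm$sample_ids))
    stop("sample_ids must be unique")
  if (ncol(d) != length(gm$chrom) || ncol(d) != length(gm$pos))
    stop("dosage columns must match chrom/pos length")
  bad <- !(is.na(d) | d == 0L | d == 1L | d == 2L)
  if (any(bad))
    stop("dosage entries must be 0, 1, 2 or NA")
  for (ch in unique(gm$chrom)) {
    p <- gm$pos[gm$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(gm$chrom_table)) {
    missing_ch <- setdiff(unique(gm$chrom), gm$chrom_table$name)
    if (length(missing_ch))
      stop("chromosomes absent from chrom_table: ",
           paste(missing_ch, collapse = ", "))
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      ncol(x$dosage), "SNPs on",
      length(unique(x$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / SNPs in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname n_samples
#' @export
n_snps <- function(gm) ncol(gm$dosage)

#' Subset a genotype matrix by SNP column index and/or sample index
#'
#' @param gm a `genotype_matrix`.
#' @param snps integer or logical index over SNP columns (optional).
#' @param samples integer or logical index over samples (optional).
#' @return the subset `genotype_matrix`.
#' @export
subset_gm <- function(gm, snps = NULL, samples = NULL) {
  if (!is.null(snps)) {
    gm$chrom <- gm$chrom[snps]
    gm$pos <- gm$pos[snps]
    gm$ref <- gm$ref[snps]
    gm$alt <- gm$alt[snps]
    gm$dosage <- gm$dosage[, snps, drop = FALSE]
  }
  if (!is.null(samples)) {
    gm$sample_ids <- gm$sample_ids[samples]
    gm$dosage <- gm$dosage[samples, , drop = FALSE]
  }
  validate_genotype_matrix(gm)
  gm
}

#' Extract SNP columns for one chromosome
#' @param gm a `genotype_matrix`.
#' @param chrom chromosome name.
#' @return integer vector of column indices.
#' @export
chrom_index <- function(gm, chrom) which(gm$chrom == chrom)
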