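#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzipped) with diploid GT fields into a
#' [genotype_matrix()]. Multiallelic records and non-SNP records (indels,
#' symbolic alleles) are skipped with a message. Genotypes with any missing
#' allele (`./.`, `.|1`, ...) become `NA`; phased and unphased genotypes are
#' treated identically, as only the alternate-allele dosage is retained.
#' Contig header lines, when present, populate the chromosome table.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param region optional region string `"chrom"` or `"chrom:start-end"`
#'   (1-based inclusive) restricting the returned SNPs.
#' @return a `genotype_matrix`; its `chrom_table` element is a data frame of
#'   contig names/lengths when the header declares them, else `NULL`.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " non-biallelic-SNP record(s)")

  keep <- which(is_snp)
  if (!is.null(region)) {
    reg <- parse_region(region)
    in_reg <- chrom == reg$chrom
    if (!is.na(reg$start)) in_reg <- in_reg & pos >= reg$start & pos <= reg$end
    keep <- intersect(keep, which(in_reg))
  }
  if (length(keep) == 0L)
    stop("no biallelic SNP records found in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(chrom))
  gt <- gt[keep, , drop = FALSE]
  dosage <- gt_to_dosage(gt)         # SNPs x samples
  ct <- contig_table(v)

  genotype_matrix(
    dosage = t(dosage),
    sample_ids = colnames(v@gt)[-1L],
    chrom = chrom[keep], pos = pos[keep],
    ref = ref[keep], alt = alt[keep],
    chrom_table = ct
  )
}

# "chr" or "chr:start-end" -> list(chrom, start, end)
parse_region <- function(region) {
  if (!grepl(":", region, fixed = TRUE))
    return(list(chrom = region, start = NA_integer_, end = NA_integer_))
  parts <- strsplit(region, "[:-]")[[1]]
  if (length(parts) != 3L) stop("malformed region string: ", region)
  list(chrom = parts[1], start = as.integer(parts[2]), end = as.integer(parts[3]))
}

# character GT matrix -> integer dosage matrix (same shape), NA for any
# genotype containing a missing allele
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  alleles1 <- substr(gt, 1L, 1L)
  alleles2 <- substr(gt, 3L, 3L)
  ok <- !is.na(gt) & alleles1 %in% c("0", "1") & alleles2 %in% c("0", "1")
  d[ok] <- (alleles1[ok] == "1") + (alleles2[ok] == "1")
  d
}

contig_table <- function(v) {
  meta <- v@meta
  cl <- grep("^##contig=", meta, value = TRUE)
  if (!length(cl)) return(NULL)
  nm <- sub(".*ID=([^,>]+).*", "\\1", cl)
  has_len <- grepl("length=", cl)
  len <- rep(NA_real_, length(cl))
  len[has_len] <- as.numeric(sub(".*length=([0-9]+).*", "\\1", cl[has_len]))
  data.frame(name = nm, length_bp = len, stringsAsFactors = FALSE)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF 4.2 text file with GT-only genotype columns, chosen so
#' that `read_vcf(write_vcf(gm))` reproduces `sample_ids`, `chrom`, `pos` and
#' `dosage` exactly (dosage 1 is written as `0/1`; missing as `./.`). Contig
#' lines are written from `gm$chrom_table` when available.
#'
#' @param gm a `genotype_matrix` with at least one sample and one SNP.
#' @param path output file path (plain text; a `.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  validate_genotype_matrix(gm)
  if (length(gm$sample_ids) == 0L) stop("cannot write VCF with zero samples")
  if (ncol(gm$dosage) == 0L) stop("cannot write VCF with zero SNPs")
  gt_code <- c("0/0", "0/1", "1/1")
  d <- gm$dosage
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]

  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(gm$chrom_table)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                gm$chrom_table$name,
                                as.integer(gm$chrom_table$length_bp)))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", gm$sample_ids),
                            collapse = "\t"))
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", ".", ".", "GT",
                sep = "\t")
  for (i in seq_len(ncol(d)))
    body[i] <- paste(c(body[i], gt[, i]), collapse = "\t")

  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ok_write <- try(writeLines(c(header, body), con), silent = TRUE)
  if (inherits(ok_write, "try-error")) stop("cannot write VCF to ", path)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Accepts either a two-column TSV (`name`, `length_bp`, no header required)
#' or a VCF whose header carries `##contig` lines; both yield the same table.
#'
#' @param path path to a TSV or VCF/VCF.gz file.
#' @return data frame with columns `name` (character) and `length_bp` (numeric).
#' @export
read_chrom_table <- function(path) {
  if (!file.exists(path)) stop("cannot read chromosome table: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE, nrows = 1)
    ct <- contig_table(v)
    if (is.null(ct)) stop("VCF header has no contig lines: ", path)
  } else {
    ct <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("name", "length_bp"),
                            colClasses = c("character", "numeric"))
  }
  if (anyDuplicated(ct$name)) stop("duplicate chromosome names in ", path)
  if (any(!is.finite(ct$length_bp)) || any(ct$length_bp <= 0))
    stop("chromosome lengths must be positive")
  ct
}

#' Look up the length of a chromosome
#' @param chrom_table data frame from [read_chrom_table()].
#' @param chrom chromosome name.
#' @return numeric length in bp; error if absent.
#' @export
chrom_length <- function(chrom_table, chrom) {
  if (is.null(chrom_table)) stop("no chromosome table available")
  i <- match(chrom, chrom_table$name)
  if (is.na(i)) stop("chromosome ", chrom, " not present in chromosome table")
  chrom_table$length_bp[i]
}
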