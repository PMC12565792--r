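#' Per-SNP alternate-allele frequency and minor allele frequency
#'
#' Frequencies are computed over non-missing samples only:
#' `freq = sum(dosage) / (2 * n_nonmissing)`. SNPs with an all-missing column
#' get `NaN` frequency and MAF, which downstream filters treat as removable.
#'
#' @param gm a `genotype_matrix`.
#' @return data frame with columns `chrom`, `pos`, `freq`, `maf`.
#' @export
allele_frequency <- function(gm) {
  stopifnot(n_snps(gm) > 0L)
  freq <- col_alt_freq(gm$dosage)
  data.frame(chrom = gm$chrom, pos = gm$pos,
             freq = freq, maf = pmin(freq, 1 - freq))
}

col_alt_freq <- function(d) {
  n_obs <- colSums(!is.na(d))
  colSums(d, na.rm = TRUE) / (2 * n_obs)
}

#' Filter SNPs and samples on MAF and missingness
#'
#' Removes SNPs with `MAF < maf_min` or per-variant missing fraction
#' `>= max_missing_frac` (an undefined MAF counts as below threshold), then
#' removes samples whose missing fraction over the surviving SNPs is
#' `>= max_missing_frac`. SNP order is preserved; counts removed at each stage
#' are reported with `message()`.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency to retain, in `[0, 0.5]`.
#' @param max_missing_frac maximum tolerated missing fraction, in `[0, 1]`.
#' @return the filtered `genotype_matrix`.
#' @export
filter_variants <- function(gm, maf_min = 0.1, max_missing_frac = 0.5) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            max_missing_frac >= 0, max_missing_frac <= 1)
  d <- gm$dosage
  maf <- pmin(col_alt_freq(d), 1 - col_alt_freq(d))
  miss_var <- colMeans(is.na(d))
  keep_snp <- !is.na(maf) & maf >= maf_min & miss_var < max_missing_frac
  message("filter_variants: removed ", sum(!keep_snp), " of ", length(keep_snp),
          " SNPs (MAF/missingness)")
  if (!any(keep_snp)) stop("no SNPs survive MAF/missingness filtering")
  gm <- subset_gm(gm, snps = keep_snp)
  miss_sample <- rowMeans(is.na(gm$dosage))
  keep_sample <- miss_sample < max_missing_frac
  message("filter_variants: removed ", sum(!keep_sample), " of ",
          length(keep_sample), " samples (missingness)")
  if (!any(keep_sample)) stop("no samples survive missingness filtering")
  subset_gm(gm, samples = keep_sample)
}

#' Windowed LD pruning of a genotype matrix
#'
#' Greedy indep-pairwise-style pruning: per chromosome, base-pair windows of
#' `window_bp` anchored at the first SNP position slide by `step_bp`; within
#' each window, while any surviving SNP pair has dosage `r^2 > r2_max`
#' (squared Pearson correlation over pairwise-complete samples), the member
#' with the lower MAF is removed (tie: the downstream SNP). After the sweep no
#' same-window pair exceeds `r2_max`.
#'
#' @param gm a `genotype_matrix`, positions sorted within chromosome.
#' @param window_bp window size in bp (default 14000).
#' @param step_bp step size in bp (default 9000).
#' @param r2_max maximum tolerated pairwise r-squared (default 0.05).
#' @return the pruned `genotype_matrix`.
#' @export
ld_prune <- function(gm, window_bp = 14000, step_bp = 9000, r2_max = 0.05) {
  keep <- rep(TRUE, n_snps(gm))
  maf <- pmin(col_alt_freq(gm$dosage), 1 - col_alt_freq(gm$dosage))
  for (ch in unique(gm$chrom)) {
    idx <- chrom_index(gm, ch)
    pos <- gm$pos[idx]
    start0 <- pos[1L]
    last <- pos[length(pos)]
    w_start <- start0
    repeat {
      w_end <- w_start + window_bp       # half-open [w_start, w_end)
      in_w <- idx[pos >= w_start & pos < w_end]
      in_w <- in_w[keep[in_w]]
      if (length(in_w) >= 2L) {
        keep[prune_window(gm$dosage, in_w, maf, r2_max)] <- FALSE
      }
      w_start <- w_start + step_bp
      if (w_start > last) break
    }
  }
  message("ld_prune: retained ", sum(keep), " of ", length(keep), " SNPs")
  subset_gm(gm, snps = keep)
}

# indices (into gm columns) to drop from one window
prune_window <- function(d, cols, maf, r2_max) {
  sub <- d[, cols, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))^2
  diag(r2) <- 0
  r2[is.na(r2)] <- 0
  alive <- rep(TRUE, length(cols))
  drop <- integer(0)
  repeat {
    r2a <- r2
    r2a[!alive, ] <- 0
    r2a[, !alive] <- 0
    mx <- max(r2a)
    if (mx <= r2_max) break
    hit <- which(r2a == mx, arr.ind = TRUE)[1L, ]
    i <- hit[["row"]]; j <- hit[["col"]]
    # remove lower-MAF member; tie -> downstream (higher position = larger col)
    victim <- if (maf[cols[i]] < maf[cols[j]]) i
              else if (maf[cols[j]] < maf[cols[i]]) j
              else max(i, j)
    alive[victim] <- FALSE
    drop <- c(drop, cols[victim])
  }
  drop
}
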