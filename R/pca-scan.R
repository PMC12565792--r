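#' Standardize dosages for PCA
#'
#' Applies the usual genotype scaling for principal component analysis:
#' column `j` becomes `(d - 2 p_j) / sqrt(2 p_j (1 - p_j))` with `p_j` the
#' alternate-allele frequency over non-missing samples. Missing entries are
#' set to 0 after centering (mean imputation). Monomorphic and zero-variance
#' columns are dropped with a message.
#'
#' @param gm a `genotype_matrix`.
#' @param chrom chromosome to standardize.
#' @return list with `z` (samples x SNPs numeric matrix) and `snp_index`
#'   (column indices of `gm` retained).
#' @export
standardize_dosage <- function(gm, chrom) {
  idx <- chrom_index(gm, chrom)
  if (length(idx) < 2L) stop("chromosome ", chrom, " has fewer than 2 SNPs")
  if (n_samples(gm) < 3L) stop("need at least 3 samples")
  d <- gm$dosage[, idx, drop = FALSE]
  p <- col_alt_freq(d)
  v <- apply(d, 2, stats::var, na.rm = TRUE)
  ok <- is.finite(p) & p > 0 & p < 1 & is.finite(v) & v > 0
  if (sum(!ok) > 0)
    message("standardize_dosage: dropped ", sum(!ok),
            " monomorphic/zero-variance SNP(s)")
  if (!any(ok)) stop("all SNPs on ", chrom, " are monomorphic")
  d <- d[, ok, drop = FALSE]
  p <- p[ok]
  z <- sweep(d, 2, 2 * p, `-`)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  z[is.na(z)] <- 0
  list(z = z, snp_index = idx[ok])
}

#' Per-chromosome principal component analysis
#'
#' PCA of the standardized dosage matrix via singular value decomposition.
#' SNP weights are the right singular vectors (unit-norm columns), sample
#' scores are left singular vectors scaled by the singular values, and
#' eigenvalues are squared singular values divided by `n_samples - 1`, so the
#' sample variance of score column `k` equals eigenvalue `k`. Each component's
#' sign is fixed so that its largest-magnitude SNP weight is positive.
#'
#' @param gm a `genotype_matrix`.
#' @param chrom chromosome name.
#' @param n_components number of components to retain (default 5); truncated
#'   with a warning if the matrix rank is lower.
#' @return object of class `inv_pca`: list with `chrom`, `scores`
#'   (samples x K), `weights` (SNPs x K), `eigenvalues` (length K),
#'   `snp_index`, `pos`, `sample_ids`.
#' @export
chromosome_pca <- function(gm, chrom, n_components = 5) {
  std <- standardize_dosage(gm, chrom)
  z <- std$z
  n <- nrow(z); m <- ncol(z)
  k_req <- min(n_components, n - 1L, m)
  if (k_req < n_components)
    warning("n_components truncated to ", k_req)

  if (n <= m) {
    G <- tcrossprod(z)                       # n x n
    eg <- eigen(G, symmetric = TRUE)
    dvals <- sqrt(pmax(eg$values, 0))
    pos_rank <- sum(dvals > max(dvals[1], 1e-12) * 1e-9)
    k <- min(k_req, pos_rank)
    if (k < k_req) warning("rank-deficient input: components truncated to ", k)
    u <- eg$vectors[, seq_len(k), drop = FALSE]
    dk <- dvals[seq_len(k)]
    w <- crossprod(z, u) %*% diag(1 / dk, k)  # m x k, unit columns
    scores <- u %*% diag(dk, k)
  } else {
    C <- crossprod(z)                        # m x m
    eg <- eigen(C, symmetric = TRUE)
    dvals <- sqrt(pmax(eg$values, 0))
    pos_rank <- sum(dvals > max(dvals[1], 1e-12) * 1e-9)
    k <- min(k_req, pos_rank)
    if (k < k_req) warning("rank-deficient input: components truncated to ", k)
    w <- eg$vectors[, seq_len(k), drop = FALSE]
    scores <- z %*% w
    dk <- dvals[seq_len(k)]
  }
  # deterministic sign: largest-|weight| entry positive per component
  for (j in seq_len(ncol(w))) {
    i_max <- which.max(abs(w[, j]))
    if (w[i_max, j] < 0) {
      w[, j] <- -w[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(chrom = chrom, scores = scores, weights = w,
         eigenvalues = dk^2 / (n - 1), snp_index = std$snp_index,
         pos = gm$pos[std$snp_index], sample_ids = gm$sample_ids),
    class = "inv_pca"
  )
}

#' @export
print.inv_pca <- function(x, ...) {
  cat("inv_pca: chromosome", x$chrom, "-", nrow(x$scores), "samples,",
      nrow(x$weights), "SNPs,", length(x$eigenvalues), "components\n")
  pve <- x$eigenvalues / sum(x$eigenvalues)
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  cat("  proportion of retained variance:",
      paste(sprintf("%.3f", pve), collapse = " "), "\n")
  invisible(x)
}

#' Sliding-window variance of SNP weights
#'
#' The inversion footprint statistic: within base-pair windows (default
#' 10 kbp, step 7.5 kbp, anchored at the chromosome's first SNP position,
#' half-open `[start, start + window)`), the unbiased sample variance of one
#' component's SNP weights. Windows holding fewer than `min_snps` SNPs carry
#' `NA`.
#'
#' @param pca an `inv_pca`.
#' @param component component number (1-based).
#' @param window_bp window size in bp (default 10000).
#' @param step_bp step size in bp (default 7500).
#' @param min_snps minimum SNPs for a defined variance (default 3).
#' @return data frame with columns `chrom`, `component`, `start`, `end`,
#'   `n_snps`, `value`.
#' @export
windowed_weight_variance <- function(pca, component, window_bp = 10000,
                                     step_bp = 7500, min_snps = 3) {
  stopifnot(component >= 1, component <= ncol(pca$weights))
  w <- pca$weights[, component]
  sliding_window_stat(
    pos = pca$pos, values = w, anchor = pca$pos[1L],
    last = pca$pos[length(pca$pos)],
    window_bp = window_bp, step_bp = step_bp, min_n = min_snps,
    stat = function(x) stats::var(x),
    chrom = pca$chrom, component = component
  )
}

# shared sliding-window machinery: positions must be sorted ascending
sliding_window_stat <- function(pos, values, anchor, last, window_bp, step_bp,
                                min_n, stat, chrom, component = NA_integer_) {
  starts <- seq(anchor, last, by = step_bp)
  lo <- findInterval(starts - 0.5, pos) + 1L          # first pos >= start
  hi <- findInterval(starts + window_bp - 0.5, pos)   # last pos < start+window
  n_in <- pmax(hi - lo + 1L, 0L)
  val <- rep(NA_real_, length(starts))
  for (i in which(n_in >= min_n))
    val[i] <- stat(values[lo[i]:hi[i]])
  data.frame(chrom = chrom, component = component,
             start = starts, end = starts + window_bp,
             n_snps = n_in, value = val)
}

#' Detect candidate inversion regions from a window-variance profile
#'
#' A window is flagged when its variance exceeds the `flag_quantile`
#' quantile or `flag_fold` times the median of all defined window values.
#' The quantile clause picks up the profile's upper tail; the fold-over-median
#' clause lets a broad elevated block (an inversion spanning a large
#' chromosome fraction, where the upper quantile itself sits inside the
#' block) be flagged contiguously, while on a flat profile neither clause
#' fires over noise alone.
#' Flagged windows are chained, tolerating up to `max_gap` consecutive
#' unflagged windows; chains with at least `min_run` flagged windows become
#' candidate regions spanning the first to last flagged window.
#'
#' @param windows data frame from [windowed_weight_variance()] for one
#'   chromosome-component.
#' @param flag_quantile quantile threshold on window values (default 0.95).
#' @param flag_fold fold-over-median threshold (default 5).
#' @param min_run minimum flagged windows per region (default 10).
#' @param max_gap maximum unflagged windows bridged inside a region (default 2).
#' @return data frame with columns `chrom`, `component`, `start`, `end`,
#'   `peak_value`, `n_windows`, sorted by decreasing `peak_value`.
#' @export
detect_candidate_regions <- function(windows, flag_quantile = 0.95,
                                     flag_fold = 5.0, min_run = 10,
                                     max_gap = 2) {
  vals <- windows$value
  defined <- which(!is.na(vals))
  if (length(defined) < 20L)
    stop("fewer than 20 defined windows; insufficient resolution")
  thr_q <- stats::quantile(vals[defined], flag_quantile, names = FALSE)
  thr_f <- flag_fold * stats::median(vals[defined])
  flagged <- !is.na(vals) & (vals > thr_q | vals > thr_f)

  out <- list()
  i <- 1L
  nw <- nrow(windows)
  while (i <= nw) {
    if (!flagged[i]) { i <- i + 1L; next }
    run_start <- i
    last_flag <- i
    j <- i + 1L
    gap <- 0L
    while (j <= nw) {
      if (flagged[j]) { last_flag <- j; gap <- 0L }
      else { gap <- gap + 1L; if (gap > max_gap) break }
      j <- j + 1L
    }
    members <- run_start:last_flag
    n_flag <- sum(flagged[members])
    if (n_flag >= min_run) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = windows$chrom[1L], component = windows$component[1L],
        start = windows$start[run_start], end = windows$end[last_flag],
        peak_value = max(vals[members], na.rm = TRUE), n_windows = n_flag)
    }
    i <- last_flag + 1L
  }
  if (!length(out))
    return(data.frame(chrom = character(), component = integer(),
                      start = numeric(), end = numeric(),
                      peak_value = numeric(), n_windows = integer()))
  res <- do.call(rbind, out)
  res[order(-res$peak_value), , drop = FALSE]
}
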