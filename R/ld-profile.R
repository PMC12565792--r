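#' Genotypic r-squared between two dosage vectors
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples
#' (the composite genotypic LD measure). Returns `NA` when fewer than 3
#' complete pairs remain or either vector is constant on the complete set.
#'
#' @param d_a,d_b integer dosage vectors of equal length (NA = missing).
#' @return squared correlation in `[0, 1]`, or `NA`.
#' @export
pair_r2 <- function(d_a, d_b) {
  ok <- !is.na(d_a) & !is.na(d_b)
  if (sum(ok) < 3L) return(NA_real_)
  a <- d_a[ok]; b <- d_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Collect short-range SNP pairs with their r-squared
#'
#' All SNP pairs on one chromosome with `0 < pos_b - pos_a <= max_dist`,
#' with r-squared computed as in [pair_r2()]; pairs with undefined r-squared
#' are skipped with a message.
#'
#' @param gm a `genotype_matrix` (positions sorted within chromosome).
#' @param chrom chromosome name.
#' @param max_dist maximum pair distance in bp (default 12000).
#' @param min_dist minimum pair distance in bp (default 0, exclusive), for
#'   the banded 12-13 kbp reading.
#' @return data frame with columns `chrom`, `pos_a`, `pos_b`, `r2`,
#'   `midpoint`.
#' @export
collect_pairs <- function(gm, chrom, max_dist = 12000, min_dist = 0) {
  idx <- chrom_index(gm, chrom)
  pos <- gm$pos[idx]
  d <- gm$dosage[, idx, drop = FALSE]
  obs <- !is.na(d)
  dz <- d; dz[!obs] <- 0L
  storage.mode(dz) <- "double"
  obs <- obs + 0

  m <- length(pos)
  pa <- pb <- r2 <- list()
  n_skipped <- 0L
  k <- 1L
  while (k < m) {
    dist <- pos[(1L + k):m] - pos[1L:(m - k)]
    sel <- which(dist > min_dist & dist <= max_dist)
    if (!length(sel)) {
      if (min(dist) > max_dist) break     # sorted positions: gaps only grow
      k <- k + 1L
      next
    }
    i <- sel; j <- sel + k
    w <- obs[, i, drop = FALSE] * obs[, j, drop = FALSE]
    a <- dz[, i, drop = FALSE] * w
    b <- dz[, j, drop = FALSE] * w
    n <- colSums(w)
    sa <- colSums(a); sb <- colSums(b)
    saa <- colSums(a * a); sbb <- colSums(b * b); sab <- colSums(a * b)
    va <- saa - sa^2 / n
    vb <- sbb - sb^2 / n
    cov <- sab - sa * sb / n
    r2k <- ifelse(n >= 3 & va > 1e-12 & vb > 1e-12, cov^2 / (va * vb), NA_real_)
    bad <- is.na(r2k)
    n_skipped <- n_skipped + sum(bad)
    pa[[k]] <- pos[i][!bad]; pb[[k]] <- pos[j][!bad]; r2[[k]] <- r2k[!bad]
    k <- k + 1L
  }
  if (n_skipped > 0)
    message("collect_pairs: skipped ", n_skipped, " undefined pair(s)")
  pos_a <- unlist(pa); pos_b <- unlist(pb); r2v <- unlist(r2)
  if (is.null(pos_a))
    return(data.frame(chrom = character(), pos_a = integer(),
                      pos_b = integer(), r2 = numeric(),
                      midpoint = numeric()))
  ord <- order(pos_a, pos_b)
  data.frame(chrom = chrom, pos_a = pos_a[ord], pos_b = pos_b[ord],
             r2 = r2v[ord], midpoint = (pos_a[ord] + pos_b[ord]) / 2)
}

#' Windowed median r-squared profile
#'
#' Sliding windows sized as a fraction of the chromosome length (default
#' 0.5%, step half a window, anchored at position 1); a pair belongs to a
#' window when its midpoint lies inside `[start, start + window)`. Windows
#' with fewer than `min_pairs` pairs carry `NA`.
#'
#' @param pairs data frame from [collect_pairs()].
#' @param chrom_length_bp chromosome length in bp.
#' @param window_frac window length as a fraction of the chromosome
#'   (default 0.005).
#' @param step_frac step as a fraction (default 0.0025).
#' @param min_pairs minimum pairs per defined window (default 5).
#' @return data frame with columns `chrom`, `start`, `end`, `n_pairs`,
#'   `value` (median r-squared).
#' @export
windowed_median_r2 <- function(pairs, chrom_length_bp, window_frac = 0.005,
                               step_frac = 0.0025, min_pairs = 5) {
  if (missing(chrom_length_bp) || is.null(chrom_length_bp) ||
      !is.finite(chrom_length_bp))
    stop("chromosome length is required for fractional LD windows")
  window_bp <- round(window_frac * chrom_length_bp)
  step_bp <- max(1, round(step_frac * chrom_length_bp))
  if (nrow(pairs) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_pairs = integer(), value = numeric()))
  ord <- order(pairs$midpoint)
  mid <- pairs$midpoint[ord]
  r2 <- pairs$r2[ord]
  out <- sliding_window_stat(
    pos = mid, values = r2, anchor = 1, last = chrom_length_bp - 1,
    window_bp = window_bp, step_bp = step_bp, min_n = min_pairs,
    stat = stats::median, chrom = pairs$chrom[1L]
  )
  names(out)[names(out) == "n_snps"] <- "n_pairs"
  out$component <- NULL
  out
}

#' Spearman correlation between LD profile and mean absolute SNP weights
#'
#' On the LD window grid, computes the mean absolute PCA weight of the SNPs
#' falling in each window and correlates it (Spearman, average ranks for
#' ties, two-sided asymptotic p) with the window median r-squared over
#' windows where both are defined.
#'
#' @param windowed_r2 data frame from [windowed_median_r2()].
#' @param pca an `inv_pca` for the same chromosome.
#' @param component component number.
#' @return list with `chrom`, `component`, `rho`, `p_value`, `n_windows`;
#'   `NULL` (with a warning) when fewer than 5 complete window pairs exist.
#' @export
weight_ld_correlation <- function(windowed_r2, pca, component) {
  aw <- abs(pca$weights[, component])
  pos <- pca$pos
  mean_w <- mapply(function(s, e) {
    sel <- pos >= s & pos < e
    if (any(sel)) mean(aw[sel]) else NA_real_
  }, windowed_r2$start, windowed_r2$end)
  ok <- !is.na(windowed_r2$value) & !is.na(mean_w)
  if (sum(ok) < 5L) {
    warning("fewer than 5 windows with both r2 and weight values")
    return(NULL)
  }
  ct <- suppressWarnings(
    stats::cor.test(windowed_r2$value[ok], mean_w[ok],
                    method = "spearman", exact = FALSE)
  )
  list(chrom = windowed_r2$chrom[1L], component = component,
       rho = unname(ct$estimate), p_value = ct$p.value, n_windows = sum(ok))
}
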