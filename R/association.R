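#' Per-SNP association scan of karyotype phenotype on dosage
#'
#' Ordinary least-squares of the quantitative karyotype phenotype (AA, AB,
#' BB coded 0, 1, 2) on SNP dosage, one SNP at a time over pairwise-complete
#' samples, with a two-sided t-test on the slope. Monomorphic SNPs (on the
#' complete set) get `beta = 0`, `p = 1`. Bonferroni correction uses
#' `M` = the number of polymorphic SNPs tested on the chromosome.
#'
#' @param gm a `genotype_matrix`.
#' @param chrom chromosome to scan.
#' @param phenotype numeric vector over `gm` samples with values in
#'   `{0, 1, 2}` (NA allowed for uncalled samples).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data frame of class `inv_assoc` with columns `chrom`, `pos`,
#'   `beta`, `se`, `p`, `p_adj`, `significant`; attribute `M` holds the
#'   Bonferroni denominator.
#' @export
association_scan <- function(gm, chrom, phenotype, alpha = 0.05) {
  stopifnot(length(phenotype) == n_samples(gm))
  y_all <- as.numeric(phenotype)
  if (length(unique(y_all[!is.na(y_all)])) < 2L)
    stop("phenotype is constant; association scan is degenerate")
  idx <- chrom_index(gm, chrom)
  x <- gm$dosage[, idx, drop = FALSE]

  w <- (!is.na(x)) & !is.na(y_all)          # complete mask per SNP
  xz <- x; xz[!w] <- 0
  yz <- matrix(y_all, nrow(x), ncol(x))
  yz[!w] <- 0

  n_c <- colSums(w)
  sx <- colSums(xz);  sy <- colSums(yz)
  sxx <- colSums(xz^2); syy <- colSums(yz^2); sxy <- colSums(xz * yz)
  sxx_c <- sxx - sx^2 / n_c
  syy_c <- syy - sy^2 / n_c
  sxy_c <- sxy - sx * sy / n_c

  poly <- is.finite(sxx_c) & sxx_c > 1e-12 & n_c >= 3L
  beta <- se <- rep(0, length(idx))
  p <- rep(1, length(idx))
  beta[poly] <- sxy_c[poly] / sxx_c[poly]
  sse <- pmax(syy_c[poly] - beta[poly] * sxy_c[poly], 0)
  df <- n_c[poly] - 2L
  se[poly] <- sqrt(sse / df / sxx_c[poly])
  tt <- ifelse(se[poly] > 0, beta[poly] / se[poly], Inf * sign(beta[poly]))
  p[poly] <- 2 * stats::pt(-abs(tt), df)

  M <- sum(poly)
  # monomorphic SNPs sit at p = 1 and are not part of the family of M tests
  p_adj <- pmin(1, p * M)
  p_adj[!poly] <- 1
  res <- data.frame(chrom = chrom, pos = gm$pos[idx], beta = beta, se = se,
                    p = p, p_adj = p_adj, significant = p_adj < alpha)
  attr(res, "M") <- M
  class(res) <- c("inv_assoc", class(res))
  res
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * M)` elementwise; `M` may exceed the vector length
#' (e.g. all SNPs tested on the chromosome while only a subset is passed).
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param M number of tests (default `length(pvals)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, M = length(pvals)) {
  stopifnot(M >= length(pvals))
  pmin(1, pvals * M)
}

#' Estimate inversion coordinates from an association scan
#'
#' Significant SNPs are grouped by single-linkage clustering with inter-SNP
#' gap at most `merge_gap_bp`; the cluster holding the most significant SNPs
#' (tie: the larger span) yields the coordinate estimate as the minimum and
#' maximum significant position within it.
#'
#' @param results an `inv_assoc` data frame from [association_scan()].
#' @param alpha significance level (default 0.05), applied to `p_adj`.
#' @param merge_gap_bp maximum gap joining SNPs into one cluster
#'   (default 1e6).
#' @return list with `start`, `end` (1-based inclusive), `n_significant`;
#'   or `NULL` (with a message) when no SNP is significant.
#' @export
estimate_coordinates <- function(results, alpha = 0.05, merge_gap_bp = 1e6) {
  sig_pos <- sort(results$pos[results$p_adj < alpha])
  if (!length(sig_pos)) {
    message("estimate_coordinates: no significant SNPs; no estimate")
    return(NULL)
  }
  brk <- c(0, which(diff(sig_pos) > merge_gap_bp), length(sig_pos))
  best <- NULL
  for (i in seq_len(length(brk) - 1L)) {
    members <- sig_pos[(brk[i] + 1L):brk[i + 1L]]
    cand <- list(start = members[1L], end = members[length(members)],
                 n_significant = length(members))
    if (is.null(best) ||
        cand$n_significant > best$n_significant ||
        (cand$n_significant == best$n_significant &&
         (cand$end - cand$start) > (best$end - best$start)))
      best <- cand
  }
  best
}
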