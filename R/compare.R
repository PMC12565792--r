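#' Pairwise dependence tests between detected inversions
#'
#' For every unordered pair of retained inversions: Spearman correlation of
#' the genotype codes (AA = 0, AB = 1, BB = 2 under each inversion's own
#' orientation) over shared samples, and a chi-square test (asymptotic, no
#' continuity correction, zero-margin rows/columns dropped) on the up-to-3x3
#' contingency table. Spearman p-values of pairs with at least `min_shared`
#' shared samples form one Benjamini-Hochberg family; low-n pairs are
#' flagged and excluded from the family.
#'
#' @param karyotypes list of `inv_karyotype` objects (or any lists with
#'   `inversion_id` and `calls` with `sample_id`/`genotype`).
#' @param min_shared minimum shared samples for the FDR family (default 10).
#' @param fdr_alpha significance level on the adjusted p (default 0.05).
#' @return data frame with columns `inv_a`, `inv_b`, `n_shared`, `rho`,
#'   `p_raw`, `p_fdr`, `chi2`, `chi2_p`, `low_n`, `significant`.
#' @export
pairwise_inversion_tests <- function(karyotypes, min_shared = 10,
                                     fdr_alpha = 0.05) {
  if (length(karyotypes) < 2L)
    stop("need at least 2 inversions for pairwise tests")
  code <- c(AA = 0, AB = 1, BB = 2)
  rows <- list()
  for (i in seq_len(length(karyotypes) - 1L)) {
    for (j in (i + 1L):length(karyotypes)) {
      a <- karyotypes[[i]]; b <- karyotypes[[j]]
      shared <- intersect(a$calls$sample_id, b$calls$sample_id)
      ga <- code[a$calls$genotype[match(shared, a$calls$sample_id)]]
      gb <- code[b$calls$genotype[match(shared, b$calls$sample_id)]]
      n <- length(shared)
      if (n >= 3L && stats::sd(ga) > 0 && stats::sd(gb) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(ga, gb, method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate); p_raw <- ct$p.value
      } else {
        rho <- NA_real_; p_raw <- NA_real_
      }
      tab <- table(factor(ga, levels = 0:2), factor(gb, levels = 0:2))
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
        cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        chi2 <- unname(cs$statistic); chi2_p <- cs$p.value
      } else {
        chi2 <- NA_real_; chi2_p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        inv_a = a$inversion_id, inv_b = b$inversion_id, n_shared = n,
        rho = rho, p_raw = p_raw, chi2 = chi2, chi2_p = chi2_p,
        low_n = n < min_shared, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- NA_real_
  fam <- which(!res$low_n & !is.na(res$p_raw))
  if (length(fam)) res$p_fdr[fam] <- bh_adjust(res$p_raw[fam])
  res$significant <- !is.na(res$p_fdr) & res$p_fdr <= fdr_alpha
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort p ascending, `q_i = p_i * m / i`, enforce
#' monotonicity from the largest down, cap at 1, return in input order.
#' Equivalent to `stats::p.adjust(method = "BH")`, which it delegates to.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}
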