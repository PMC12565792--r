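#' Select the top-weight SNPs of a component
#'
#' Retains the `ceiling(fraction * n_snps)` SNPs with the largest absolute
#' weight on one principal component, over the whole chromosome the PCA was
#' fitted on. Ties at the cut are broken towards the lower position.
#'
#' @param pca an `inv_pca`.
#' @param component component number.
#' @param fraction fraction of SNPs to keep, in `(0, 1]` (default 0.01).
#' @return integer vector of `gm` column indices (subset of `pca$snp_index`),
#'   sorted by position.
#' @export
select_top_weight_snps <- function(pca, component, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  aw <- abs(pca$weights[, component])
  n_keep <- ceiling(fraction * length(aw))
  ord <- order(-aw, pca$pos)        # largest |weight| first; ties: lower pos
  sel <- ord[seq_len(n_keep)]
  if (n_keep < 2L) stop("fewer than 2 top-weight SNPs selected")
  if (n_keep < 10L) warning("fewer than 10 top-weight SNPs selected")
  sort(pca$snp_index[sel])
}

#' Identity-by-state similarity matrix
#'
#' `IBS(i, j)` is the mean over the SNP subset (pairwise-complete) of
#' `(2 - |d_i - d_j|) / 2`, i.e. the proportion of alleles shared between two
#' samples. Symmetric with unit diagonal.
#'
#' @param gm a `genotype_matrix`.
#' @param snp_subset integer vector of SNP column indices.
#' @return samples x samples numeric matrix in `[0, 1]`.
#' @export
ibs_matrix <- function(gm, snp_subset) {
  stopifnot(length(snp_subset) >= 1L, n_samples(gm) >= 2L)
  d <- gm$dosage[, snp_subset, drop = FALSE]
  obs <- !is.na(d)
  a0 <- (!is.na(d) & d == 0L) + 0
  a1 <- (!is.na(d) & d == 1L) + 0
  a2 <- (!is.na(d) & d == 2L) + 0
  # sum over shared SNPs of |d_i - d_j|
  s <- tcrossprod(a0, a1) + tcrossprod(a1, a0) +
       tcrossprod(a1, a2) + tcrossprod(a2, a1) +
       2 * (tcrossprod(a0, a2) + tcrossprod(a2, a0))
  n_shared <- tcrossprod(obs + 0)
  if (any(n_shared == 0))
    stop("sample pair(s) share zero non-missing SNPs in the subset")
  ibs <- 1 - s / (2 * n_shared)
  dimnames(ibs) <- list(gm$sample_ids, gm$sample_ids)
  ibs
}

#' Classical multidimensional scaling of an IBS similarity matrix
#'
#' Embeds samples in `k` dimensions by classical (Torgerson) MDS of the
#' distance `D = 1 - IBS` via `stats::cmdscale`; negative eigenvalues are
#' discarded, and each returned axis is sign-fixed so that the
#' largest-magnitude coordinate is positive. If fewer than `k` positive
#' eigenvalues exist, fewer columns are returned with a warning.
#'
#' @param similarity symmetric samples x samples similarity with unit diagonal.
#' @param k number of dimensions (1 for karyotype clustering, 2 for biplots).
#' @return samples x k (or fewer) coordinate matrix.
#' @export
classical_mds <- function(similarity, k = 1) {
  stopifnot(isSymmetric(unname(similarity), tol = 1e-8))
  d <- 1 - similarity
  diag(d) <- 0
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  if (ncol(pts) < k)
    warning("only ", ncol(pts), " positive-eigenvalue dimension(s) available")
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(similarity)
  pts
}

#' Fuzzy c-means clustering of a one-dimensional embedding
#'
#' Standard fuzzy c-means with fuzzifier `m`: centers are membership^m
#' weighted means, memberships follow the inverse-distance^(2/(m-1))
#' normalization, iterated until the largest center shift falls below `tol`.
#' Initialization is deterministic and range-based: centers start at the
#' 1% quantile, the 99% quantile, and their midpoint. Because the three
#' karyotype clusters of an inversion sit at near-equal spacing on the 1-D
#' embedding, range-based starts land one center near each cluster
#' regardless of how unbalanced the cluster sizes are (under Hardy-Weinberg
#' the minor homozygote class can hold under 10% of samples, where
#' probability-quantile starts collapse onto the two big clusters and hit a
#' local optimum). Collided centers get a tiny seed-controlled jitter. A
#' point coinciding with a center receives membership 1 for that cluster.
#'
#' @param coords numeric vector (or single-column matrix) of 1-D coordinates.
#' @param c number of clusters (default 3).
#' @param m fuzzifier, `> 1` (default 2).
#' @param tol convergence tolerance on center movement (default 1e-6).
#' @param max_iter iteration cap (default 500); non-convergence warns and
#'   returns the best state.
#' @param seed integer seed used only if jitter is needed (default 1).
#' @return list with `memberships` (samples x c, rows sum to 1), `centers`
#'   (ascending), `iterations`, `converged`.
#' @export
fuzzy_cmeans <- function(coords, c = 3, m = 2.0, tol = 1e-6, max_iter = 500,
                         seed = 1) {
  x <- as.numeric(coords)
  n <- length(x)
  if (length(unique(x)) < c)
    stop("need at least ", c, " distinct coordinate values")
  lo <- stats::quantile(x, 0.01, names = FALSE)
  hi <- stats::quantile(x, 0.99, names = FALSE)
  centers <- if (c == 1L) (lo + hi) / 2 else
    lo + (hi - lo) * (seq_len(c) - 1) / (c - 1)
  if (anyDuplicated(centers)) {
    set.seed(seed)
    centers <- centers + stats::rnorm(c, 0, 1e-8 + stats::sd(x) * 1e-6)
  }
  centers <- sort(centers)
  expo <- 2 / (m - 1)
  converged <- FALSE
  iter <- 0L
  u <- matrix(0, n, c)
  repeat {
    iter <- iter + 1L
    dist2 <- abs(outer(x, centers, `-`))
    # memberships: u_ik = 1 / sum_j (d_ik / d_ij)^expo, with the
    # degenerate-distance convention for points lying on a center
    zero_row <- dist2 < .Machine$double.eps
    inv <- (1 / pmax(dist2, .Machine$double.eps))^expo
    u <- inv / rowSums(inv)
    hit <- which(rowSums(zero_row) > 0)
    if (length(hit)) {
      u[hit, ] <- 0
      u[cbind(hit, max.col(-dist2[hit, , drop = FALSE]))] <- 1
    }
    um <- u^m
    new_centers <- as.numeric(crossprod(um, x) / colSums(um))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # memberships consistent with the final centers
  dist2 <- abs(outer(x, centers, `-`))
  zero_row <- dist2 < .Machine$double.eps
  inv <- (1 / pmax(dist2, .Machine$double.eps))^expo
  u <- inv / rowSums(inv)
  hit <- which(rowSums(zero_row) > 0)
  if (length(hit)) {
    u[hit, ] <- 0
    u[cbind(hit, max.col(-dist2[hit, , drop = FALSE]))] <- 1
  }
  if (!converged) warning("fuzzy_cmeans did not converge in ", max_iter,
                          " iterations")
  ord <- order(centers)
  list(memberships = u[, ord, drop = FALSE], centers = centers[ord],
       iterations = iter, converged = converged)
}

#' Call AA/AB/BB inversion karyotypes from a fuzzy clustering
#'
#' Assigns each sample the genotype of its maximal-membership cluster.
#' Orientation follows the convention that the larger homozygote cluster
#' (an extreme center) is `AA`, the other extreme `BB`, and the middle
#' center `AB`, so the minor-arrangement frequency is at most 0.5. The call
#' set is retained only when all three clusters have at least
#' `min_cluster_size` members, the mean maximal membership is at least
#' `min_mean_membership`, and the middle center sits within
#' `spacing_window` of the span between the extreme centers.
#'
#' @param fcm result of [fuzzy_cmeans()] with `c = 3`.
#' @param sample_ids character vector of sample names.
#' @param min_cluster_size minimum samples per cluster (default 3).
#' @param min_mean_membership minimum mean maximal membership (default 0.8).
#' @param spacing_window admissible relative position of the middle center
#'   between the extremes (default `c(0.3, 0.7)`).
#' @return list with `calls` (data frame: `sample_id`, `genotype`, `m_AA`,
#'   `m_AB`, `m_BB`, `mds1`), `retained` (logical), `reason` (string),
#'   `centers` (named, AA/AB/BB order).
#' @export
call_karyotypes <- function(fcm, sample_ids, min_cluster_size = 3,
                            min_mean_membership = 0.8,
                            spacing_window = c(0.3, 0.7)) {
  u <- fcm$memberships
  stopifnot(ncol(u) == 3L)
  centers <- fcm$centers              # ascending
  cl <- max.col(u, ties.method = "first")
  sizes <- tabulate(cl, nbins = 3L)

  # orientation: clusters 1 and 3 are the homozygotes; larger one is AA
  if (sizes[1] >= sizes[3]) map <- c("AA", "AB", "BB") else map <- c("BB", "AB", "AA")
  genotype <- map[cl]
  g_order <- match(c("AA", "AB", "BB"), map)

  retained <- TRUE
  reason <- ""
  if (any(sizes < min_cluster_size)) {
    retained <- FALSE; reason <- "cluster size"
  }
  mean_max_u <- mean(u[cbind(seq_len(nrow(u)), cl)])
  if (retained && mean_max_u < min_mean_membership) {
    retained <- FALSE; reason <- "membership"
  }
  rel <- (centers[2] - centers[1]) / (centers[3] - centers[1])
  if (retained && !is.finite(rel)) {
    retained <- FALSE; reason <- "center spacing"
  }
  if (retained && (rel < spacing_window[1] || rel > spacing_window[2])) {
    retained <- FALSE; reason <- "center spacing"
  }

  mds1 <- if (!is.null(fcm$coords)) fcm$coords else rep(NA_real_, nrow(u))
  calls <- data.frame(
    sample_id = sample_ids, genotype = genotype,
    m_AA = u[, g_order[1]], m_AB = u[, g_order[2]], m_BB = u[, g_order[3]],
    mds1 = mds1, stringsAsFactors = FALSE
  )
  list(calls = calls, retained = retained, reason = reason,
       centers = stats::setNames(centers[g_order], c("AA", "AB", "BB")),
       mean_max_membership = mean_max_u, spacing_ratio = rel)
}

#' Inversion frequency and fixation index of a karyotype call set
#'
#' Treats the inversion as a biallelic locus: with counts
#' `(n_AA, n_AB, n_BB)` and `n` samples, the minor-arrangement frequency is
#' `q = (2 n_BB + n_AB) / (2 n)`, observed heterozygosity `H_obs = n_AB / n`,
#' expected `H_exp = 2 q (1 - q)`, and the fixation index
#' `F = 1 - H_obs / H_exp` (0 when `H_exp = 0`).
#'
#' @param calls data frame with a `genotype` column of `"AA"/"AB"/"BB"`.
#' @return list with `counts` (named), `inv_maf`, `f_index`.
#' @export
inversion_summary <- function(calls) {
  g <- factor(calls$genotype, levels = c("AA", "AB", "BB"))
  counts <- table(g)
  n <- sum(counts)
  q <- (2 * counts[["BB"]] + counts[["AB"]]) / (2 * n)
  h_obs <- counts[["AB"]] / n
  h_exp <- 2 * q * (1 - q)
  f <- if (h_exp == 0) 0 else 1 - h_obs / h_exp
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       inv_maf = q, f_index = f)
}

#' Karyotype one candidate chromosome-component
#'
#' Convenience wrapper running the full genotyping chain for one component:
#' top-weight SNP selection, IBS matrix, classical MDS at `k = 1`, fuzzy
#' c-means with 3 clusters, karyotype calling and the frequency/fixation
#' summary. MDS coordinates at `k = 2` are attached for plotting.
#'
#' @param gm a `genotype_matrix`.
#' @param pca an `inv_pca` for the same chromosome.
#' @param component component number.
#' @param top_fraction fraction of SNPs kept by absolute weight (default 0.01).
#' @param seed passed to [fuzzy_cmeans()].
#' @param ... further arguments to [call_karyotypes()].
#' @return object of class `inv_karyotype`: the [call_karyotypes()] result
#'   plus `inversion_id`, `chrom`, `component`, `summary`, `mds2`,
#'   `snp_subset`.
#' @export
karyotype_component <- function(gm, pca, component, top_fraction = 0.01,
                                seed = 1, ...) {
  subset <- select_top_weight_snps(pca, component, top_fraction)
  ibs <- ibs_matrix(gm, subset)
  mds1 <- classical_mds(ibs, k = 1)
  mds2 <- tryCatch(classical_mds(ibs, k = 2), warning = function(w) NULL)
  fcm <- fuzzy_cmeans(mds1[, 1], c = 3, seed = seed)
  fcm$coords <- mds1[, 1]
  res <- call_karyotypes(fcm, gm$sample_ids, ...)
  res$inversion_id <- paste0(pca$chrom, ":C", component)
  res$chrom <- pca$chrom
  res$component <- component
  res$summary <- inversion_summary(res$calls)
  res$mds2 <- mds2
  res$snp_subset <- subset
  class(res) <- "inv_karyotype"
  res
}

#' @export
print.inv_karyotype <- function(x, ...) {
  s <- x$summary
  cat("inv_karyotype", x$inversion_id, if (x$retained) "(retained)" else
      paste0("(dropped: ", x$reason, ")"), "\n")
  cat(sprintf("  AA/AB/BB: %d/%d/%d  inv MAF: %.3f  F: %.3f\n",
              s$counts[["AA"]], s$counts[["AB"]], s$counts[["BB"]],
              s$inv_maf, s$f_index))
  invisible(x)
}
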