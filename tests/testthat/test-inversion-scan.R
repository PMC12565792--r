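test_that("standardize_dosage applies the genotype PCA scaling", {
  # (d - 2p) / sqrt(2 p (1-p)); column (0,1,2) has p = 0.5
  gm <- make_gm(cbind(c(0L, 1L, 2L), c(0L, 0L, 2L), c(1L, 1L, 1L)))
  std <- suppressMessages(standardize_dosage(gm, "1"))
  expect_equal(std$snp_index, c(1L, 2L))      # zero-variance column dropped
  expect_equal(unname(std$z[, 1]), (c(0, 1, 2) - 1) / sqrt(0.5))
  # missing entries become 0 after centering
  gm2 <- make_gm(cbind(c(0L, NA, 2L, 1L, 1L), c(0L, 1L, 2L, 0L, 1L)))
  std2 <- standardize_dosage(gm2, "1")
  expect_equal(unname(std2$z[2, 1]), 0)
  expect_error(standardize_dosage(make_gm(cbind(c(1L, 1L, 1L), c(2L, 2L, 2L))), "1"),
               "monomorphic")
})

test_that("chromosome_pca matches a brute-force covariance eigendecomposition", {
  for (seed in c(2, 5, 8)) {
    gm <- random_gm(n = 15, m = 20, seed = seed)
    pca <- chromosome_pca(gm, "1", n_components = 5)
    std <- standardize_dosage(gm, "1")
    cv <- cov(std$z)                          # brute-force oracle
    eg <- eigen(cv, symmetric = TRUE)
    expect_equal(pca$eigenvalues, eg$values[1:5], tolerance = 1e-8)
    for (k in 1:5) {
      dot <- abs(sum(pca$weights[, k] * eg$vectors[, k]))
      expect_equal(dot, 1, tolerance = 1e-8)  # same axis up to sign
    }
    # weight columns orthonormal; score variance equals eigenvalue
    expect_equal(crossprod(pca$weights), diag(5), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(apply(pca$scores, 2, var), pca$eigenvalues,
                 tolerance = 1e-8, ignore_attr = TRUE)
    # deterministic sign convention
    expect_true(all(apply(pca$weights, 2,
                          function(w) w[which.max(abs(w))] > 0)))
  }
})

test_that("two anticorrelated SNPs put all variance on PC1 with equal weights", {
  d <- cbind(c(0L, 0L, 2L, 2L, 0L, 2L), c(2L, 2L, 0L, 0L, 2L, 0L))
  pca <- suppressWarnings(chromosome_pca(make_gm(d), "1", n_components = 2))
  expect_equal(abs(unname(pca$weights[, 1])), c(1, 1) / sqrt(2),
               tolerance = 1e-10)
  expect_gt(pca$eigenvalues[1] / sum(pca$eigenvalues), 1 - 1e-10)
})

test_that("duplicating every sample leaves PCA weights unchanged", {
  gm <- random_gm(n = 12, m = 15, seed = 4)
  gm_dup <- genotype_matrix(rbind(gm$dosage, gm$dosage),
                            c(gm$sample_ids, paste0(gm$sample_ids, "b")),
                            gm$chrom, gm$pos)
  w1 <- chromosome_pca(gm, "1", 3)$weights
  w2 <- chromosome_pca(gm_dup, "1", 3)$weights
  for (k in 1:3)
    expect_equal(abs(sum(w1[, k] * w2[, k])), 1, tolerance = 1e-8)
})

test_that("iid-noise genotypes yield no dominant component", {
  ratios <- vapply(1:100, function(seed) {
    gm <- random_gm(n = 500, m = 50, seed = 1000 + seed)
    ev <- chromosome_pca(gm, "1", 2)$eigenvalues
    ev[1] / ev[2]
  }, numeric(1))
  expect_gte(mean(ratios < 2), 0.95)
})

test_that("windowed weight variance matches a naive per-window loop", {
  # closed forms first
  pca <- list(chrom = "1", weights = cbind(c(0.1, 0.2, 0.3)),
              pos = c(1000L, 2000L, 3000L), eigenvalues = 1)
  class(pca) <- "inv_pca"
  win <- windowed_weight_variance(pca, 1, window_bp = 10000, step_bp = 7500)
  expect_equal(win$value[1], 0.01)            # var with n-1 = 2
  expect_equal(win$n_snps[1], 3L)

  set.seed(21)
  m <- 1000
  pos <- sort(sample.int(2e6, m))
  w <- rnorm(m, 0, 0.01)
  pca2 <- structure(list(chrom = "1", weights = cbind(w), pos = pos,
                         eigenvalues = 1), class = "inv_pca")
  win2 <- windowed_weight_variance(pca2, 1)
  # naive oracle
  for (i in sample(nrow(win2), 50)) {
    sel <- pos >= win2$start[i] & pos < win2$end[i]
    expect_equal(win2$n_snps[i], sum(sel))
    if (sum(sel) >= 3) expect_equal(win2$value[i], var(w[sel]))
    else expect_true(is.na(win2$value[i]))
  }
  # all-equal weights give zero variance
  pca3 <- structure(list(chrom = "1", weights = cbind(rep(0.2, 50)),
                         pos = seq(1000L, 50000L, by = 1000L),
                         eigenvalues = 1), class = "inv_pca")
  expect_true(all(windowed_weight_variance(pca3, 1)$value == 0, na.rm = TRUE))
})

make_profile <- function(values) {
  data.frame(chrom = "1", component = 1L,
             start = seq_along(values) * 7500 - 7499,
             end = seq_along(values) * 7500 + 2501,
             n_snps = 5L, value = values)
}

test_that("candidate region detection chains flagged windows", {
  # flat profile: nothing exceeds the fold threshold
  expect_equal(nrow(detect_candidate_regions(make_profile(rep(0.1, 100)))), 0L)

  # one 50-window block at 10x background -> exactly one region over it
  v <- c(rep(1, 100), rep(10, 50), rep(1, 100))
  reg <- detect_candidate_regions(make_profile(v))
  expect_equal(nrow(reg), 1L)
  prof <- make_profile(v)
  expect_equal(reg$start, prof$start[101])
  expect_equal(reg$end, prof$end[150])
  expect_equal(reg$peak_value, 10)
  expect_equal(reg$n_windows, 50L)

  # two 30-window blocks separated by 20 background windows -> two regions
  v2 <- c(rep(1, 80), rep(8, 30), rep(1, 20), rep(12, 30), rep(1, 80))
  reg2 <- detect_candidate_regions(make_profile(v2))
  expect_equal(nrow(reg2), 2L)
  expect_equal(reg2$peak_value, c(12, 8))     # sorted by peak
  # regions never overlap
  r <- reg2[order(reg2$start), ]
  expect_true(all(r$start[-1] >= r$end[-nrow(r)]))

  # gaps up to max_gap are bridged, longer gaps split
  v3 <- c(rep(1, 50), rep(10, 8), 1, 1, rep(10, 8), rep(1, 50))
  expect_equal(nrow(detect_candidate_regions(make_profile(v3))), 1L)
  v4 <- c(rep(1, 50), rep(10, 8), rep(1, 3), rep(10, 8), rep(1, 50))
  expect_equal(nrow(detect_candidate_regions(make_profile(v4))), 0L)

  expect_error(detect_candidate_regions(make_profile(rep(1, 10))),
               "insufficient resolution")
})

test_that("window variance is elevated inside simulated inversions", {
  hits <- vapply(1:50, function(seed) {
    sim <- simulate_inversion_dataset(small_sim_config(seed))
    pca <- suppressMessages(chromosome_pca(sim$gm, "2", 1))
    win <- windowed_weight_variance(pca, 1)
    inside <- win$start >= 5e5 & win$end <= 1.5e6
    mean(win$value[inside], na.rm = TRUE) >
      mean(win$value[!inside], na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
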