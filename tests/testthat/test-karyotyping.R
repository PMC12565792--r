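test_that("top-weight SNP selection uses the ceiling rule and position ties", {
  mk_pca <- function(w, pos) structure(
    list(chrom = "1", weights = cbind(w), pos = pos,
         snp_index = seq_along(w), eigenvalues = 1), class = "inv_pca")
  w200 <- c(0.9, 0.8, rep(0.01, 198))
  pca <- mk_pca(w200, seq_len(200) * 100L)
  # small selections come with a warning but are returned
  expect_warning(sel200 <- select_top_weight_snps(pca, 1, 0.01),
                 "fewer than 10")
  expect_equal(sel200, c(1L, 2L))
  # 250 SNPs -> ceil(2.5) = 3
  w250 <- c(0.9, 0.8, 0.7, rep(0.01, 247))
  expect_length(suppressWarnings(
    select_top_weight_snps(mk_pca(w250, seq_len(250) * 100L), 1, 0.01)), 3L)
  # tie in |weight| at the cut: lower position wins; sign is irrelevant
  w_tie <- c(0.5, -0.5, 0.5, 0.9, rep(0.01, 396))
  sel <- suppressWarnings(
    select_top_weight_snps(mk_pca(w_tie, seq_len(400) * 100L), 1, 0.01))
  expect_equal(sel, c(1L, 2L, 3L, 4L))
  expect_error(suppressWarnings(
    select_top_weight_snps(mk_pca(w200, seq_len(200) * 100L), 1, 0.005)),
    "fewer than 2")
})

test_that("IBS matrix matches its closed forms and the double-loop oracle", {
  gm <- make_gm(rbind(rep(0L, 6), rep(0L, 6), rep(2L, 6), rep(1L, 6)))
  ibs <- ibs_matrix(gm, 1:6)
  expect_equal(ibs[1, 2], 1)        # identical rows
  expect_equal(ibs[1, 3], 0)        # all-0 vs all-2
  expect_equal(ibs[1, 4], 0.5)      # all-0 vs all-1
  expect_equal(diag(ibs), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(ibs))

  gm2 <- random_gm(n = 20, m = 50, seed = 13, missing_rate = 0.1)
  ibs2 <- ibs_matrix(gm2, 1:50)
  oracle <- matrix(NA_real_, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    a <- gm2$dosage[i, ]; b <- gm2$dosage[j, ]
    ok <- !is.na(a) & !is.na(b)
    oracle[i, j] <- mean((2 - abs(a[ok] - b[ok])) / 2)
  }
  expect_equal(unname(ibs2), oracle)

  gm3 <- make_gm(rbind(c(0L, NA), c(NA, 1L)))
  expect_error(ibs_matrix(gm3, 1:2), "zero non-missing")
})

test_that("classical MDS recovers 1-D configurations exactly", {
  # three collinear points, distances 0.1 / 0.1 / 0.2
  s <- 1 - rbind(c(0, 0.1, 0.2), c(0.1, 0, 0.1), c(0.2, 0.1, 0))
  pts <- classical_mds(s, k = 1)
  expect_equal(as.vector(dist(pts)), c(0.1, 0.2, 0.1), tolerance = 1e-10)
  # two identical samples coincide
  s2 <- 1 - rbind(c(0, 0, 0.3), c(0, 0, 0.3), c(0.3, 0.3, 0))
  pts2 <- classical_mds(s2, k = 1)
  expect_equal(pts2[1, 1], pts2[2, 1], tolerance = 1e-12)
  # deterministic axis sign
  expect_gt(pts[which.max(abs(pts[, 1])), 1], 0)

  # distances generated from true 1-D points are reproduced within 1e-8
  set.seed(5)
  x <- runif(15, -0.4, 0.4)
  d <- as.matrix(dist(x)) / 2
  pts3 <- classical_mds(1 - d, k = 1)
  expect_equal(unname(as.vector(dist(pts3))), as.vector(dist(x)) / 2,
               tolerance = 1e-8)
})

test_that("fuzzy c-means finds tight 1-D groups deterministically", {
  set.seed(77)
  coords <- c(rnorm(30, -0.25, 0.005), rnorm(30, 0, 0.005),
              rnorm(30, 0.25, 0.005))
  fcm <- fuzzy_cmeans(coords)
  expect_equal(fcm$centers, c(-0.25, 0, 0.25), tolerance = 0.01)
  expect_gt(mean(apply(fcm$memberships, 1, max)), 0.95)
  expect_equal(rowSums(fcm$memberships), rep(1, 90), tolerance = 1e-8)
  expect_true(fcm$converged)

  # membership singularity: a point exactly on a center
  fcm2 <- fuzzy_cmeans(c(rep(-1, 10), rep(0, 10), rep(1, 10), 0.5))
  at_center <- which(abs(c(rep(-1, 10), rep(0, 10), rep(1, 10), 0.5) -
                           fcm2$centers[2]) < 1e-12)
  if (length(at_center))
    expect_equal(max(fcm2$memberships[at_center[1], ]), 1)

  # duplicating the dataset leaves centers unchanged
  fcm3 <- fuzzy_cmeans(rep(coords, 2))
  expect_equal(fcm3$centers, fcm$centers, tolerance = 1e-6)

  expect_error(fuzzy_cmeans(c(0, 0, 1, 1)), "distinct")
})

test_that("fuzzy c-means agrees with the e1071 reference implementation", {
  set.seed(42)
  coords <- c(rnorm(40, -0.2, 0.02), rnorm(50, 0.01, 0.02),
              rnorm(30, 0.22, 0.02))
  mine <- fuzzy_cmeans(coords)
  lo <- quantile(coords, 0.01, names = FALSE)
  hi <- quantile(coords, 0.99, names = FALSE)
  init <- matrix(c(lo, (lo + hi) / 2, hi), ncol = 1)
  ref <- e1071::cmeans(matrix(coords, ncol = 1), centers = init, m = 2,
                       iter.max = 500)
  expect_equal(mine$centers, sort(as.vector(ref$centers)), tolerance = 1e-4)
  ord <- order(as.vector(ref$centers))
  expect_equal(mine$memberships, unname(ref$membership[, ord]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

crisp_fcm <- function(n_aa, n_ab, n_bb, centers = c(-0.25, 0, 0.25)) {
  coords <- rep(centers, c(n_aa, n_ab, n_bb))
  u <- matrix(0, length(coords), 3)
  u[cbind(seq_along(coords), rep(1:3, c(n_aa, n_ab, n_bb)))] <- 1
  list(memberships = u, centers = centers, coords = coords)
}

test_that("karyotype calling orients clusters and applies retention rules", {
  res <- call_karyotypes(crisp_fcm(150, 60, 10),
                         sprintf("s%03d", 1:220))
  expect_true(res$retained)
  expect_equal(sum(res$calls$genotype == "AA"), 150L)
  expect_equal(sum(res$calls$genotype == "BB"), 10L)

  # larger homozygote cluster on the right still becomes AA
  res_r <- call_karyotypes(crisp_fcm(10, 60, 150), sprintf("s%03d", 1:220))
  expect_equal(sum(res_r$calls$genotype == "AA"), 150L)
  s <- inversion_summary(res_r$calls)
  expect_lte(s$inv_maf, 0.5)

  # an (effectively) empty cluster fails retention
  res2 <- call_karyotypes(crisp_fcm(150, 60, 1), sprintf("s%03d", 1:211))
  expect_false(res2$retained)
  expect_equal(res2$reason, "cluster size")

  # middle center at relative position 0.1 fails spacing
  res3 <- call_karyotypes(crisp_fcm(100, 50, 30, c(0, 0.05, 0.5)),
                          sprintf("s%03d", 1:180))
  expect_false(res3$retained)
  expect_equal(res3$reason, "center spacing")

  # diffuse memberships fail the mean-membership rule
  fcm_soft <- crisp_fcm(100, 50, 30)
  fcm_soft$memberships <- fcm_soft$memberships * 0.4 + 0.2
  res4 <- call_karyotypes(fcm_soft, sprintf("s%03d", 1:180))
  expect_false(res4$retained)
  expect_equal(res4$reason, "membership")
})

test_that("inversion summary reproduces the fixation-index closed forms", {
  mk_calls <- function(n_aa, n_ab, n_bb)
    data.frame(genotype = rep(c("AA", "AB", "BB"), c(n_aa, n_ab, n_bb)))
  s1 <- inversion_summary(mk_calls(81, 18, 1))
  expect_equal(s1$inv_maf, 0.10)
  expect_equal(s1$f_index, 0)
  s2 <- inversion_summary(mk_calls(50, 0, 50))
  expect_equal(s2$inv_maf, 0.5)
  expect_equal(s2$f_index, 1)
  s3 <- inversion_summary(mk_calls(0, 100, 0))
  expect_equal(s3$f_index, -1)
  # monomorphic call set: F defined as 0
  expect_equal(inversion_summary(mk_calls(100, 0, 0))$f_index, 0)
})

test_that("karyotypes recover simulated truth with near-equal cluster spacing", {
  conc <- numeric(50); spacing <- numeric(50)
  for (seed in 1:50) {
    sim <- simulate_inversion_dataset(small_sim_config(seed))
    pca <- suppressMessages(chromosome_pca(sim$gm, "2", 1))
    kt <- karyotype_component(sim$gm, pca, 1, seed = seed)
    called <- c(AA = 0, AB = 1, BB = 2)[kt$calls$genotype]
    tk <- sim$truth$karyotypes[, 1]
    conc[seed] <- max(mean(called == tk), mean((2 - called) == tk))
    spacing[seed] <- kt$spacing_ratio
  }
  expect_gte(mean(conc >= 0.98), 0.95)
  # relative position of the heterozygote center between the homozygote
  # centers; near 0.5 under Hardy-Weinberg simulated inversions
  expect_gte(median(spacing), 0.4)
  expect_lte(median(spacing), 0.6)
})
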