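# fixture builders shared across the suite

# small deterministic genotype matrix from an explicit dosage matrix
make_gm <- function(dosage, pos = NULL, chrom = "1", chrom_len = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  ct <- if (!is.null(chrom_len))
    data.frame(name = chrom, length_bp = chrom_len) else NULL
  genotype_matrix(
    dosage = dosage,
    sample_ids = sprintf("s%02d", seq_len(nrow(dosage))),
    chrom = rep(chrom, m), pos = pos, chrom_table = ct
  )
}

# random genotype matrix with independent SNPs (for oracle comparisons)
random_gm <- function(n = 20, m = 50, seed = 1, missing_rate = 0,
                      pos_max = m * 1000L) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA_integer_
  pos <- sort(sample.int(pos_max, m))
  make_gm(d, pos = pos)
}

# desk-scale simulation used by module-level property tests: 2 Mb
# chromosome, 1 Mb inversion, strong signal at modest n
small_sim_config <- function(seed, q = 0.3, divergence = 0.3,
                             error = 0.1, n = 120, inversion = TRUE) {
  inv <- if (inversion)
    data.frame(start_bp = 5e5, end_bp = 1.5e6, freq = q,
               divergence = divergence, fst_drift = 0.2)
  else
    data.frame(start_bp = numeric(0), end_bp = numeric(0), freq = numeric(0),
               divergence = numeric(0), fst_drift = numeric(0))
  simulation_config(
    n_samples = n, chrom_length_bp = 2e6, snp_density_per_kb = 1.5,
    inversions = inv, genotype_error_rate = error, missing_rate = 0.01,
    seed = seed
  )
}

# independent Spearman oracle with average ranks (ties) for cross-checks
spearman_avg_rank <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  suppressWarnings(stats::cor(rx, ry))
}
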