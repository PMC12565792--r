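# Full-scale recovery and null runs at the validation design: 200 samples,
# 20 Mb chromosome, one 8 Mb inversion at frequency 0.3, divergence 0.3,
# 10% genotype error. Computed once per session and shared across the
# acceptance blocks.

.recovery_cache <- new.env(parent = emptyenv())

jaccard_interval <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start))
  union <- max(a_end, b_end) - min(a_start, b_start)
  inter / union
}

run_recovery_seed <- function(seed, inversion = TRUE) {
  cfg <- if (inversion) simulation_config(seed = seed) else
    simulation_config(
      inversions = data.frame(start_bp = numeric(0), end_bp = numeric(0),
                              freq = numeric(0), divergence = numeric(0),
                              fst_drift = numeric(0)),
      seed = seed)
  sim <- simulate_inversion_dataset(cfg)
  fit <- suppressMessages(suppressWarnings(
    detect_inversions(sim$gm, seed = seed)))
  out <- list(n_retained = nrow(fit$report))
  if (inversion && nrow(fit$report) >= 1L) {
    id <- fit$report$inversion_id[1L]
    kt <- fit$karyotypes[[id]]
    called <- c(AA = 0, AB = 1, BB = 2)[kt$calls$genotype]
    truth_k <- sim$truth$karyotypes[, 1L]
    out$concordance <- max(mean(called == truth_k),
                           mean((2 - called) == truth_k))
    out$jaccard <- jaccard_interval(fit$report$start[1L], fit$report$end[1L],
                                    cfg$inversions$start_bp[1L],
                                    cfg$inversions$end_bp[1L])
    out$spacing <- kt$spacing_ratio
    lc <- fit$ld$correlations[[id]]
    if (!is.null(lc)) { out$rho <- lc$rho; out$rho_p <- lc$p_value }
    ldw <- fit$ld$windows[[kt$chrom]]
    inside <- ldw$start >= cfg$inversions$start_bp[1L] &
      ldw$end <= cfg$inversions$end_bp[1L]
    out$r2_inside <- stats::median(ldw$value[inside], na.rm = TRUE)
    out$r2_background <- stats::median(ldw$value[!inside], na.rm = TRUE)
  }
  out
}

recovery_runs <- function(n_seeds = 20) {
  key <- paste0("recovery", n_seeds)
  if (is.null(.recovery_cache[[key]]))
    .recovery_cache[[key]] <- lapply(seq_len(n_seeds), run_recovery_seed)
  .recovery_cache[[key]]
}

null_runs <- function(n_seeds = 20) {
  key <- paste0("null", n_seeds)
  if (is.null(.recovery_cache[[key]]))
    .recovery_cache[[key]] <- lapply(100 + seq_len(n_seeds),
                                     run_recovery_seed, inversion = FALSE)
  .recovery_cache[[key]]
}
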