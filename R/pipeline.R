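#' Detect and genotype polymorphic chromosome inversions
#'
#' The package's central fitting function: runs the full detection pipeline
#' on a genotype matrix — optional marker filtering and LD pruning,
#' per-chromosome PCA, sliding-window SNP-weight variance scan, candidate
#' region detection, karyotyping of candidate components (top-weight SNPs,
#' IBS, 1-D classical MDS, fuzzy c-means), association-based coordinate
#' estimation, short-range LD corroboration, and pairwise dependence tests
#' between retained inversions.
#'
#' @param gm a `genotype_matrix`.
#' @param chrom_table optional chromosome-length table (data frame with
#'   `name`, `length_bp`); defaults to `gm$chrom_table`. Required for the LD
#'   profile stage.
#' @param filter apply MAF/missingness filtering first (default TRUE).
#' @param prune apply windowed LD pruning (default TRUE).
#' @param maf_min,max_missing_frac passed to [filter_variants()].
#' @param prune_window_bp,prune_step_bp,prune_r2 passed to [ld_prune()].
#' @param n_components PCA components scanned per chromosome (default 5).
#' @param window_bp,step_bp,min_snps weight-variance window parameters.
#' @param flag_quantile,flag_fold,min_run,max_gap candidate-region detection
#'   thresholds, see [detect_candidate_regions()].
#' @param top_fraction fraction of SNPs used for karyotyping (default 0.01).
#' @param alpha significance level of the association scan (default 0.05).
#' @param merge_gap_bp cluster gap of [estimate_coordinates()] (default 1e6).
#' @param ld_max_dist maximum LD pair distance in bp (default 12000).
#' @param ld_window_frac,ld_step_frac fractional LD window parameters.
#' @param seed integer seed; stages derive their own sub-seeds from it so
#'   each stage is individually reproducible.
#' @return object of class `invscan`; see [print.invscan()],
#'   [summary.invscan()], [plot.invscan()]. Key elements: `report` (one row
#'   per retained inversion: chrom, component, start, end, length, counts,
#'   inv MAF, F), `karyotypes` (all candidate components), `windows`,
#'   `regions`, `associations`, `ld`, `pairs`, `params`.
#' @export
detect_inversions <- function(gm, chrom_table = NULL,
                              filter = TRUE, prune = TRUE,
                              maf_min = 0.1, max_missing_frac = 0.5,
                              prune_window_bp = 14000, prune_step_bp = 9000,
                              prune_r2 = 0.05,
                              n_components = 5,
                              window_bp = 10000, step_bp = 7500, min_snps = 3,
                              flag_quantile = 0.95, flag_fold = 5.0,
                              min_run = 10, max_gap = 2,
                              top_fraction = 0.01,
                              alpha = 0.05, merge_gap_bp = 1e6,
                              ld_max_dist = 12000,
                              ld_window_frac = 0.005, ld_step_frac = 0.0025,
                              seed = 1) {
  params <- as.list(environment())
  params$gm <- NULL; params$chrom_table <- NULL
  if (is.null(chrom_table)) chrom_table <- gm$chrom_table
  n_input <- n_snps(gm)

  if (filter) gm <- filter_variants(gm, maf_min, max_missing_frac)
  if (prune) gm <- ld_prune(gm, prune_window_bp, prune_step_bp, prune_r2)

  chroms <- unique(gm$chrom)
  all_windows <- list(); all_regions <- list()
  karyotypes <- list(); associations <- list(); coords <- list()
  ld_windows <- list(); ld_cors <- list()
  pcas <- list()

  for (ch in chroms) {
    pca <- chromosome_pca(gm, ch, n_components)
    pcas[[ch]] <- pca
    pairs_ch <- NULL
    for (comp in seq_along(pca$eigenvalues)) {
      win <- windowed_weight_variance(pca, comp, window_bp, step_bp, min_snps)
      all_windows[[paste0(ch, ":C", comp)]] <- win
      reg <- detect_candidate_regions(win, flag_quantile, flag_fold,
                                      min_run, max_gap)
      if (nrow(reg) == 0L) next
      all_regions[[paste0(ch, ":C", comp)]] <- reg

      kt <- karyotype_component(gm, pca, comp, top_fraction,
                                seed = stage_seed(seed, paste0("fcm:", ch, comp)))
      kt$region <- reg[1L, ]
      karyotypes[[kt$inversion_id]] <- kt
      if (!kt$retained) next

      pheno <- c(AA = 0, AB = 1, BB = 2)[kt$calls$genotype]
      assoc <- association_scan(gm, ch, pheno, alpha)
      associations[[kt$inversion_id]] <- assoc
      est <- estimate_coordinates(assoc, alpha, merge_gap_bp)
      coords[[kt$inversion_id]] <- est

      if (!is.null(chrom_table)) {
        if (is.null(pairs_ch)) {
          pairs_ch <- collect_pairs(gm, ch, ld_max_dist)
          ldw <- windowed_median_r2(pairs_ch, chrom_length(chrom_table, ch),
                                    ld_window_frac, ld_step_frac)
          ld_windows[[ch]] <- ldw
        }
        lc <- weight_ld_correlation(ld_windows[[ch]], pca, comp)
        if (!is.null(lc)) ld_cors[[kt$inversion_id]] <- lc
      }
    }
  }

  retained <- Filter(function(k) k$retained, karyotypes)
  pairs_tab <- if (length(retained) >= 2L)
    pairwise_inversion_tests(retained) else NULL

  report <- build_report(retained, coords)
  structure(
    list(report = report, karyotypes = karyotypes, coordinates = coords,
         associations = associations, windows = all_windows,
         regions = all_regions, ld = list(windows = ld_windows,
                                          correlations = ld_cors),
         pairs = pairs_tab, pca = pcas, gm_pruned = gm,
         n_snps_input = n_input, n_snps_used = n_snps(gm),
         params = params),
    class = "invscan")
}

# deterministic per-stage sub-seed below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 1009L * (h %% 1000003L)) %% 2147483647L
}

build_report <- function(retained, coords) {
  if (!length(retained))
    return(data.frame(inversion_id = character(), chrom = character(),
                      component = integer(), start = numeric(),
                      end = numeric(), length = numeric(),
                      n_significant = integer(), n_AA = integer(),
                      n_AB = integer(), n_BB = integer(),
                      inv_maf = numeric(), f_index = numeric()))
  rows <- lapply(retained, function(k) {
    est <- coords[[k$inversion_id]]
    s <- k$summary
    data.frame(
      inversion_id = k$inversion_id, chrom = k$chrom,
      component = k$component,
      start = if (is.null(est)) NA_real_ else est$start,
      end = if (is.null(est)) NA_real_ else est$end,
      length = if (is.null(est)) NA_real_ else est$end - est$start,
      n_significant = if (is.null(est)) 0L else est$n_significant,
      n_AA = s$counts[["AA"]], n_AB = s$counts[["AB"]],
      n_BB = s$counts[["BB"]],
      inv_maf = s$inv_maf, f_index = s$f_index,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom, out$component), , drop = FALSE]
}

#' @export
print.invscan <- function(x, ...) {
  cat("invscan:", x$n_snps_used, "SNPs analysed (of", x$n_snps_input,
      "input) across", length(x$pca), "chromosome(s)\n")
  nr <- nrow(x$report)
  cat(" ", length(x$karyotypes), "candidate component(s),", nr,
      "retained inversion(s)\n")
  if (nr) {
    cat("\n")
    print(x$report, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a fitted inversion scan
#'
#' @param object an `invscan` object.
#' @param ... unused.
#' @return `object`, invisibly; prints the inversion report, dropped
#'   candidates with reasons, LD corroboration and pairwise tests.
#' @export
summary.invscan <- function(object, ...) {
  print(object)
  dropped <- Filter(function(k) !k$retained, object$karyotypes)
  if (length(dropped)) {
    cat("\nDropped candidates:\n")
    for (k in dropped)
      cat("  ", k$inversion_id, "-", k$reason, "\n")
  }
  if (length(object$ld$correlations)) {
    cat("\nLD corroboration (Spearman rho of window median r2 vs mean |weight|):\n")
    for (lc in object$ld$correlations)
      cat(sprintf("  %s:C%d  rho = %.3f  p = %.3g  (%d windows)\n",
                  lc$chrom, lc$component, lc$rho, lc$p_value, lc$n_windows))
  }
  if (!is.null(object$pairs)) {
    cat("\nPairwise inversion tests:\n")
    print(object$pairs, row.names = FALSE)
  }
  invisible(object)
}

#' Plot the inversion scan signal tracks
#'
#' Base-graphics tracks per retained inversion: the sliding-window SNP-weight
#' variance profile with the detected candidate region and the
#' association-based coordinate estimate, and (when available) the windowed
#' median r-squared profile.
#'
#' @param x an `invscan` object.
#' @param ... passed to `plot.default`.
#' @return `x`, invisibly.
#' @export
plot.invscan <- function(x, ...) {
  ids <- x$report$inversion_id
  if (!length(ids)) {
    graphics::plot.new(); graphics::title("no retained inversions")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(length(ids), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (id in ids) {
    win <- x$windows[[id]]
    plot(win$start / 1e6, win$value, type = "l",
         xlab = "position (Mb)", ylab = "weight variance", main = id, ...)
    reg <- x$regions[[id]]
    if (!is.null(reg))
      graphics::rect(reg$start / 1e6, 0, reg$end / 1e6,
                     max(win$value, na.rm = TRUE),
                     col = grDevices::adjustcolor("steelblue", 0.2),
                     border = NA)
    est <- x$coordinates[[id]]
    if (!is.null(est))
      graphics::abline(v = c(est$start, est$end) / 1e6, col = "firebrick",
                       lty = 2)
  }
  invisible(x)
}

#' Write all pipeline outputs of a fitted scan to a directory
#'
#' Emits the consolidated inversion report, per-component window and region
#' tables, karyotype calls and summaries, association results, LD windows
#' and correlations, pairwise tests (all TSV with header), and a JSON run
#' manifest recording parameters, seed and per-stage row counts.
#'
#' @param x an `invscan` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_invscan <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tsv(x$report, "inversions.tsv")
  tsv(do.call(rbind, c(x$windows, list(make.row.names = FALSE))),
      "windows.tsv")
  if (length(x$regions))
    tsv(do.call(rbind, c(x$regions, list(make.row.names = FALSE))),
        "regions.tsv")
  if (length(x$karyotypes)) {
    calls <- do.call(rbind, lapply(x$karyotypes, function(k)
      cbind(inversion_id = k$inversion_id, k$calls)))
    tsv(calls, "karyotype_calls.tsv")
    summ <- do.call(rbind, lapply(x$karyotypes, function(k) {
      s <- k$summary
      data.frame(inversion_id = k$inversion_id, n_AA = s$counts[["AA"]],
                 n_AB = s$counts[["AB"]], n_BB = s$counts[["BB"]],
                 inv_maf = s$inv_maf, f_index = s$f_index,
                 retained = k$retained, reason = k$reason)
    }))
    tsv(summ, "karyotype_summary.tsv")
  }
  if (length(x$associations))
    tsv(do.call(rbind, lapply(names(x$associations), function(id)
      cbind(inversion_id = id, x$associations[[id]]))), "associations.tsv")
  if (length(x$ld$windows))
    tsv(do.call(rbind, c(x$ld$windows, list(make.row.names = FALSE))),
        "ld_windows.tsv")
  if (length(x$ld$correlations))
    tsv(do.call(rbind, lapply(x$ld$correlations, as.data.frame)),
        "ld_correlations.tsv")
  if (!is.null(x$pairs)) tsv(x$pairs, "inversion_pairs.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("invscan")),
    parameters = x$params,
    n_snps_input = x$n_snps_input, n_snps_used = x$n_snps_used,
    n_candidates = length(x$karyotypes), n_retained = nrow(x$report))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
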