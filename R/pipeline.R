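# Study orchestration: simulate -> extract -> align -> band metrics ->
# chemometrics -> report.

#' Default run configuration
#'
#' A fully serializable description of a study run: one master seed plus
#' per-stage parameters. A run is reproducible from config alone.
#'
#' @param seed Master seed (every stage derives its sub-seed from it).
#' @param channels Channels to simulate and analyse.
#' @param n_resamples Permutation resamples for the y-scrambling test.
#' @param max_components Components scanned in cross-validation.
#' @param band_threshold Peak-picking threshold on scaled lanes.
#' @param dice_tolerance Dice positional tolerance (Rf).
#' @param alpha Significance level of the pairwise comparisons.
#' @param top_n Discriminant bands reported.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, channels = c("universal", "bacteroides"),
                       n_resamples = 200, max_components = 10,
                       band_threshold = 0.03, dice_tolerance = 0.008,
                       alpha = 0.01, top_n = 4) {
  structure(list(seed = as.integer(seed), channels = channels,
                 n_resamples = n_resamples, max_components = max_components,
                 band_threshold = band_threshold,
                 dice_tolerance = dice_tolerance, alpha = alpha,
                 top_n = top_n),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Simulate one channel end-to-end and align it
#'
#' Builds the calibrated cohort for a channel, plans gels, renders gel
#' images, extracts and quality-filters lane traces, and runs the full
#' two-stage alignment. Images are round-tripped through 16-bit TIFF files
#' when `image_dir` is given; otherwise extraction runs on the in-memory
#' images (identical up to quantization).
#'
#' @param channel `"universal"` or `"bacteroides"`.
#' @param seed Master seed.
#' @param presets Group presets (default [default_presets()] for the
#'   channel).
#' @param image_dir Directory for gel TIFFs (optional).
#' @param band_threshold Threshold used for SS lane quality checks.
#' @return List with `cohort`, `layout`, `aligned` (an [align_experiment()]
#'   result), `rejections` (quality-filter log) and `ss` (the standard).
#' @export
simulate_channel <- function(channel = "universal", seed = 1L,
                             presets = default_presets(channel),
                             image_dir = NULL, band_threshold = 0.03) {
  pool <- species_pool(n_bands = attr(presets, "pool_size"),
                       rf_range = attr(presets, "rf_range"),
                       seed = derive_seed(seed, paste0("pool-", channel)))
  cohort <- build_cohort(presets, pool,
                         seed = derive_seed(seed, paste0("cohort-", channel)))
  layout <- plan_gels(cohort,
                      seed = derive_seed(seed, paste0("gels-", channel)))
  ss <- make_synthetic_standard()
  gels <- unique(layout$gel_id)
  traces <- list(); meta <- list()
  for (g in gels) {
    rg <- render_gel_image(layout, g, cohort, ss,
                           seed = derive_seed(seed, paste0("render-", channel)))
    img <- rg$image
    if (!is.null(image_dir)) {
      dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(image_dir, paste0(channel, "_", g, ".tif"))
      write_gel_image(img, path)
      img <- read_gel_image(path)
    } else {
      img <- round(img * 65535) / 65535   # 16-bit quantization
    }
    traces <- c(traces, extract_lanes(img, rg$metadata))
    meta[[g]] <- rg$metadata
  }
  meta <- do.call(rbind, meta)
  qf <- quality_filter(traces, meta, expected_ss_bands = nrow(ss$bands))
  aligned <- align_experiment(qf$traces, qf$metadata,
                              expected_ss_bands = nrow(ss$bands))
  list(cohort = cohort, layout = layout, aligned = aligned,
       rejections = qf$log, ss = ss)
}

#' Band-level statistics of an aligned channel
#'
#' Peak-picks every retained lane, averages band counts and Shannon indices
#' over each sample's replicates, computes replicate-averaged per-sample
#' band sets and within-group Dice similarity summaries, and runs the
#' one-way ANOVAs with Bonferroni pairwise comparisons.
#'
#' @param aligned An [align_experiment()] result.
#' @param config A [run_config()].
#' @return List with `group_summaries` (per group: n, band-count mean/sd,
#'   Shannon mean/sd, Dice median and IQR), `anova_band_count`,
#'   `anova_shannon`, `per_sample` (data frame) and `sample_bands`.
#' @export
band_stats_for_channel <- function(aligned, config) {
  X <- aligned$X; meta <- aligned$metadata
  g <- rf_grid()[rf_window_index()]
  lane_bands <- lapply(seq_len(nrow(X)), function(i)
    pick_bands(X[i, ], g, threshold = config$band_threshold))
  lane_counts <- vapply(lane_bands, nrow, integer(1))
  lane_shannon <- vapply(lane_bands, shannon_index, numeric(1))
  counts <- average_replicates(lane_counts, meta$sample_id)
  shannon <- average_replicates(lane_shannon, meta$sample_id)
  sample_groups <- vapply(names(counts), function(s)
    meta$group[match(s, meta$sample_id)], character(1))
  # replicate-averaged aligned profiles -> per-sample band sets for Dice
  Xavg <- average_replicates(X, meta$sample_id)
  sample_bands <- lapply(seq_len(nrow(Xavg)), function(i)
    pick_bands(Xavg[i, ], g, threshold = config$band_threshold))
  names(sample_bands) <- rownames(Xavg)
  groups <- unique(sample_groups)
  summaries <- lapply(setNames(groups, groups), function(grp) {
    sel <- sample_groups == grp
    sim <- similarity_summary(sample_bands[sel],
                              tolerance = config$dice_tolerance)
    list(group = grp, n = sum(sel),
         band_count_mean = mean(counts[sel]),
         band_count_sd = sd(counts[sel]),
         shannon_mean = mean(shannon[sel]), shannon_sd = sd(shannon[sel]),
         dice_median = sim$median, dice_iqr = sim$iqr)
  })
  list(group_summaries = summaries,
       anova_band_count = anova_bonferroni(counts, sample_groups,
                                           alpha = config$alpha),
       anova_shannon = anova_bonferroni(shannon, sample_groups,
                                        alpha = config$alpha),
       per_sample = data.frame(sample_id = names(counts),
                               group = sample_groups,
                               band_count = unname(counts),
                               shannon = unname(shannon)),
       sample_bands = sample_bands)
}

#' Run the full study on synthetic cohorts
#'
#' Composes every stage for each configured channel and, for the universal
#' channel, the chemometric analyses: leave-sample-out cross-validated
#' PLS-DA, y-scrambling permutation test at the chosen model size, CVA
#' projection and discriminant-band ranking. Deterministic given the config
#' seed; writes all interface files when `out_dir` is given.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (optional).
#' @param image_dir Directory for gel TIFFs (optional; images stay in
#'   memory if `NULL`).
#' @return A `study_report` list with per-channel `group_summaries`,
#'   ANOVA reports, similarity summaries, the CV curve and chosen model
#'   size, permutation result, CVA scores and ranked discriminant bands.
#' @export
run_study <- function(config = run_config(), out_dir = NULL,
                      image_dir = NULL) {
  report <- list(config = config, channels = list())
  for (ch in config$channels) {
    sim <- simulate_channel(ch, seed = config$seed,
                            image_dir = image_dir,
                            band_threshold = config$band_threshold)
    stats <- band_stats_for_channel(sim$aligned, config)
    entry <- list(stats = stats, rejections = sim$rejections,
                  truth = cohort_truth(sim$cohort),
                  n_lanes = nrow(sim$aligned$X))
    if (ch == "universal") {
      X <- sim$aligned$X; meta <- sim$aligned$metadata
      cv <- cross_validate_plsda(X, meta$group, meta$sample_id,
                                 max_components = config$max_components)
      perm <- permutation_test_plsda(
        X, meta$group, meta$sample_id, n_components = cv$best_k,
        n_resamples = config$n_resamples,
        seed = derive_seed(config$seed, "perm"))
      cva <- cva_cross_validated(X, meta$group, meta$sample_id,
                                 n_components = min(cv$best_k,
                                                    config$max_components))
      rf_axis <- rf_grid()[rf_window_index()]
      ranked <- rank_discriminant_bands(cv$fold_models, rf_axis,
                                        top_n = config$top_n)
      entry <- c(entry, list(cv = cv, permutation = perm, cva = cva,
                             ranked_bands = ranked))
    }
    report$channels[[ch]] <- entry
  }
  class(report) <- "study_report"
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  for (ch in names(x$channels)) {
    e <- x$channels[[ch]]
    cat(sprintf("== %s channel (%d retained lanes) ==\n", ch, e$n_lanes))
    for (s in e$stats$group_summaries)
      cat(sprintf(
        "  %-8s n=%2d  bands %.1f +/- %.1f  Shannon %.2f +/- %.2f  Dice median %.1f%% (IQR %.1f-%.1f)\n",
        s$group, s$n, s$band_count_mean, s$band_count_sd, s$shannon_mean,
        s$shannon_sd, s$dice_median, s$dice_iqr[1], s$dice_iqr[2]))
    cat(sprintf("  band-count ANOVA p = %.3g; Shannon ANOVA p = %.3g\n",
                e$stats$anova_band_count$p_value,
                e$stats$anova_shannon$p_value))
    if (!is.null(e$cv)) {
      cat(sprintf("  PLS-DA CV success %.1f%% at %d component(s); permutation p = %.4g (tail %.3g)\n",
                  100 * e$cv$best_rate, e$cv$best_k,
                  e$permutation$p_empirical, e$permutation$p_tail))
      cat(sprintf("  top discriminant bands (Rf): %s; consistent across segments: %s\n",
                  paste(sprintf("%.3f", e$ranked_bands$bands$rf),
                        collapse = ", "),
                  e$ranked_bands$consistent))
    }
  }
  invisible(x)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(report$channels)) {
    e <- report$channels[[ch]]
    gs <- do.call(rbind, lapply(e$stats$group_summaries, function(s)
      data.frame(group = s$group, n = s$n,
                 band_count_mean = s$band_count_mean,
                 band_count_sd = s$band_count_sd,
                 shannon_mean = s$shannon_mean, shannon_sd = s$shannon_sd,
                 dice_median = s$dice_median,
                 dice_iqr_low = s$dice_iqr[1], dice_iqr_high = s$dice_iqr[2])))
    write.csv(gs, file.path(out_dir, paste0(ch, "_group_summary.csv")),
              row.names = FALSE)
    write.csv(e$stats$per_sample,
              file.path(out_dir, paste0(ch, "_per_sample.csv")),
              row.names = FALSE)
    if (!is.null(e$cv)) {
      write.csv(data.frame(components = seq_along(e$cv$success_rate),
                           success_rate = e$cv$success_rate),
                file.path(out_dir, "cv_curve.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(observed = e$permutation$observed,
             p_empirical = e$permutation$p_empirical,
             p_tail = e$permutation$p_tail,
             n_resamples = e$permutation$n_resamples),
        file.path(out_dir, "permutation.json"), auto_unbox = TRUE,
        digits = NA)
      write.csv(data.frame(sample_lane = seq_len(nrow(e$cva$projection)),
                           group = e$cva$labels,
                           cv1 = e$cva$projection[, 1],
                           cv2 = e$cva$projection[, 2]),
                file.path(out_dir, "cva_scores.csv"), row.names = FALSE)
      write.csv(cbind(e$ranked_bands$bands,
                      consistent = e$ranked_bands$consistent),
                file.path(out_dir, "ranked_bands.csv"), row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Compare a study report against target values
#'
#' @param report A [run_study()] result.
#' @param targets Data frame with columns `id`, `channel`, `group`,
#'   `metric` (`band_count_mean`, `shannon_mean`, `dice_median`,
#'   `cv_success`), `target`, `tolerance`, `cmp` (`"eq"` or `"ge"`); see
#'   [default_study_targets()].
#' @return The targets with `value` and `pass` columns appended.
#' @export
compare_to_targets <- function(report, targets) {
  targets$value <- NA_real_; targets$pass <- NA
  for (i in seq_len(nrow(targets))) {
    e <- report$channels[[targets$channel[i]]]
    if (is.null(e)) { targets$pass[i] <- FALSE; next }
    v <- if (targets$metric[i] == "cv_success") {
      if (is.null(e$cv)) NA_real_ else 100 * e$cv$best_rate
    } else {
      s <- e$stats$group_summaries[[targets$group[i]]]
      if (is.null(s)) NA_real_ else s[[targets$metric[i]]]
    }
    targets$value[i] <- v
    targets$pass[i] <- if (is.na(v)) FALSE
    else if (targets$cmp[i] == "ge") v >= targets$target[i]
    else abs(v - targets$target[i]) <= targets$tolerance[i]
  }
  targets
}

#' Default study targets derived from the calibration presets
#'
#' The targets a calibrated run is expected to reproduce: the preset
#' band-count means, Shannon targets and Dice medians of both channels,
#' plus the minimum cross-validated classification success.
#'
#' @return Data frame accepted by [compare_to_targets()].
#' @export
default_study_targets <- function() {
  rows <- list()
  for (ch in c("universal", "bacteroides")) {
    pr <- default_presets(ch)
    for (p in pr) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_%s_bands", ch, p$name), channel = ch,
        group = p$name, metric = "band_count_mean",
        target = p$band_count_mean, tolerance = 2, cmp = "eq")
      if (!is.na(p$shannon_target))
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%s_shannon", ch, p$name), channel = ch,
          group = p$name, metric = "shannon_mean",
          target = p$shannon_target, tolerance = 0.1, cmp = "eq")
      if (!is.na(p$dice_target))
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%s_dice", ch, p$name), channel = ch,
          group = p$name, metric = "dice_median",
          target = p$dice_target, tolerance = 3, cmp = "eq")
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    id = "universal_cv_success", channel = "universal", group = NA,
    metric = "cv_success", target = 64, tolerance = NA, cmp = "ge")
  do.call(rbind, rows)
}
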