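# Cohort generation: latent subject profiles.
#
# Group cores are nested prefixes of one seeded permutation of the pool,
# ordered by decreasing core size. The largest (healthy control) core
# therefore contains every patient core: patients are modelled as having
# lost taxa from the healthy core, and as being dominated more strongly by
# fewer phylotypes. Accessory bands are drawn uniformly from all non-core
# pool positions, so the latent expected shared-band count between two
# subjects of a group with core c, mean count n and pool size P is
# approximately c + (n - c)^2 / (P - c); core sizes were calibrated from
# that relation and verified by Monte Carlo against the Dice targets.

#' Generate a latent cohort of subject profiles
#'
#' Draws, for every subject of every preset group, a latent band set: the
#' group core plus accessory bands sampled from the rest of the species
#' pool, with two-tier abundances (see [group_preset()]). The result is the
#' ground truth that rendered gels, alignment and band statistics are
#' validated against.
#'
#' @param presets Named list of [group_preset()]s (e.g. [default_presets()]).
#' @param pool A [species_pool()]; its size must cover the largest
#'   `core_size`.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   `(presets, pool, seed)`.
#' @param min_abund_ratio Lower bound enforced on `min(abundance)/max(abundance)`
#'   within a subject, so every planted band stays above the detection
#'   threshold by construction; abundance draws violating it are redrawn.
#' @return A `cohort`: list of subject profiles, each a list with
#'   `subject_id`, `group`, `channel` and a `bands` data frame
#'   (`label`, `rf`, `abundance`, `dominant`), abundances summing to 1 and
#'   `rf` strictly increasing.
#' @export
#' @examples
#' co <- build_cohort(default_presets(), species_pool(seed = 1), seed = 1)
#' length(co)  # 46 subjects
build_cohort <- function(presets, pool, seed = 1L, min_abund_ratio = 0.042) {
  stopifnot(inherits(pool, "species_pool"), length(presets) >= 1)
  channel <- attr(presets, "channel") %||% "universal"
  n_pool <- nrow(pool)
  sizes <- vapply(presets, `[[`, integer(1), "core_size")
  if (max(sizes) > n_pool)
    stop("species pool smaller than the largest group core")

  set.seed(derive_seed(seed, "cores"))
  perm <- sample.int(n_pool)

  cohort <- list()
  for (pr in presets) {
    core_ids <- perm[seq_len(pr$core_size)]
    dom_ids <- perm[seq_len(pr$n_dominant)]
    rest_ids <- setdiff(seq_len(n_pool), core_ids)
    n_max <- pr$core_size + length(rest_ids)
    set.seed(derive_seed(seed, paste0("subjects-", pr$name)))
    for (i in seq_len(pr$n_subjects)) {
      n_bands <- round(rnorm(1, pr$band_count_mean, pr$band_count_sd))
      n_bands <- min(max(n_bands, pr$core_size), n_max)
      acc <- if (n_bands > pr$core_size)
        sample(rest_ids, n_bands - pr$core_size) else integer(0)
      ids <- sort(c(core_ids, acc))
      dom <- ids %in% dom_ids
      # redraw jitter until the faintest band clears the detection floor
      for (try in 1:50) {
        w <- exp(rnorm(n_bands, 0, pr$intensity_spread) +
                   ifelse(dom, pr$dominant_boost, 0))
        if (min(w) / max(w) >= min_abund_ratio) break
      }
      if (min(w) / max(w) < min_abund_ratio)
        stop("could not satisfy min_abund_ratio; lower dominant_boost or spread")
      bands <- data.frame(label = pool$label[ids], rf = pool$rf[ids],
                          abundance = w / sum(w), dominant = dom,
                          stringsAsFactors = FALSE)
      cohort[[length(cohort) + 1L]] <- list(
        subject_id = sprintf("%s%02d", pr$name, i),
        group = pr$name, channel = channel, bands = bands)
    }
  }
  structure(cohort, class = "cohort", channel = channel,
            pool = pool, presets = presets)
}

#' Latent (ground-truth) summaries of a cohort
#'
#' Computes, from the latent profiles only (no rendering or alignment), the
#' per-group mean band count, mean Shannon index and all within-group
#' pairwise Dice similarities (by exact shared-taxon identity — positions
#' play no role at the latent level since the pool spacing exceeds the
#' matching tolerance). Used to verify preset calibration independently of
#' the measurement pipeline.
#'
#' @param cohort A [build_cohort()] result.
#' @return List with one entry per group: `n`, `band_count_mean`,
#'   `shannon_mean`, `dice_values` (percent), `dice_mean`, `dice_median`.
#' @export
cohort_truth <- function(cohort) {
  groups <- unique(vapply(cohort, `[[`, character(1), "group"))
  out <- list()
  for (g in groups) {
    subs <- Filter(function(s) s$group == g, cohort)
    counts <- vapply(subs, function(s) nrow(s$bands), numeric(1))
    shan <- vapply(subs, function(s) {
      p <- s$bands$abundance
      -sum(p * log(p))
    }, numeric(1))
    labs <- lapply(subs, function(s) s$bands$label)
    dice <- if (length(subs) >= 2) {
      pairs <- combn(length(subs), 2)
      apply(pairs, 2, function(ij) {
        a <- labs[[ij[1]]]; b <- labs[[ij[2]]]
        100 * 2 * length(intersect(a, b)) / (length(a) + length(b))
      })
    } else numeric(0)
    out[[g]] <- list(n = length(subs), band_count_mean = mean(counts),
                     shannon_mean = mean(shan), dice_values = dice,
                     dice_mean = mean(dice), dice_median = median(dice))
  }
  out
}

#' Synthetic standard (SS) profile
#'
#' The SS is a fixed multi-band mixture loaded in several lanes of every
#' gel; its bands are spread across the full migration range and serve as
#' the anchors of the alignment procedure. It is identical in every SS lane
#' of an experiment by design.
#'
#' @param n_bands Number of SS bands (default 24, at least 10).
#' @param rf_span Interval covered by the SS bands (default `c(0.05, 0.95)`).
#' @return A subject-profile list (`subject_id = "SS"`) with equally spaced,
#'   equal-abundance bands.
#' @export
#' @examples
#' ss <- make_synthetic_standard()
#' diff(ss$bands$rf)[1]  # ~0.0391 = (0.95 - 0.05) / 23
make_synthetic_standard <- function(n_bands = 24, rf_span = c(0.05, 0.95)) {
  if (n_bands < 2) stop("n_bands must be at least 2")
  if (n_bands < 10)
    warning("fewer than 10 SS bands gives a coarse alignment anchor set")
  if (rf_span[1] <= 0 || rf_span[2] >= 1 || rf_span[2] <= rf_span[1])
    stop("rf_span must be inside (0, 1)")
  rf <- seq(rf_span[1], rf_span[2], length.out = n_bands)
  list(subject_id = "SS", group = "SS", channel = "standard",
       bands = data.frame(label = sprintf("ss%02d", seq_len(n_bands)),
                          rf = rf, abundance = rep(1 / n_bands, n_bands),
                          dominant = FALSE, stringsAsFactors = FALSE))
}
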