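# Group presets: the study conditions the simulator reproduces.
#
# Each subject group is summarised by its cohort size, its band-count
# distribution, how much of the profile is a fixed group "core" (shared by
# every subject of the group) versus accessory draws from the remaining
# species pool, and by an abundance model. Abundances follow a two-tier
# model: most bands carry comparable loads (lognormal jitter of scale
# `intensity_spread`), while the first `n_dominant` core bands are boosted
# by `exp(dominant_boost)` — a handful of strongly dominant phylotypes over
# a detectable minor flora. The boost is the calibration knob for the
# group's mean Shannon diversity (see `calibrate_dominant_boost()`); the
# core size is the knob for the within-group Dice similarity.

#' Construct a group preset
#'
#' @param name Group label, one of `"control"`, `"UC"`, `"IBS"`.
#' @param n_subjects Number of subjects in the group.
#' @param band_count_mean,band_count_sd Mean and SD of the per-subject
#'   latent band count; counts are drawn as `round(Normal(mean, sd))`
#'   clipped to at least `core_size`.
#' @param core_size Number of pool bands present in every subject of the
#'   group.
#' @param n_dominant Number of core bands carrying the dominance boost.
#' @param dominant_boost Log-scale abundance boost of dominant bands.
#' @param intensity_spread Log-scale SD of the within-tier abundance jitter.
#' @param shannon_target Target mean Shannon index (natural log) used for
#'   calibration; `NA` if the group has no published target.
#' @param dice_target Target within-group median Dice similarity (percent).
#' @return A `group_preset` list.
#' @export
group_preset <- function(name, n_subjects, band_count_mean, band_count_sd,
                         core_size, n_dominant, dominant_boost,
                         intensity_spread, shannon_target = NA_real_,
                         dice_target = NA_real_) {
  stopifnot(is.character(name), n_subjects >= 1, band_count_mean > 0,
            band_count_sd >= 0, core_size >= 1, n_dominant >= 0,
            intensity_spread >= 0)
  if (core_size > band_count_mean)
    stop(sprintf("preset '%s': core_size (%d) exceeds band_count_mean (%.1f)",
                 name, core_size, band_count_mean))
  if (n_dominant > core_size)
    stop("n_dominant must not exceed core_size")
  structure(list(
    name = name, n_subjects = as.integer(n_subjects),
    band_count_mean = band_count_mean, band_count_sd = band_count_sd,
    core_size = as.integer(core_size), n_dominant = as.integer(n_dominant),
    dominant_boost = dominant_boost, intensity_spread = intensity_spread,
    shannon_target = shannon_target, dice_target = dice_target),
    class = "group_preset")
}

#' Default study presets for the simulated faecal cohort
#'
#' Encodes the study conditions for the two DGGE channels: the cohort sizes
#' (22 controls, 13 UC, 11 IBS), the per-group band-count distributions
#' (universal channel 45±3 / 37±5 / 39±6; Bacteroides channel 14.0±3.3 /
#' 11.9±2.9 / 14.3±2.9), and the Shannon and within-group Dice targets the
#' abundance/core parameters were calibrated against (universal Shannon
#' 3.25 / 2.94 / 2.90, Dice medians 82.9 / 76.1 / 73.8 percent; Bacteroides
#' Dice medians 58.8 / 36.4 / 55.2 percent). Core sizes and dominance
#' boosts were fixed once by Monte Carlo calibration
#' ([calibrate_dominant_boost()]); the methods vignette records the
#' procedure.
#'
#' @param channel `"universal"` (whole-community primers) or
#'   `"bacteroides"` (genus-specific primers).
#' @return Named list of three `group_preset`s (control, UC, IBS) with
#'   attributes `channel`, `pool_size` and `rf_range`.
#' @export
#' @examples
#' names(default_presets())
default_presets <- function(channel = c("universal", "bacteroides")) {
  channel <- match.arg(channel)
  if (channel == "universal") {
    p <- list(
      control = group_preset("control", 22, 45, 3, core_size = 32,
                             n_dominant = 2, dominant_boost = 2.63,
                             intensity_spread = 0.10,
                             shannon_target = 3.25, dice_target = 82.9),
      UC = group_preset("UC", 13, 37, 5, core_size = 24,
                        n_dominant = 3, dominant_boost = 2.57,
                        intensity_spread = 0.10,
                        shannon_target = 2.94, dice_target = 76.1),
      IBS = group_preset("IBS", 11, 39, 6, core_size = 22,
                         n_dominant = 5, dominant_boost = 2.61,
                         intensity_spread = 0.10,
                         shannon_target = 2.90, dice_target = 73.8))
    attr(p, "pool_size") <- 64L
  } else {
    p <- list(
      control = group_preset("control", 22, 14.0, 3.3, core_size = 7,
                             n_dominant = 1, dominant_boost = 1.8,
                             intensity_spread = 0.25,
                             dice_target = 58.8),
      UC = group_preset("UC", 13, 11.9, 2.9, core_size = 2,
                        n_dominant = 1, dominant_boost = 1.8,
                        intensity_spread = 0.25,
                        dice_target = 36.4),
      IBS = group_preset("IBS", 11, 14.3, 2.9, core_size = 6,
                         n_dominant = 1, dominant_boost = 1.8,
                         intensity_spread = 0.25,
                         dice_target = 55.2))
    attr(p, "pool_size") <- 40L
  }
  attr(p, "channel") <- channel
  attr(p, "rf_range") <- c(0.10, 0.81)
  p
}
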