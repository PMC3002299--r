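# Loading-based ranking of discriminant bands.

#' Rank discriminant bands from cross-validation PLS fits
#'
#' The absolute first-component X-loading profiles of all training-segment
#' PLS models are averaged; peaks of the mean profile are the candidate
#' discriminant bands, ranked by height. For each ranked band the min-max
#' range of the loading across segments measures stability, and the
#' `consistent` flag records whether the same `top_n` positions (within
#' `tolerance`) top the ranking in every single segment.
#'
#' @param cv_models List of [fit_plsda()] models (e.g. `fold_models` of a
#'   [cross_validate_plsda()] result).
#' @param rf_axis Rf value of each X column.
#' @param top_n Number of bands reported (default 4).
#' @param tolerance Positional tolerance for the consistency check
#'   (default 0.008 Rf).
#' @param threshold Peak threshold relative to the maximum mean loading
#'   (default 0.05).
#' @return List with `bands` (data frame: `rank`, `rf`, `mean_loading`,
#'   `range_low`, `range_high`), `consistent`, and `mean_profile`.
#' @export
rank_discriminant_bands <- function(cv_models, rf_axis, top_n = 4,
                                    tolerance = 0.008, threshold = 0.05) {
  L <- vapply(cv_models, function(m) abs(m$loadings[, 1]),
              numeric(length(rf_axis)))
  mean_l <- rowMeans(L)
  if (top_n == 0)
    return(list(bands = data.frame(rank = integer(0), rf = numeric(0),
                                   mean_loading = numeric(0),
                                   range_low = numeric(0),
                                   range_high = numeric(0)),
                consistent = NA, mean_profile = mean_l))
  pk <- pick_bands(mean_l / max(mean_l), rf_axis, threshold = threshold,
                   min_separation = 0.004)
  if (nrow(pk) < top_n)
    warning("fewer loading peaks than top_n; returning all ", nrow(pk))
  pk$height <- pk$intensity * max(mean_l)
  pk <- pk[order(-pk$height), , drop = FALSE]
  sel <- utils::head(pk, top_n)
  idx <- vapply(sel$rf, function(r) which.min(abs(rf_axis - r)), integer(1))
  bands <- data.frame(rank = seq_len(nrow(sel)), rf = sel$rf,
                      mean_loading = sel$height,
                      range_low = apply(L[idx, , drop = FALSE], 1, min),
                      range_high = apply(L[idx, , drop = FALSE], 1, max))
  # consistency: every segment's own top_n peaks match (within tolerance)
  consistent <- all(vapply(seq_len(ncol(L)), function(j) {
    pj <- pick_bands(L[, j] / max(L[, j]), rf_axis, threshold = threshold,
                     min_separation = 0.004)
    if (nrow(pj) < nrow(sel)) return(FALSE)
    pj <- pj[order(-pj$intensity), , drop = FALSE]
    topj <- utils::head(pj$rf, nrow(sel))
    all(vapply(bands$rf, function(r) any(abs(topj - r) <= tolerance),
               logical(1)))
  }, logical(1)))
  list(bands = bands, consistent = consistent, mean_profile = mean_l)
}
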