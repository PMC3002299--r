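# Lane and gel-image rendering: the simulator's measurement model.
#
# A lane trace is a dense densitometric profile along the migration axis:
# a sum of Gaussian band peaks (width sigma_band on the Rf scale) at the
# warped band positions, over a small constant baseline, plus white pixel
# noise, clamped to the detector range [0, 1]. Band amplitudes are the
# subject's relative abundances scaled so the strongest band of a lane uses
# most of the dynamic range; a per-gel intensity factor emulates staining /
# imaging differences between gels (later removed by per-lane scaling).

#' Render one lane trace
#'
#' @param profile Subject profile (element of a [build_cohort()] cohort or
#'   [make_synthetic_standard()]).
#' @param distortion One row of a layout's `distortions` attribute.
#' @param lane_index,n_lanes Lane slot and gel width, for the smile term.
#' @param npix Pixels along the migration axis (default 1400; gel images
#'   carry somewhat more than 1000 pixels per lane).
#' @param band_sigma Gaussian band SD on the Rf scale (default 0.0025).
#' @param noise_sd Pixel noise SD (default 0.003 of full scale).
#' @param baseline Constant background level (default 0.005).
#' @param seed Integer seed for the noise draw.
#' @param min_resolvable Minimum post-warp spacing of planted bands; closer
#'   pairs trigger a warning (the caller should regenerate the cohort).
#' @return A `lane_trace`: list with `intensities` (length `npix`,
#'   in `[0, 1]`), `npix`, and the warped band positions as attribute
#'   `planted` (for ground-truth checks).
#' @export
render_lane <- function(profile, distortion, lane_index, n_lanes,
                        npix = 1400, band_sigma = 0.0025, noise_sd = 0.003,
                        baseline = 0.005, seed = 1L, min_resolvable = 0.005) {
  x <- seq(0, 1, length.out = npix)
  pos <- warp_position(profile$bands$rf, distortion, lane_index, n_lanes)
  if (any(diff(sort(pos)) < min_resolvable))
    warning(sprintf("lane %d: planted bands closer than %.3f Rf after warp",
                    lane_index, min_resolvable))
  amp <- profile$bands$abundance / max(profile$bands$abundance)
  signal <- rep(0, npix)
  for (i in seq_along(pos))
    signal <- signal + amp[i] * exp(-(x - pos[i])^2 / (2 * band_sigma^2))
  peak_scale <- 0.85 * distortion$intensity
  set.seed(as.integer(seed))
  v <- baseline + peak_scale * signal + rnorm(npix, 0, noise_sd)
  v <- pmin(pmax(v, 0), 1)
  structure(list(intensities = v, npix = npix),
            planted = pos, class = "lane_trace")
}

#' Render all lanes of a gel and compose the gel image
#'
#' Produces a 16-bit-style grayscale image matrix (rows = migration axis,
#' Rf increasing with row index; columns = lanes, each lane occupying a
#' fixed column span separated by background gaps) together with the lane
#' metadata table used by [extract_lanes()].
#'
#' @param layout A [plan_gels()] layout (all gels); only `gel_id`'s rows are
#'   used.
#' @param gel_id Which gel to render.
#' @param cohort The cohort providing subject profiles.
#' @param ss The synthetic-standard profile.
#' @param seed Master seed (per-lane sub-seeds are derived from it).
#' @param lane_px,gap_px Column width of a lane and of the gap between
#'   lanes (pixels).
#' @param ... Passed to [render_lane()].
#' @return List with `image` (numeric matrix in `[0, 1]`), `metadata`
#'   (the layout rows plus `col_start`, `col_end`), and `traces` (the
#'   rendered `lane_trace` objects, for round-trip tests).
#' @export
render_gel_image <- function(layout, gel_id, cohort, ss, seed = 1L,
                             lane_px = 8, gap_px = 4, ...) {
  stopifnot(inherits(layout, "gel_layout"))
  meta <- layout[layout$gel_id == gel_id, , drop = FALSE]
  if (nrow(meta) == 0) stop("unknown gel_id: ", gel_id)
  dist <- attr(layout, "distortions")
  dist <- dist[dist$gel_id == gel_id, , drop = FALSE]
  n_lanes <- attr(layout, "lanes_per_gel")
  if (nrow(meta) != n_lanes) stop("slot/trace count mismatch for ", gel_id)
  profiles <- setNames(cohort, vapply(cohort, `[[`, character(1), "subject_id"))

  dots <- list(...)
  npix <- dots$npix %||% 1400
  baseline <- dots$baseline %||% 0.005
  img <- matrix(baseline, nrow = npix,
                ncol = n_lanes * (lane_px + gap_px) + gap_px)
  traces <- vector("list", nrow(meta))
  meta$col_start <- NA_integer_; meta$col_end <- NA_integer_
  for (r in seq_len(nrow(meta))) {
    prof <- if (meta$is_SS[r]) ss else profiles[[meta$sample_id[r]]]
    if (is.null(prof)) stop("no profile for sample ", meta$sample_id[r])
    tr <- do.call(render_lane, c(list(
      profile = prof, distortion = dist, lane_index = meta$lane_index[r],
      n_lanes = n_lanes,
      seed = derive_seed(seed, paste0(gel_id, "-", meta$replicate_id[r]))),
      dots))
    cs <- gap_px + (meta$lane_index[r] - 1) * (lane_px + gap_px) + 1
    ce <- cs + lane_px - 1
    img[, cs:ce] <- tr$intensities
    meta$col_start[r] <- cs; meta$col_end[r] <- ce
    traces[[r]] <- tr
  }
  list(image = img, metadata = meta, traces = traces)
}
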