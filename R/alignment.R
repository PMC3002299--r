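# Two-stage synthetic-standard-anchored lane alignment.
#
# Stage 1 (within gel): SS band maxima are peak-picked in every SS lane of
# a gel. For each SS band, a low-degree polynomial in lane index is fitted
# to its displacement from the gel-mean position; this captures the "smile"
# curvature of a gel. Every lane is then resampled by subtracting its
# position-dependent displacement (linear interpolation between SS anchor
# positions, constant beyond the outermost anchors).
#
# Stage 2 (between gels): each gel's (corrected) SS anchor positions are
# mapped onto the global mean anchor positions by a piecewise linear warp —
# every block of data bounded by SS bands is stretched or shrunk so its
# bounding anchors land on the global means; beyond the outermost anchors
# the adjacent block's linear map is extended, which keeps the warp
# strictly increasing. The result is resampled onto the canonical
# 1001-point Rf grid, truncated to Rf in [0.09, 0.82] (731 points) and
# min-max scaled per lane to [0, 1].

#' Detect synthetic-standard anchor positions on one gel
#'
#' Peak-picks the SS band maxima of every SS lane (on the min-max scaled
#' trace, with sub-pixel parabolic refinement) and matches them to the SS
#' reference ordering by rank. SS lanes in which the expected number of
#' bands is not recovered are flagged and excluded; fewer than two usable
#' SS lanes make the gel unalignable.
#'
#' @param ss_traces List of `lane_trace` objects for the gel's SS lanes.
#' @param lane_indices Lane slots of those traces on the gel.
#' @param expected_n Number of SS bands (default 24).
#' @param threshold Peak threshold on the scaled trace (default 0.3).
#' @param min_separation Minimum peak separation in Rf (default 0.02;
#'   the SS bands are ~0.04 apart by design).
#' @return An `ss_anchor_set`: list with `anchors` (matrix, usable SS lanes
#'   x expected_n, positions on the 0-1 Rf/pixel scale), `lane_indices`,
#'   and `flagged` (lane slots excluded).
#' @export
detect_ss_anchors <- function(ss_traces, lane_indices, expected_n = 24,
                              threshold = 0.3, min_separation = 0.02) {
  stopifnot(length(ss_traces) == length(lane_indices))
  anchors <- list(); ok <- logical(length(ss_traces))
  for (i in seq_along(ss_traces)) {
    v <- ss_traces[[i]]$intensities
    x <- seq(0, 1, length.out = length(v))
    sc <- (v - min(v)) / diff(range(v))
    pk <- pick_bands(sc, x, threshold = threshold,
                     min_separation = min_separation, refine = TRUE)
    if (nrow(pk) == expected_n) {
      ok[i] <- TRUE
      anchors[[length(anchors) + 1L]] <- pk$rf
    }
  }
  if (sum(ok) < 2)
    stop("fewer than 2 usable SS lanes: gel is unalignable")
  A <- do.call(rbind, anchors)
  if (any(apply(A, 1, function(r) any(diff(r) <= 0))))
    stop("SS anchors not strictly increasing within a lane")
  structure(list(anchors = A, lane_indices = lane_indices[ok],
                 flagged = lane_indices[!ok]), class = "ss_anchor_set")
}

#' Within-gel curvature correction
#'
#' For each SS band, fits a polynomial (in lane index, default degree 2) to
#' its displacement from the gel-mean position across the SS lanes, then
#' resamples every lane of the gel with the displacement field interpolated
#' across the SS band positions (constant extrapolation beyond the first and
#' last anchor) subtracted.
#'
#' @param traces List of `lane_trace` objects — all lanes of one gel.
#' @param lane_indices Lane slots matching `traces`.
#' @param anchors An [detect_ss_anchors()] result for the gel.
#' @param degree Polynomial degree (default 2, capturing gel "smile"); if
#'   fewer SS lanes than `degree + 1` are available the degree is reduced
#'   with a warning.
#' @return List with `traces` (corrected), `anchor_means` (gel-mean SS
#'   positions, the gel's anchors for the between-gel stage), and
#'   `displacement` (function of `(position, lane_index)`, exposed for
#'   diagnostics).
#' @export
within_gel_correct <- function(traces, lane_indices, anchors, degree = 2) {
  A <- anchors$anchors
  n_ss <- nrow(A)
  if (n_ss < degree + 1) {
    degree <- n_ss - 1
    warning("fewer SS lanes than degree + 1; degree reduced to ", degree)
  }
  M <- colMeans(A)
  # per-band polynomial displacement model in lane index
  fits <- lapply(seq_len(ncol(A)), function(k) {
    d <- A[, k] - M[k]
    lm(d ~ poly(li, degree, raw = TRUE),
       data = data.frame(d = d, li = anchors$lane_indices))
  })
  disp_at <- function(lane) {
    vapply(fits, function(f)
      predict(f, newdata = data.frame(li = lane)), numeric(1))
  }
  displacement <- function(pos, lane) {
    dk <- disp_at(lane)
    approx(M, dk, xout = pos, rule = 2)$y
  }
  corrected <- lapply(seq_along(traces), function(i) {
    v <- traces[[i]]$intensities
    x <- seq(0, 1, length.out = length(v))
    src <- x + displacement(x, lane_indices[i])
    out <- approx(x, v, xout = src, rule = 2)$y
    structure(list(intensities = out, npix = length(v)),
              class = "lane_trace")
  })
  list(traces = corrected, anchor_means = M, displacement = displacement)
}

# piecewise linear map through (x0, y0) with the outer segments' slopes
# extended beyond the first/last node
piecewise_map <- function(x0, y0, xout) {
  if (any(diff(x0) <= 0) || any(diff(y0) <= 0))
    stop("non-monotone warp: crossing anchors")
  y <- approx(x0, y0, xout = xout, rule = 1)$y
  n <- length(x0)
  lo <- xout < x0[1]; hi <- xout > x0[n]
  s1 <- (y0[2] - y0[1]) / (x0[2] - x0[1])
  s2 <- (y0[n] - y0[n - 1]) / (x0[n] - x0[n - 1])
  y[lo] <- y0[1] + s1 * (xout[lo] - x0[1])
  y[hi] <- y0[n] + s2 * (xout[hi] - x0[n])
  y
}

#' Between-gel alignment onto the canonical Rf grid
#'
#' Piecewise-linearly stretches or shrinks each block of a lane bounded by
#' SS anchors so that the gel's anchors land on the global mean anchor
#' positions, and resamples the result onto the 1001-point Rf grid.
#'
#' @param trace A (within-gel corrected) `lane_trace`.
#' @param gel_anchors The gel's SS anchor positions (Rf scale).
#' @param global_anchor_means Mean SS anchor positions over all gels.
#' @return Numeric vector of length 1001 (the aligned lane, pre-truncation).
#' @export
between_gel_align <- function(trace, gel_anchors, global_anchor_means) {
  v <- trace$intensities
  x <- seq(0, 1, length.out = length(v))
  # content at global-grid position g originates from the gel position
  # obtained by the inverse warp (global means -> gel anchors)
  src <- piecewise_map(global_anchor_means, gel_anchors, rf_grid())
  approx(x, v, xout = src, rule = 2)$y
}

#' Truncate an aligned lane and scale it to [0, 1]
#'
#' Keeps the grid points with Rf in the truncation window (731 values for
#' the default `[0.09, 0.82]`) and min-max scales the result per lane, to
#' mitigate between-gel intensity variance.
#'
#' @param aligned Numeric vector of length 1001.
#' @param window Truncation window (default `c(0.09, 0.82)`).
#' @return Numeric vector (length 731 for the default window), min 0, max 1.
#' @export
truncate_and_scale <- function(aligned, window = c(0.09, 0.82)) {
  if (length(aligned) != 1001L)
    stop("expected a 1001-element aligned vector, got ", length(aligned))
  w <- aligned[rf_window_index(window)]
  r <- range(w)
  if (diff(r) == 0)
    stop("constant truncated vector: scaling undefined; lane rejected")
  (w - r[1]) / diff(r)
}

#' Align a full experiment
#'
#' Runs both alignment stages over all gels of an experiment and assembles
#' the lanes-by-731 aligned data matrix for the retained (non-SS) lanes,
#' plus diagnostics on SS convergence.
#'
#' @param traces List of `lane_trace` objects (all lanes, all gels).
#' @param metadata Matching metadata data frame.
#' @param expected_ss_bands Number of SS bands (default 24).
#' @param degree Within-gel polynomial degree (default 2).
#' @param window Truncation window.
#' @return List with:
#'   \describe{
#'     \item{X}{matrix (retained sample lanes x 731), rownames =
#'       `replicate_id`, colnames = Rf values;}
#'     \item{metadata}{metadata rows matching `X`;}
#'     \item{X_ss}{aligned SS lanes (same columns), for convergence checks;}
#'     \item{ss_positions_before, ss_positions_after}{per-SS-lane anchor
#'       positions before correction and after full alignment;}
#'     \item{global_anchor_means}{the consensus anchor positions.}
#'   }
#' @export
align_experiment <- function(traces, metadata, expected_ss_bands = 24,
                             degree = 2, window = c(0.09, 0.82)) {
  stopifnot(length(traces) == nrow(metadata))
  gels <- unique(metadata$gel_id)
  per_gel <- list()
  for (g in gels) {
    sel <- which(metadata$gel_id == g)
    ss_sel <- sel[metadata$is_SS[sel]]
    an <- detect_ss_anchors(traces[ss_sel], metadata$lane_index[ss_sel],
                            expected_n = expected_ss_bands)
    cor <- within_gel_correct(traces[sel], metadata$lane_index[sel], an,
                              degree = degree)
    per_gel[[g]] <- list(sel = sel, anchors_raw = an, corrected = cor)
  }
  G <- colMeans(do.call(rbind, lapply(per_gel, function(pg)
    pg$corrected$anchor_means)))

  n <- length(traces)
  full <- matrix(NA_real_, n, 1001L)
  for (g in gels) {
    pg <- per_gel[[g]]
    for (j in seq_along(pg$sel))
      full[pg$sel[j], ] <- between_gel_align(pg$corrected$traces[[j]],
                                             pg$corrected$anchor_means, G)
  }

  keep <- !metadata$is_SS
  X <- t(vapply(which(keep), function(i)
    truncate_and_scale(full[i, ], window), numeric(length(rf_window_index(window)))))
  rownames(X) <- metadata$replicate_id[keep]
  colnames(X) <- sprintf("%.3f", rf_grid()[rf_window_index(window)])
  X_ss <- t(vapply(which(!keep), function(i) {
    v <- full[i, ]
    w <- v[rf_window_index(window)]
    (w - min(w)) / diff(range(w))
  }, numeric(length(rf_window_index(window)))))
  rownames(X_ss) <- metadata$replicate_id[!keep]

  # SS convergence diagnostics: anchor positions before vs after
  before <- do.call(rbind, lapply(gels, function(g)
    per_gel[[g]]$anchors_raw$anchors))
  after <- t(vapply(which(!keep), function(i) {
    v <- full[i, ]
    sc <- (v - min(v)) / diff(range(v))
    pk <- pick_bands(sc, rf_grid(), threshold = 0.3,
                     min_separation = 0.02, refine = TRUE)
    if (nrow(pk) == expected_ss_bands) pk$rf
    else rep(NA_real_, expected_ss_bands)
  }, numeric(expected_ss_bands)))

  list(X = X, metadata = metadata[keep, , drop = FALSE], X_ss = X_ss,
       ss_positions_before = before, ss_positions_after = after,
       global_anchor_means = G)
}
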