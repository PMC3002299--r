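# Gel layout: slot assignment and per-gel distortion parameters.

#' Plan gels for a cohort
#'
#' Assigns every subject to at least two lanes on different gels (extra
#' capacity is used for triplicates, mirroring real loading plans), places
#' the synthetic standard in fixed slots of every gel — at least four,
#' always including both outermost lanes — and draws per-gel distortion
#' parameters: a global Rf shift, a linear stretch about mid-gel, a "smile"
#' (quadratic displacement across lane index) and a gel intensity factor.
#'
#' @param cohort A [build_cohort()] result.
#' @param lanes_per_gel Total slots per gel (default 16).
#' @param ss_slots Slot indices holding the synthetic standard
#'   (default `c(1, 6, 11, 16)`).
#' @param seed Integer seed.
#' @param max_shift,max_stretch Half-ranges of the per-gel uniform shift
#'   (Rf) and stretch (fractional) draws; defaults 0.02 and 0.02 are large
#'   enough that unaligned between-gel profiles fail Dice matching at the
#'   ±0.008 tolerance.
#' @param smile_range Range of the per-gel smile amplitude (Rf at the
#'   outermost lanes relative to centre).
#' @return A `gel_layout`: data frame with one row per lane
#'   (`gel_id`, `lane_index`, `sample_id`, `replicate_id`, `group`,
#'   `is_SS`, `channel`) and attribute `distortions` (one row per gel).
#' @export
plan_gels <- function(cohort, lanes_per_gel = 16, ss_slots = c(1, 6, 11, 16),
                      seed = 1L, max_shift = 0.02, max_stretch = 0.02,
                      smile_range = c(0.003, 0.010)) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(ss_slots) < 4) stop("at least 4 SS slots per gel are required")
  if (!(1 %in% ss_slots && lanes_per_gel %in% ss_slots))
    stop("SS slots must include both outermost lanes")
  n_sample_slots <- lanes_per_gel - length(ss_slots)
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  grps <- vapply(cohort, `[[`, character(1), "group")
  n_sub <- length(ids)
  n_gels <- ceiling(2 * n_sub / n_sample_slots)
  capacity <- n_gels * n_sample_slots

  set.seed(derive_seed(seed, "layout"))
  ord <- sample.int(n_sub)
  # duplicate every subject; fill leftover capacity with triplicates
  occurrences <- c(rep(ord, 2), ord[seq_len(capacity - 2 * n_sub)])
  # greedy: place each occurrence on the least-loaded gel not already
  # holding a lane of that subject
  load <- integer(n_gels)
  used <- vector("list", n_sub)
  assign_gel <- integer(length(occurrences))
  for (k in seq_along(occurrences)) {
    s <- occurrences[k]
    cand <- setdiff(order(load, seq_len(n_gels)), used[[s]])
    if (length(cand) == 0) cand <- order(load)[1]  # unavoidable same-gel pair
    g <- cand[which(load[cand] < n_sample_slots)][1]
    assign_gel[k] <- g
    load[g] <- load[g] + 1L
    used[[s]] <- c(used[[s]], g)
  }

  rows <- list()
  rep_counter <- integer(n_sub)
  sample_slot_idx <- setdiff(seq_len(lanes_per_gel), ss_slots)
  fill <- integer(n_gels)
  for (k in seq_along(occurrences)) {
    s <- occurrences[k]; g <- assign_gel[k]
    fill[g] <- fill[g] + 1L
    rep_counter[s] <- rep_counter[s] + 1L
    rows[[k]] <- data.frame(
      gel_id = sprintf("gel%02d", g),
      lane_index = sample_slot_idx[fill[g]],
      sample_id = ids[s],
      replicate_id = sprintf("%s_r%d", ids[s], rep_counter[s]),
      group = grps[s], is_SS = FALSE,
      channel = attr(cohort, "channel"), stringsAsFactors = FALSE)
  }
  ss_rows <- do.call(rbind, lapply(seq_len(n_gels), function(g) {
    data.frame(gel_id = sprintf("gel%02d", g), lane_index = ss_slots,
               sample_id = "SS",
               replicate_id = sprintf("SS_g%02d_s%d", g, seq_along(ss_slots)),
               group = "SS", is_SS = TRUE,
               channel = attr(cohort, "channel"), stringsAsFactors = FALSE)
  }))
  layout <- rbind(do.call(rbind, rows), ss_rows)
  layout <- layout[order(layout$gel_id, layout$lane_index), ]
  rownames(layout) <- NULL

  set.seed(derive_seed(seed, "distortions"))
  dist <- data.frame(
    gel_id = sprintf("gel%02d", seq_len(n_gels)),
    shift = runif(n_gels, -max_shift, max_shift),
    stretch = runif(n_gels, -max_stretch, max_stretch),
    smile = runif(n_gels, smile_range[1], smile_range[2]) *
      sample(c(-1, 1), n_gels, replace = TRUE),
    intensity = runif(n_gels, 0.6, 1.0), stringsAsFactors = FALSE)
  structure(layout, distortions = dist, lanes_per_gel = lanes_per_gel,
            class = c("gel_layout", "data.frame"))
}

#' Distortion warp of a gel
#'
#' Maps a latent Rf position to its observed migration position on a given
#' lane: `rf + shift + stretch * (rf - 0.5) + smile * u^2`, where `u` is the
#' lane index rescaled to `[-1, 1]` across the gel.
#'
#' @param rf Latent Rf positions.
#' @param distortion One row of the layout's `distortions` attribute.
#' @param lane_index Lane index (1-based).
#' @param n_lanes Number of lanes on the gel.
#' @return Warped positions.
#' @export
warp_position <- function(rf, distortion, lane_index, n_lanes) {
  u <- 2 * (lane_index - 1) / (n_lanes - 1) - 1
  rf + distortion$shift + distortion$stretch * (rf - 0.5) +
    distortion$smile * u^2
}
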