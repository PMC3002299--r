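# Two-stage SS-anchored alignment.

ss12 <- seq(0.08, 0.92, length.out = 12)

test_that("SS anchors are detected at the planted positions", {
  tr <- list(gauss_trace(ss12), gauss_trace(ss12))
  an <- detect_ss_anchors(tr, c(1, 5), expected_n = 12)
  expect_equal(dim(an$anchors), c(2, 12))
  expect_true(all(abs(t(an$anchors) - ss12) < 0.5 / 1399))
  # translation moves every anchor by the same amount
  tr_s <- list(gauss_trace(ss12 + 0.01), gauss_trace(ss12 + 0.01))
  an_s <- detect_ss_anchors(tr_s, c(1, 5), expected_n = 12)
  expect_equal(an_s$anchors - an$anchors,
               matrix(0.01, 2, 12), tolerance = 1e-4)
})

test_that("SS lanes with wrong band counts are flagged; <2 usable is an error", {
  tr <- list(gauss_trace(ss12), gauss_trace(ss12), gauss_trace(ss12[1:5]))
  an <- detect_ss_anchors(tr, c(1, 5, 9), expected_n = 12)
  expect_equal(an$flagged, 9)
  expect_error(detect_ss_anchors(list(gauss_trace(ss12[1:5]),
                                      gauss_trace(ss12)),
                                 c(1, 5), expected_n = 12),
               "unalignable")
})

test_that("within-gel correction is the identity for an undistorted gel", {
  tr <- list(gauss_trace(ss12), gauss_trace(c(0.3, 0.6)), gauss_trace(ss12),
             gauss_trace(ss12))
  an <- detect_ss_anchors(tr[c(1, 3, 4)], c(1, 3, 5), expected_n = 12)
  cor <- within_gel_correct(tr, c(1, 2, 3, 5), an)
  for (i in seq_along(tr))
    expect_equal(cor$traces[[i]]$intensities, tr[[i]]$intensities,
                 tolerance = 1e-6)
})

test_that("within-gel correction collapses a quadratic smile", {
  lanes <- 1:9
  smile <- function(l) 0.008 * ((l - 5) / 4)^2
  tr <- lapply(lanes, function(l) gauss_trace(ss12 + smile(l)))
  ss_lanes <- c(1, 4, 6, 9)
  an <- detect_ss_anchors(tr[ss_lanes], ss_lanes, expected_n = 12)
  sd_before <- mean(apply(an$anchors, 2, sd))
  cor <- within_gel_correct(tr, lanes, an)
  an2 <- detect_ss_anchors(cor$traces[ss_lanes], ss_lanes, expected_n = 12)
  sd_after <- mean(apply(an2$anchors, 2, sd))
  expect_gt(sd_before / sd_after, 5)
})

test_that("a sample band between two anchors moves by the interpolated displacement", {
  # SS bands displaced by 0 at 0.2 and +0.01 at 0.8 on lane 3 relative to
  # the gel mean; a band at 0.5 must move back by the midpoint value 0.005
  lanes <- c(1, 3, 5)
  disp <- c(-0.01, 0, 0.01)  # linear in lane index -> gel mean at lane 3
  tr <- lapply(disp, function(d)
    gauss_trace(c(0.2, 0.5 + 0.5 * d, 0.8 + d)))
  # anchors are the two outer bands only
  an <- structure(list(
    anchors = do.call(rbind, lapply(disp, function(d) c(0.2, 0.8 + d))),
    lane_indices = lanes, flagged = integer(0)), class = "ss_anchor_set")
  cor <- within_gel_correct(tr, lanes, an, degree = 1)
  x <- seq(0, 1, length.out = 1400)
  for (i in 1:3) {
    v <- cor$traces[[i]]$intensities
    mid_peak <- x[which(x > 0.35 & x < 0.65)[
      which.max(v[x > 0.35 & x < 0.65])]]
    expect_lt(abs(mid_peak - 0.5), 1e-3)
  }
})

test_that("between-gel alignment applies the closed-form piecewise map", {
  tr <- gauss_trace(c(0.3, 0.5))
  out <- between_gel_align(tr, gel_anchors = c(0.2, 0.8),
                           global_anchor_means = c(0.25, 0.75))
  expect_length(out, 1001)
  g <- rf_grid()
  pk <- pick_bands(out / max(out), g, threshold = 0.2)
  # 0.3 -> 0.25 + 0.1 * (0.5/0.6) = 1/3; 0.5 -> 0.5 (fixed point)
  expect_equal(pk$rf, c(1 / 3, 0.5), tolerance = 1.5e-3)
})

test_that("identity anchors give identity alignment on grid-sampled lanes", {
  g <- rf_grid()
  v <- exp(-(g - 0.4)^2 / (2 * 0.0025^2)) + 0.5 * exp(-(g - 0.7)^2 / 5e-6)
  tr <- structure(list(intensities = v, npix = 1001), class = "lane_trace")
  A <- c(0.1, 0.5, 0.9)
  out <- between_gel_align(tr, A, A)
  expect_lt(sqrt(mean((out - v)^2)) / sqrt(mean(v^2)), 1e-6)
})

test_that("crossing anchors raise a monotonicity error", {
  tr <- gauss_trace(0.5)
  expect_error(between_gel_align(tr, c(0.2, 0.8), c(0.75, 0.25)),
               "non-monotone")
  expect_error(between_gel_align(tr, c(0.8, 0.2), c(0.25, 0.75)),
               "non-monotone")
})

test_that("truncation keeps exactly 731 grid points and scales to [0, 1]", {
  ramp <- seq(0, 1, length.out = 1001)
  out <- truncate_and_scale(ramp)
  expect_length(out, 731)
  expect_equal(range(out), c(0, 1))
  expect_true(all(diff(out) > 0))
  expect_error(truncate_and_scale(rep(1, 1001)), "constant")
  expect_error(truncate_and_scale(ramp[1:900]), "1001")
})

test_that("a two-gel experiment with a pure relative shift aligns duplicates", {
  # one sample loaded on two gels that differ by a rigid shift of 0.012 Rf
  mk_gel <- function(gel, shift) {
    pos <- c(0.25, 0.47, 0.63)
    tr <- list(gauss_trace(ss12 + shift), gauss_trace(pos + shift),
               gauss_trace(ss12 + shift), gauss_trace(ss12 + shift))
    meta <- data.frame(gel_id = gel, lane_index = c(1, 2, 3, 5),
                       sample_id = c("SS", "sampleA", "SS", "SS"),
                       replicate_id = paste0(gel, "_l", c(1, 2, 3, 5)),
                       group = c("SS", "control", "SS", "SS"),
                       is_SS = c(TRUE, FALSE, TRUE, TRUE),
                       channel = "universal")
    list(traces = tr, meta = meta)
  }
  g1 <- mk_gel("gelA", 0); g2 <- mk_gel("gelB", 0.012)
  res <- align_experiment(c(g1$traces, g2$traces), rbind(g1$meta, g2$meta),
                          expected_ss_bands = 12)
  expect_equal(dim(res$X), c(2, 731))
  rf <- rf_grid()[rf_window_index()]
  b1 <- pick_bands(res$X[1, ], rf, threshold = 0.2)
  b2 <- pick_bands(res$X[2, ], rf, threshold = 0.2)
  expect_equal(nrow(b1), 3)
  expect_equal(nrow(b2), 3)
  expect_true(all(abs(b1$rf - b2$rf) <= 0.001 + 1e-9))
  # unaligned, the duplicates disagree by the full shift
  expect_equal(dice_similarity(b1, b2), 100)
})

test_that("full alignment converges all SS lanes onto the consensus", {
  runs <- calibrated_universal()
  al <- runs[[1]]$sim$aligned
  sds <- apply(al$ss_positions_after, 2, sd, na.rm = TRUE)
  expect_true(all(sds <= 0.001))
  # and alignment does not create or destroy planted bands: per-lane counts
  # equal the latent counts for nearly all lanes
  meta <- al$metadata
  co <- runs[[1]]$sim$cohort
  latent <- vapply(co, function(s) nrow(s$bands), integer(1))
  names(latent) <- vapply(co, `[[`, character(1), "subject_id")
  rf <- rf_grid()[rf_window_index()]
  counts <- vapply(seq_len(nrow(al$X)), function(i)
    nrow(pick_bands(al$X[i, ], rf)), integer(1))
  expect_gte(mean(counts == latent[meta$sample_id]), 0.95)
})
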