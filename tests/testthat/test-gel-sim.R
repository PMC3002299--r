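# Synthetic cohort and gel generation.

test_that("species pool positions are sorted with guaranteed spacing", {
  pool <- species_pool(seed = 3)
  expect_s3_class(pool, "species_pool")
  expect_true(all(diff(pool$rf) > 0))
  expect_true(all(diff(pool$rf) >= 0.006))
  expect_error(species_pool(n_bands = 400), "too dense")
})

test_that("degenerate presets give exact latent statistics", {
  pool <- species_pool(seed = 1)
  # sd = 0, mean = core: every subject carries exactly the core set
  pr <- list(control = group_preset("control", 8, 30, 0, core_size = 30,
                                    n_dominant = 0, dominant_boost = 0,
                                    intensity_spread = 0.2))
  attr(pr, "channel") <- "universal"
  co <- build_cohort(pr, pool, seed = 2)
  tr <- cohort_truth(co)
  expect_equal(tr$control$band_count_mean, 30)
  expect_true(all(tr$control$dice_values == 100))
  # no jitter, no boost: equal abundances, Shannon = log(band count) exactly
  pr2 <- list(control = group_preset("control", 5, 25, 2, core_size = 20,
                                     n_dominant = 0, dominant_boost = 0,
                                     intensity_spread = 0))
  attr(pr2, "channel") <- "universal"
  co2 <- build_cohort(pr2, pool, seed = 2)
  for (s in co2) {
    expect_equal(-sum(s$bands$abundance * log(s$bands$abundance)),
                 log(nrow(s$bands)), tolerance = 1e-12)
  }
})

test_that("subject band sets respect pool membership and invariants", {
  pool <- species_pool(seed = 5)
  co <- build_cohort(default_presets(), pool, seed = 5)
  expect_length(co, 46)
  for (s in co[c(1, 10, 25, 40)]) {
    expect_true(all(diff(s$bands$rf) > 0))
    expect_true(all(diff(s$bands$rf) >= 0.006))
    expect_equal(sum(s$bands$abundance), 1, tolerance = 1e-12)
    expect_true(all(s$bands$abundance > 0))
    expect_true(all(s$bands$label %in% pool$label))
  }
  # every subject of a group carries the full group core
  pr <- default_presets()
  ctrl <- Filter(function(s) s$group == "control", co)
  core_labels <- Reduce(intersect, lapply(ctrl, function(s) s$bands$label))
  expect_gte(length(core_labels), pr$control$core_size)
})

test_that("latent cohort statistics match the calibration targets", {
  # scaled-up groups so Monte Carlo error is small
  pr <- default_presets()
  big <- lapply(pr, function(p) { p$n_subjects <- 220L; p })
  attributes(big) <- attributes(pr)
  pool <- species_pool(seed = 11)
  co <- build_cohort(big, pool, seed = 11)
  tr <- cohort_truth(co)
  for (g in names(pr)) {
    expect_lt(abs(tr[[g]]$band_count_mean - pr[[g]]$band_count_mean), 1)
    # boosts are set so the pipeline-measured Shannon (slightly inflated by
    # the noise floor) matches the target; the latent mean sits just below
    expect_lt(abs(tr[[g]]$shannon_mean - pr[[g]]$shannon_target), 0.05)
    expect_lt(abs(tr[[g]]$dice_mean - pr[[g]]$dice_target), 2)
  }
})

test_that("cohort generation is deterministic in the seed", {
  pool <- species_pool(seed = 4)
  a <- build_cohort(default_presets(), pool, seed = 9)
  b <- build_cohort(default_presets(), pool, seed = 9)
  c <- build_cohort(default_presets(), pool, seed = 10)
  expect_identical(a[[7]]$bands, b[[7]]$bands)
  expect_false(identical(a[[7]]$bands, c[[7]]$bands))
})

test_that("synthetic standard is fixed, equally spaced and equal-abundance", {
  ss <- make_synthetic_standard()
  expect_equal(nrow(ss$bands), 24)
  expect_equal(unique(round(diff(ss$bands$rf), 6)),
               round((0.95 - 0.05) / 23, 6))
  expect_true(all(ss$bands$abundance == 1 / 24))
  expect_identical(ss, make_synthetic_standard())
  ss2 <- suppressWarnings(make_synthetic_standard(n_bands = 2))
  expect_equal(ss2$bands$rf, c(0.05, 0.95))
  expect_error(make_synthetic_standard(rf_span = c(-0.1, 0.9)), "rf_span")
})

test_that("rendered lanes place band maxima where planted", {
  dist0 <- data.frame(gel_id = "g", shift = 0, stretch = 0, smile = 0,
                      intensity = 1)
  prof <- list(subject_id = "x", group = "g", channel = "universal",
               bands = data.frame(label = "b", rf = 0.5, abundance = 1,
                                  dominant = FALSE))
  tr <- render_lane(prof, dist0, 2, 16, noise_sd = 0, baseline = 0, seed = 1)
  x <- seq(0, 1, length.out = tr$npix)
  expect_lt(abs(x[which.max(tr$intensities)] - 0.5), 0.5 / (tr$npix - 1))
  # up to ~1% attenuation when the band centre falls between pixels
  expect_equal(max(tr$intensities), 0.85, tolerance = 0.015)
  # a pure shift displaces every planted band by the shift
  dist1 <- within(dist0, shift <- 0.01)
  tr1 <- render_lane(prof, dist1, 2, 16, noise_sd = 0, baseline = 0, seed = 1)
  expect_lt(abs(x[which.max(tr1$intensities)] - 0.51), 0.5 / (tr$npix - 1))
})

test_that("peak-picking unaligned traces recovers planted band counts", {
  pr <- default_presets()
  pool <- species_pool(seed = 21)
  big <- pr
  big$control$n_subjects <- 100L
  big$UC <- NULL; big$IBS <- NULL
  attr(big, "channel") <- "universal"
  co <- build_cohort(big, pool, seed = 21)
  dist0 <- data.frame(gel_id = "g", shift = 0, stretch = 0, smile = 0,
                      intensity = 0.8)
  hits <- vapply(seq_along(co), function(i) {
    tr <- render_lane(co[[i]], dist0, 2, 16, seed = 100 + i)
    v <- tr$intensities
    sc <- (v - min(v)) / diff(range(v))
    n <- nrow(pick_bands(sc, seq(0, 1, length.out = length(v)),
                         threshold = 0.03))
    n == nrow(co[[i]]$bands)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("gel layout satisfies the loading-plan constraints", {
  co <- build_cohort(default_presets(), species_pool(seed = 2), seed = 2)
  lay <- plan_gels(co, seed = 2)
  expect_s3_class(lay, "gel_layout")
  for (g in unique(lay$gel_id)) {
    lg <- lay[lay$gel_id == g, ]
    expect_gte(sum(lg$is_SS), 4)
    expect_true(all(c(1, 16) %in% lg$lane_index[lg$is_SS]))
    expect_equal(nrow(lg), 16)
  }
  # every sample appears on at least two different gels
  smp <- lay[!lay$is_SS, ]
  n_gels_per_sample <- tapply(smp$gel_id, smp$sample_id,
                              function(x) length(unique(x)))
  expect_true(all(n_gels_per_sample >= 2))
  expect_equal(nrow(smp), 96)  # 46 duplicates + 4 triplicate lanes
})

test_that("gel images carry one metadata row per slot and round-trip traces", {
  co <- build_cohort(default_presets(), species_pool(seed = 2), seed = 2)
  lay <- plan_gels(co, seed = 2)
  rg <- render_gel_image(lay, "gel01", co, make_synthetic_standard(),
                         seed = 2)
  expect_equal(nrow(rg$metadata), 16)
  tr <- extract_lanes(rg$image, rg$metadata)
  rms <- vapply(seq_along(tr), function(i) {
    a <- tr[[i]]$intensities; b <- rg$traces[[i]]$intensities
    sqrt(mean((a - b)^2)) / diff(range(b))
  }, numeric(1))
  expect_true(all(rms < 0.01))
})
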