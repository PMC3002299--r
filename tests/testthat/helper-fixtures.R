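# Shared fixtures. The calibrated study runs are expensive (seconds each),
# so they are computed once per session and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# replicate calibrated universal-channel runs (cohort draws differ by seed;
# summaries are averaged over runs to separate recovery error from cohort
# sampling noise)
calibrated_universal <- function() memo("universal", {
  cfg <- run_config(seed = 101)
  lapply(c(101, 102, 103), function(ms) {
    sim <- simulate_channel("universal", seed = ms)
    list(sim = sim, stats = band_stats_for_channel(sim$aligned, cfg))
  })
})

calibrated_bacteroides <- function() memo("bacteroides", {
  cfg <- run_config(seed = 101)
  lapply(c(101, 102, 103), function(ms) {
    sim <- simulate_channel("bacteroides", seed = ms)
    list(sim = sim, stats = band_stats_for_channel(sim$aligned, cfg))
  })
})

group_stat <- function(runs, group, field) {
  vapply(runs, function(r) r$stats$group_summaries[[group]][[field]],
         numeric(1))
}

# a flat trace with Gaussian bands planted at given Rf positions
gauss_trace <- function(pos, amp = rep(1, length(pos)), npix = 1400,
                        sigma = 0.0025, baseline = 0) {
  x <- seq(0, 1, length.out = npix)
  v <- rep(baseline, npix)
  for (i in seq_along(pos)) v <- v + amp[i] * exp(-(x - pos[i])^2 / (2 * sigma^2))
  structure(list(intensities = v, npix = npix), class = "lane_trace")
}

# exhaustive maximum matching for the Dice oracle (recursion over the
# smaller set; feasible for sets of up to ~8 bands)
max_matching <- function(a, b, tolerance) {
  ok <- abs(outer(a, b, "-")) <= tolerance
  rec <- function(i, used) {
    if (i > length(a)) return(0L)
    best <- rec(i + 1L, used)  # leave a[i] unmatched
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  rec(1L, rep(FALSE, length(b)))
}
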