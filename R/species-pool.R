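#' Build a species pool of band positions
#'
#' The pool holds the latent "taxa" of a simulated study: each entry is one
#' phylotype whose V3 amplicon melts at a fixed position, so it always
#' migrates to the same Rf. Positions are laid out on a jittered regular
#' grid inside the truncation window, with a guaranteed minimum spacing so
#' that distinct taxa never co-migrate into one unresolvable band and never
#' fall within the Dice matching tolerance of each other.
#'
#' @param n_bands Number of pool positions (default 64).
#' @param rf_range Interval of the Rf axis occupied by the pool; kept inside
#'   the `[0.09, 0.82]` truncation window with a margin.
#' @param jitter Uniform jitter half-width applied to the regular grid (Rf).
#' @param min_spacing Minimum pairwise spacing between pool positions (Rf);
#'   an error names the pool density if the requested layout violates it.
#' @param seed Integer seed.
#' @return A `species_pool`: data frame with columns `label` and `rf`
#'   (sorted, strictly increasing).
#' @export
#' @examples
#' pool <- species_pool(seed = 1)
#' all(diff(pool$rf) >= 0.006)
species_pool <- function(n_bands = 64, rf_range = c(0.10, 0.81),
                         jitter = 5e-4, min_spacing = 0.006, seed = 1L) {
  stopifnot(n_bands >= 2, rf_range[1] > 0, rf_range[2] < 1,
            rf_range[2] > rf_range[1])
  base <- seq(rf_range[1], rf_range[2], length.out = n_bands)
  if (min(diff(base)) - 2 * jitter < min_spacing)
    stop(sprintf(
      "pool too dense: %d bands in %.2f Rf gives spacing %.4f < min_spacing %.4f",
      n_bands, diff(rf_range), min(diff(base)) - 2 * jitter, min_spacing))
  set.seed(as.integer(seed))
  rf <- base + runif(n_bands, -jitter, jitter)
  pool <- data.frame(label = sprintf("b%03d", seq_len(n_bands)), rf = rf,
                     stringsAsFactors = FALSE)
  class(pool) <- c("species_pool", "data.frame")
  pool
}
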