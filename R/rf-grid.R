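# The canonical Rf grid and truncation window.
#
# Band positions are reported on the conventional DGGE "Rf" scale, the
# relative migration distance in [0, 1]. Aligned lanes live on a fixed grid
# of 1001 points (Rf = i/1000, i = 0..1000); downstream statistics use the
# truncated window Rf in [0.09, 0.82] (731 grid points), because the
# extreme top and bottom of a gel are dominated by loading-well and
# running-front artefacts.

#' Canonical Rf grid for aligned lanes
#'
#' @return Numeric vector of 1001 Rf values, `0, 0.001, ..., 1`.
#' @export
#' @examples
#' length(rf_grid())  # 1001
rf_grid <- function() seq(0, 1, by = 0.001)

#' Indices of the truncation window on the canonical grid
#'
#' @param window Closed Rf interval retained after alignment
#'   (default `c(0.09, 0.82)`).
#' @return Integer indices into [rf_grid()] (731 of them for the default).
#' @export
rf_window_index <- function(window = c(0.09, 0.82)) {
  g <- rf_grid()
  which(g >= window[1] - 1e-9 & g <= window[2] + 1e-9)
}
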