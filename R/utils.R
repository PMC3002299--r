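# Small internal helpers: hierarchical seeding and validation.

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Stages of a study run (cohort generation, gel layout, lane rendering,
#' permutation testing) each draw their randomness from a sub-seed derived
#' deterministically from one master seed, so any stage can be re-run in
#' isolation and still reproduce the full-run result.
#'
#' @param master integer master seed.
#' @param tag character stage label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "cohort")
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v)) + 131 * sum(v)
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1)
    stop(sprintf("'%s' must be a single number in (0, 1)", name), call. = FALSE)
  invisible(x)
}
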