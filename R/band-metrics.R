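# Band-level statistics: peak picking, Shannon diversity, Dice similarity,
# replicate averaging, ANOVA with Bonferroni pairwise comparisons.

#' Peak-pick the bands of a lane
#'
#' Bands are local intensity maxima above a user-defined threshold,
#' separated by at least `min_separation` on the Rf axis. Where two maxima
#' fall within the separation, the higher peak is kept (ties: the lower
#' Rf).
#'
#' @param x Intensity vector (typically an aligned, scaled lane).
#' @param rf Rf coordinate of each element of `x`.
#' @param threshold Minimum intensity of a band on the scaled trace
#'   (default 0.03).
#' @param min_separation Minimum band separation in Rf (default 0.006, the
#'   resolvable spacing at the nominal band width; this also suppresses
#'   noise ripples on the saddle between two adjacent strong bands, which
#'   sit closer than 0.006 to a real peak).
#' @param refine If `TRUE`, refine peak positions to sub-grid precision by
#'   parabolic interpolation (used for SS anchor detection).
#' @return A `band_set` data frame with columns `rf` (strictly increasing)
#'   and `intensity`; zero rows if no band qualifies.
#' @export
#' @examples
#' g <- rf_grid()
#' x <- exp(-(g - 0.5)^2 / (2 * 0.0025^2))
#' pick_bands(x, g)
pick_bands <- function(x, rf, threshold = 0.03, min_separation = 0.006,
                       refine = FALSE) {
  stopifnot(length(x) == length(rf))
  assert_prob(threshold, "threshold")
  n <- length(x)
  # local maxima: strictly above the left neighbour, not below the right
  # (plateaus resolve to their leftmost point)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= threshold]
  if (length(cand) == 0)
    return(structure(data.frame(rf = numeric(0), intensity = numeric(0)),
                     class = c("band_set", "data.frame")))
  pos <- rf[cand]
  if (refine) {
    dx <- rf[2] - rf[1]
    for (j in seq_along(cand)) {
      i <- cand[j]
      den <- x[i - 1] - 2 * x[i] + x[i + 1]
      if (den < 0) {
        off <- 0.5 * (x[i - 1] - x[i + 1]) / den
        pos[j] <- rf[i] + max(min(off, 0.5), -0.5) * dx
      }
    }
  }
  # enforce separation: keep higher peaks first (ties -> lower Rf)
  ord <- order(-x[cand], pos)
  kept_pos <- numeric(0); kept_idx <- integer(0)
  for (j in ord) {
    if (all(abs(pos[j] - kept_pos) >= min_separation)) {
      kept_pos <- c(kept_pos, pos[j]); kept_idx <- c(kept_idx, j)
    }
  }
  o <- order(kept_pos)
  structure(data.frame(rf = kept_pos[o], intensity = x[cand][kept_idx][o]),
            class = c("band_set", "data.frame"))
}

#' Shannon diversity index of a band set
#'
#' Intensity-weighted diversity: with relative band intensities
#' `p_i = intensity_i / sum(intensity)`, `H = -sum(p_i * log(p_i))`
#' (natural log). Jointly reflects band number and evenness; equals
#' `log(n)` for n equally intense bands.
#'
#' @param bands A [pick_bands()] result (at least one band).
#' @return The Shannon index (natural log).
#' @export
#' @examples
#' shannon_index(data.frame(rf = 1:3 / 10, intensity = c(0.5, 0.25, 0.25)))
shannon_index <- function(bands) {
  if (nrow(bands) == 0) stop("Shannon index undefined for an empty band set")
  if (any(bands$intensity <= 0)) stop("band intensities must be positive")
  p <- bands$intensity / sum(bands$intensity)
  -sum(p * log(p))
}

#' Dice similarity of two band sets with positional tolerance
#'
#' Bands are matched one-to-one when their Rf positions differ by at most
#' `tolerance`, greedily in migration order (two-pointer sweep over the
#' sorted positions); with `m` matches, `D = 100 * 2m / (n_a + n_b)`
#' percent. The in-order sweep is deterministic and attains the maximum
#' matching for positions on a line (verified against an exhaustive
#' oracle in the test suite).
#'
#' @param a,b [pick_bands()] results.
#' @param tolerance Positional tolerance on the Rf scale (default 0.008).
#' @return Similarity in percent (0-100).
#' @export
#' @examples
#' a <- data.frame(rf = c(0.100, 0.200, 0.300), intensity = 1)
#' b <- data.frame(rf = c(0.105, 0.400), intensity = 1)
#' dice_similarity(a, b)  # 40
dice_similarity <- function(a, b, tolerance = 0.008) {
  na <- nrow(a); nb <- nrow(b)
  if (na + nb == 0) stop("Dice undefined: both band sets are empty")
  if (na == 0 || nb == 0) return(0)
  ra <- sort(a$rf); rb <- sort(b$rf)
  i <- 1L; j <- 1L; m <- 0L
  while (i <= na && j <= nb) {
    if (abs(ra[i] - rb[j]) <= tolerance) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (ra[i] < rb[j]) i <- i + 1L else j <- j + 1L
  }
  100 * 2 * m / (na + nb)
}

#' Average replicate measurements per sample
#'
#' Arithmetic mean of scalar metrics, or the elementwise mean of aligned
#' vectors, over the replicate lanes of each sample.
#'
#' @param x Numeric vector (one value per lane) or matrix (lanes x grid).
#' @param sample_ids Sample of each lane.
#' @return Named vector or matrix with one entry/row per unique sample, in
#'   order of first appearance.
#' @export
#' @examples
#' average_replicates(c(44, 46), c("s1", "s1"))  # s1 = 45
average_replicates <- function(x, sample_ids) {
  ids <- unique(sample_ids)
  if (is.matrix(x)) {
    out <- t(vapply(ids, function(s)
      colMeans(x[sample_ids == s, , drop = FALSE]), numeric(ncol(x))))
    rownames(out) <- ids
    out
  } else {
    vapply(setNames(ids, ids), function(s) mean(x[sample_ids == s]),
           numeric(1))
  }
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Compares per-sample values between groups: overall F test, pairwise
#' two-sample t comparisons with Bonferroni adjustment at level `alpha`,
#' and pre-checks for normality (Shapiro-Wilk per group) and equality of
#' variance (Bartlett) — reported, not enforced.
#'
#' @param values Per-sample values.
#' @param groups Group of each sample (>= 2 groups with >= 2 samples each).
#' @param alpha Significance level for the pairwise flags (default 0.01).
#' @return An `anova_report` list: `statistic` (F), `p_value`, `pairwise`
#'   (data frame: `group1`, `group2`, `p_adjusted`, `significant`),
#'   `normality_p` (per group), `variance_p`.
#' @export
anova_bonferroni <- function(values, groups, alpha = 0.01) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("at least 2 groups are required")
  if (any(tab < 2)) stop("every group needs at least 2 samples")
  fit <- aov(values ~ factor(groups))
  an <- summary(fit)[[1]]
  pw <- pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                        pool.sd = FALSE)
  pm <- pw$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pairwise <- data.frame(
    group1 = rownames(pm)[pairs[, 1]], group2 = colnames(pm)[pairs[, 2]],
    p_adjusted = pm[pairs],
    significant = pm[pairs] < alpha, stringsAsFactors = FALSE)
  norm <- vapply(names(tab), function(g) {
    v <- values[groups == g]
    if (length(v) >= 3 && length(unique(v)) > 1) shapiro.test(v)$p.value
    else NA_real_
  }, numeric(1))
  structure(list(statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 pairwise = pairwise, alpha = alpha,
                 normality_p = norm,
                 variance_p = tryCatch(bartlett.test(values, groups)$p.value,
                                       error = function(e) NA_real_)),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.2f, p = %.3g\n", x$statistic, x$p_value))
  cat(sprintf("Pairwise (Bonferroni, alpha = %.2g):\n", x$alpha))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s vs %s: p_adj = %.3g%s\n", x$pairwise$group1[i],
                x$pairwise$group2[i], x$pairwise$p_adjusted[i],
                if (x$pairwise$significant[i]) " *" else ""))
  invisible(x)
}

#' Within-group similarity summary
#'
#' All pairwise Dice similarities between the (replicate-averaged) band
#' sets of one group, summarised non-parametrically by median and IQR.
#'
#' @param band_sets List of [pick_bands()] results, one per sample.
#' @param tolerance Dice positional tolerance (default 0.008).
#' @return List: `median`, `iqr` (lower, upper), `values`, `n_pairs`.
#' @export
similarity_summary <- function(band_sets, tolerance = 0.008) {
  if (length(band_sets) < 2)
    stop("at least 2 samples are needed for a similarity summary")
  pairs <- combn(length(band_sets), 2)
  vals <- apply(pairs, 2, function(ij)
    dice_similarity(band_sets[[ij[1]]], band_sets[[ij[2]]], tolerance))
  list(median = median(vals),
       iqr = unname(quantile(vals, c(0.25, 0.75))),
       values = vals, n_pairs = length(vals))
}
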