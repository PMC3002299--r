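# PLS-DA: NIPALS-style PLS2 regression on class-indicator responses,
# leave-sample-out cross-validation and y-scrambling permutation testing.
#
# Per component the weight vector is the dominant direction maximising the
# covariance between X-scores and Y — the NIPALS PLS2 fixed point, computed
# here directly as the first left singular vector of X'Y (identical to the
# converged NIPALS iteration, without its convergence loop). X and Y are
# deflated by the extracted component. X is column-centered only (lanes are
# already scaled to [0, 1]; columns are never autoscaled).

#' Fit a PLS-DA model
#'
#' @param X Numeric matrix, lanes x variables (aligned, per-lane scaled).
#' @param labels Class of each row.
#' @param n_components Number of latent components.
#' @return A `plsda` model: `weights` (W), `loadings` (P), `scores` (T),
#'   `y_loadings` (Q), `coefficients` (per component count), `x_means`,
#'   `y_means`, `levels`.
#' @export
fit_plsda <- function(X, labels, n_components) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  Y <- outer(labels, lv, "==") + 0
  colnames(Y) <- lv
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p))
    stop("n_components exceeds the rank bound min(n - 1, p)")
  x_means <- colMeans(X); y_means <- colMeans(Y)
  Xd <- sweep(X, 2, x_means); Yd <- sweep(Y, 2, y_means)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components); Q <- matrix(0, ncol(Y), n_components)
  for (k in seq_len(n_components)) {
    M <- crossprod(Xd, Yd)                 # p x classes
    sv <- svd(M, nu = 1, nv = 0)
    w <- sv$u[, 1]
    j <- which.max(abs(w))                 # sign convention
    if (w[j] < 0) w <- -w
    t_k <- drop(Xd %*% w)
    tt <- sum(t_k^2)
    if (tt < 1e-12) stop("n_components exceeds the effective rank of X")
    p_k <- drop(crossprod(Xd, t_k)) / tt
    q_k <- drop(crossprod(Yd, t_k)) / tt
    Xd <- Xd - tcrossprod(t_k, p_k)
    Yd <- Yd - tcrossprod(t_k, q_k)
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k; Q[, k] <- q_k
  }
  # regression coefficients for each truncated model size
  coefs <- lapply(seq_len(n_components), function(k) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    Qk <- Q[, seq_len(k), drop = FALSE]
    Wk %*% solve(crossprod(Pk, Wk), t(Qk))
  })
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = Q,
                 coefficients = coefs, x_means = x_means, y_means = y_means,
                 levels = lv, n_components = n_components),
            class = "plsda")
}

#' Predict class indicators and classes from a PLS-DA model
#'
#' @param object A [fit_plsda()] model.
#' @param newdata Matrix of lanes to predict.
#' @param n_components Model size to use (default: all fitted components).
#' @param ... Unused.
#' @return List with `indicator` (predicted Y matrix) and `class`
#'   (argmax of the indicator columns).
#' @export
predict.plsda <- function(object, newdata, n_components = NULL, ...) {
  k <- n_components %||% object$n_components
  stopifnot(k >= 1, k <= object$n_components)
  Xc <- sweep(as.matrix(newdata), 2, object$x_means)
  Yhat <- sweep(Xc %*% object$coefficients[[k]], 2, object$y_means, "+")
  colnames(Yhat) <- object$levels
  list(indicator = Yhat,
       class = object$levels[max.col(Yhat, ties.method = "first")])
}

#' Project new lanes onto the PLS score space
#'
#' @param object A [fit_plsda()] model.
#' @param newdata Matrix of lanes.
#' @param n_components Number of score columns (default: all).
#' @return Matrix of scores (rows x components).
#' @export
plsda_scores <- function(object, newdata, n_components = NULL) {
  k <- n_components %||% object$n_components
  Xc <- sweep(as.matrix(newdata), 2, object$x_means)
  Tm <- matrix(0, nrow(Xc), k)
  for (j in seq_len(k)) {
    t_j <- drop(Xc %*% object$weights[, j])
    Xc <- Xc - tcrossprod(t_j, object$loadings[, j])
    Tm[, j] <- t_j
  }
  Tm
}

#' Leave-sample-out cross-validated PLS-DA
#'
#' Replicate lanes of one sample always share a cross-validation segment:
#' for each held-out sample, the model is fitted on the remaining samples'
#' lanes and the held-out lanes' predicted indicator vectors are averaged
#' before the class is assigned by argmax — the sample, not the lane, is
#' the statistical unit. The success-rate curve over component counts and
#' its first local maximum (ties toward fewer components) are reported.
#'
#' @param X Aligned matrix (lanes x variables).
#' @param labels Group of each lane.
#' @param sample_ids Sample of each lane (defines the segments).
#' @param max_components Largest model size scanned (default 10).
#' @return A `plsda_cv` list: `success_rate` (per component count),
#'   `best_k` (first local maximum), `best_rate`, `predicted` (per-sample
#'   class at `best_k`), `truth`, `segments`, and `fold_models`.
#' @export
cross_validate_plsda <- function(X, labels, sample_ids, max_components = 10) {
  X <- as.matrix(X); labels <- as.character(labels)
  samples <- unique(sample_ids)
  truth <- vapply(samples, function(s)
    unique(labels[sample_ids == s])[1], character(1))
  lv <- sort(unique(labels))
  pred_class <- matrix(NA_character_, length(samples), max_components)
  fold_models <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    hold <- sample_ids == samples[si]
    if (length(unique(labels[!hold])) < length(lv))
      stop("a segment holds all lanes of a class: degenerate training set")
    fit <- fit_plsda(X[!hold, , drop = FALSE], labels[!hold], max_components)
    fold_models[[si]] <- fit
    for (k in seq_len(max_components)) {
      ind <- predict(fit, X[hold, , drop = FALSE], n_components = k)$indicator
      pred_class[si, k] <- fit$levels[which.max(colMeans(ind))]
    }
  }
  success <- colMeans(pred_class == truth)
  best_k <- first_local_maximum(success)
  structure(list(success_rate = success, best_k = best_k,
                 best_rate = success[best_k],
                 predicted = setNames(pred_class[, best_k], samples),
                 truth = setNames(truth, samples), segments = samples,
                 fold_models = fold_models),
            class = "plsda_cv")
}

#' First local maximum of a success-rate curve
#'
#' Smallest k whose value is not exceeded by the next point (ties resolved
#' toward fewer components); the last point if the curve is strictly
#' increasing throughout.
#'
#' @param curve Numeric vector.
#' @return Integer index.
#' @export
first_local_maximum <- function(curve) {
  n <- length(curve)
  for (k in seq_len(n - 1)) if (curve[k] >= curve[k + 1]) return(k)
  n
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat("Leave-sample-out cross-validated PLS-DA\n")
  cat(sprintf("  segments: %d samples\n", length(x$segments)))
  cat(sprintf("  success rate by components: %s\n",
              paste(sprintf("%.0f%%", 100 * x$success_rate), collapse = " ")))
  cat(sprintf("  first local maximum: %.1f%% at %d component(s)\n",
              100 * x$best_rate, x$best_k))
  invisible(x)
}

#' y-scrambling permutation test of the cross-validated success rate
#'
#' Group labels are permuted at the sample level (replicate lanes keep
#' their sample's permuted label), the leave-sample-out CV success rate at
#' `n_components` is recomputed for each resample, and the observed rate is
#' referred to that null distribution. The empirical p-value is
#' `(1 + #{null >= observed}) / (n_resamples + 1)`; a Gaussian tail
#' estimate fitted to the null is also reported, since the empirical value
#' cannot resolve below its floor of `1 / (n_resamples + 1)`.
#'
#' @param X,labels,sample_ids As in [cross_validate_plsda()].
#' @param n_components Model size tested.
#' @param n_resamples Number of label permutations (>= 20; default 200).
#' @param seed Integer seed for the permutations.
#' @return A `perm_test` list: `observed`, `null_rates`, `p_empirical`,
#'   `p_tail`, `n_resamples`, `chance_rate`.
#' @export
permutation_test_plsda <- function(X, labels, sample_ids, n_components = 4,
                                   n_resamples = 200, seed = 1L) {
  if (n_resamples < 20) stop("n_resamples must be at least 20")
  X <- as.matrix(X); labels <- as.character(labels)
  samples <- unique(sample_ids)
  sample_label <- vapply(samples, function(s)
    unique(labels[sample_ids == s])[1], character(1))
  obs <- cross_validate_plsda(X, labels, sample_ids,
                              max_components = n_components)
  observed <- obs$success_rate[n_components]
  set.seed(as.integer(seed))
  null_rates <- vapply(seq_len(n_resamples), function(b) {
    perm <- sample(sample_label)
    lab_b <- perm[match(sample_ids, samples)]
    cv <- cross_validate_plsda(X, lab_b, sample_ids,
                               max_components = n_components)
    cv$success_rate[n_components]
  }, numeric(1))
  p_emp <- (1 + sum(null_rates >= observed)) / (n_resamples + 1)
  mu <- mean(null_rates); s <- sd(null_rates)
  p_tail <- if (s > 0) pnorm(observed, mu, s, lower.tail = FALSE) else NA_real_
  structure(list(observed = observed, null_rates = null_rates,
                 p_empirical = p_emp, p_tail = p_tail,
                 n_resamples = n_resamples,
                 chance_rate = max(table(sample_label)) / length(samples)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "y-scrambling permutation test (%d resamples)\n  observed %.1f%%, null %.1f%% +/- %.1f%%\n  p_empirical = %.4g (floor %.4g), Gaussian tail p = %.3g\n",
    x$n_resamples, 100 * x$observed, 100 * mean(x$null_rates),
    100 * sd(x$null_rates), x$p_empirical, 1 / (x$n_resamples + 1), x$p_tail))
  invisible(x)
}
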