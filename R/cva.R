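# Canonical variate analysis on PLS scores: the optimal low-dimensional
# view of a multi-group structure (at most groups - 1 canonical variates).

#' Fit a canonical variate analysis
#'
#' Canonical directions are the leading eigenvectors of
#' `solve(W) %*% B`, where `W` and `B` are the within- and between-group
#' scatter matrices of the input scores; they maximise between-group
#' relative to within-group separation. For 3 groups the projection is
#' 2-dimensional.
#'
#' @param scores Numeric matrix (lanes x input dimensions), typically the
#'   first K PLS score columns.
#' @param labels Group of each row.
#' @param n_dim Number of canonical variates kept
#'   (default `min(groups - 1, ncol(scores))`).
#' @return A `cva` list: `projection` (lanes x n_dim canonical scores),
#'   `directions`, `eigenvalues`, `centroids` (group means in canonical
#'   space), `means`, `levels`.
#' @export
fit_cva <- function(scores, labels, n_dim = NULL) {
  S <- as.matrix(scores); labels <- as.character(labels)
  lv <- sort(unique(labels))
  g <- length(lv); p <- ncol(S)
  n_dim <- n_dim %||% min(g - 1, p)
  mu <- colMeans(S)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (l in lv) {
    Sl <- S[labels == l, , drop = FALSE]
    ml <- colMeans(Sl)
    W <- W + crossprod(sweep(Sl, 2, ml))
    B <- B + nrow(Sl) * tcrossprod(ml - mu)
  }
  W <- W / (nrow(S) - g); B <- B / (g - 1)
  if (rcond(W) < 1e-12) {
    warning("singular within-group scatter; ridge added")
    W <- W + diag(1e-8 * sum(diag(W)), p)
  }
  eig <- eigen(solve(W, B))
  keep <- seq_len(n_dim)
  V <- Re(eig$vectors[, keep, drop = FALSE])
  ev <- Re(eig$values[keep])
  proj <- S %*% V
  centroids <- t(vapply(lv, function(l)
    colMeans(proj[labels == l, , drop = FALSE]), numeric(n_dim)))
  structure(list(projection = proj, directions = V, eigenvalues = ev,
                 centroids = centroids, means = mu, levels = lv),
            class = "cva")
}

#' Leave-sample-out cross-validated CVA of PLS scores
#'
#' For each held-out sample, a PLS-DA model and a CVA are fitted on the
#' training lanes only, and the held-out lanes are projected through both
#' maps; canonical score signs are aligned to a reference fit so folds can
#' be overlaid.
#'
#' @param X Aligned matrix (lanes x variables).
#' @param labels Group of each lane.
#' @param sample_ids Sample of each lane.
#' @param n_components PLS model size feeding the CVA (default 4).
#' @return List with `projection` (lanes x 2, cross-validated canonical
#'   scores), `labels`, `centroids` (per group, of the cross-validated
#'   scores) and `reference` (the full-data `cva`).
#' @export
cva_cross_validated <- function(X, labels, sample_ids, n_components = 4) {
  X <- as.matrix(X); labels <- as.character(labels)
  full_pls <- fit_plsda(X, labels, n_components)
  reference <- fit_cva(full_pls$scores, labels)
  n_dim <- ncol(reference$projection)
  proj <- matrix(NA_real_, nrow(X), n_dim)
  for (s in unique(sample_ids)) {
    hold <- sample_ids == s
    fit <- fit_plsda(X[!hold, , drop = FALSE], labels[!hold], n_components)
    cva <- fit_cva(fit$scores, labels[!hold])
    # align fold directions with the reference (sign only)
    sgn <- sign(colSums(cva$directions * reference$directions[
      , seq_len(ncol(cva$directions)), drop = FALSE]))
    sgn[sgn == 0] <- 1
    sc <- plsda_scores(fit, X[hold, , drop = FALSE])
    proj[hold, ] <- sweep(sc %*% cva$directions, 2, sgn, "*")
  }
  lv <- sort(unique(labels))
  centroids <- t(vapply(lv, function(l)
    colMeans(proj[labels == l, , drop = FALSE]), numeric(n_dim)))
  list(projection = proj, labels = labels, centroids = centroids,
       reference = reference)
}
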