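# PLS-DA, cross-validation, permutation testing, CVA and band ranking.

test_that("PLS components agree with an independent implementation up to sign", {
  skip_if_not_installed("mixOmics")
  check_case <- function(n, p, ncomp, seed) {
    set.seed(seed)
    X <- matrix(rnorm(n * p), n, p)
    lab <- sample(rep(c("a", "b", "c"), length.out = n))
    Y <- unclass(outer(lab, sort(unique(lab)), "==") + 0)
    ours <- fit_plsda(X, lab, ncomp)
    oracle <- mixOmics::pls(X, Y, ncomp = ncomp, scale = FALSE,
                            mode = "regression")
    for (k in seq_len(ncomp)) {
      d <- min(max(abs(ours$scores[, k] - oracle$variates$X[, k])),
               max(abs(ours$scores[, k] + oracle$variates$X[, k])))
      expect_lt(d / max(abs(ours$scores[, k])), 1e-6)
    }
  }
  check_case(20, 10, 3, seed = 2)
  check_case(50, 731, 5, seed = 7)
})

test_that("PLS scores are mutually orthogonal and weights unit-norm", {
  set.seed(5)
  X <- matrix(rnorm(40 * 60), 40, 60)
  fit <- fit_plsda(X, rep(c("a", "b"), 20), 6)
  G <- crossprod(fit$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  expect_equal(colSums(fit$weights^2), rep(1, 6), tolerance = 1e-9)
})

test_that("a separable two-class problem is solved by one component", {
  set.seed(8)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(lab == "a", 1, -1), matrix(rnorm(n * 9, 0, 0.01), n, 9))
  fit <- fit_plsda(X, lab, 1)
  expect_equal(predict(fit, X, 1)$class, lab)
})

test_that("training success is near chance for permuted labels on random data", {
  set.seed(9)
  acc <- replicate(20, {
    X <- matrix(rnorm(90 * 10), 90, 10)
    lab <- sample(rep(c("a", "b", "c"), 30))
    fit <- fit_plsda(X, lab, 1)
    mean(predict(fit, X, 1)$class == lab)
  })
  # chance is 1/3 for balanced groups; a single noise component can only
  # overfit mildly at n >> p
  expect_lt(abs(mean(acc) - 1 / 3), 0.12)
})

test_that("leave-sample-out CV keeps replicates together and scores per sample", {
  set.seed(10)
  n_samp <- 24
  lab_s <- rep(c("a", "b", "c"), each = n_samp / 3)
  # class means on a triangle (collinear means would mask the middle class
  # for any linear indicator classifier)
  mu1 <- ifelse(lab_s == "a", -3, ifelse(lab_s == "b", 3, 0))
  mu2 <- ifelse(lab_s == "c", 4, 0)
  # two replicate lanes per sample
  sample_ids <- rep(sprintf("s%02d", 1:n_samp), each = 2)
  labs <- rep(lab_s, each = 2)
  X <- cbind(rep(mu1, each = 2) + rnorm(2 * n_samp, 0, 0.2),
             rep(mu2, each = 2) + rnorm(2 * n_samp, 0, 0.2),
             matrix(rnorm(2 * n_samp * 8, 0, 0.5), 2 * n_samp, 8))
  cv <- cross_validate_plsda(X, labs, sample_ids, max_components = 4)
  expect_length(cv$success_rate, 4)
  expect_equal(length(cv$truth), n_samp)
  expect_equal(cv$best_rate, 1)
  # success is invariant to lane order and to group renaming
  perm <- sample(nrow(X))
  cv2 <- cross_validate_plsda(X[perm, ], labs[perm], sample_ids[perm],
                              max_components = 4)
  expect_equal(cv2$success_rate, cv$success_rate)
  relabel <- c(a = "Z", b = "Q", c = "M")[labs]
  cv3 <- cross_validate_plsda(X, relabel, sample_ids, max_components = 4)
  expect_equal(cv3$success_rate, cv$success_rate)
  # a segment holding every lane of a class is degenerate
  tiny_ids <- c("s1", "s1", "s2", "s2", "s3", "s3")
  tiny_lab <- c("a", "a", "b", "b", "c", "c")
  expect_error(cross_validate_plsda(X[1:6, ], tiny_lab, tiny_ids, 2),
               "degenerate")
})

test_that("scrambled labels drop CV success to chance", {
  set.seed(11)
  n_samp <- 24
  sample_ids <- rep(sprintf("s%02d", 1:n_samp), each = 2)
  labs <- rep(rep(c("a", "b", "c"), each = n_samp / 3), each = 2)
  X <- matrix(rnorm(2 * n_samp * 30), 2 * n_samp, 30)
  cv <- cross_validate_plsda(X, labs, sample_ids, max_components = 3)
  expect_lt(max(cv$success_rate), 0.7)
})

test_that("first_local_maximum follows the tie-toward-fewer rule", {
  expect_equal(first_local_maximum(c(0.5, 0.8, 0.8, 0.9)), 2)
  expect_equal(first_local_maximum(c(0.9, 0.5, 0.6)), 1)
  expect_equal(first_local_maximum(c(0.2, 0.4, 0.6)), 3)
})

test_that("permutation null is centred on chance and p has the right floor", {
  set.seed(12)
  n_samp <- 30
  sample_ids <- rep(sprintf("s%02d", 1:n_samp), each = 2)
  labs <- rep(rep(c("a", "b", "c"), each = n_samp / 3), each = 2)
  X <- matrix(rnorm(2 * n_samp * 25), 2 * n_samp, 25)
  pt <- permutation_test_plsda(X, labs, sample_ids, n_components = 2,
                               n_resamples = 60, seed = 4)
  se <- sd(pt$null_rates) / sqrt(pt$n_resamples)
  # held-out samples shrink their own class in the training fold, so the
  # null mean carries a small finite-sample bias around the chance rate
  expect_lt(abs(mean(pt$null_rates) - 1 / 3), 2 * se + 0.08)
  expect_gte(pt$p_empirical, 1 / 61)
  # random labels on random data should not look significant
  expect_gt(pt$p_empirical, 0.05)
  expect_error(permutation_test_plsda(X, labs, sample_ids, 2,
                                      n_resamples = 10), "at least 20")
})

test_that("CVA yields groups-minus-one canonical variates and null eigenvalues for equal means", {
  set.seed(13)
  lab <- rep(c("a", "b", "c"), each = 20)
  S <- cbind(ifelse(lab == "a", -2, ifelse(lab == "b", 0, 2)) + rnorm(60, 0, 0.4),
             matrix(rnorm(60 * 3), 60, 3))
  cva <- fit_cva(S, lab)
  expect_equal(ncol(cva$projection), 2)
  expect_equal(nrow(cva$centroids), 3)
  expect_gt(cva$eigenvalues[1], 10)
  S0 <- matrix(rnorm(60 * 4), 60, 4)
  cva0 <- fit_cva(S0, lab)
  # no real structure: eigenvalues stay at the finite-sample noise level,
  # far below the structured case above
  expect_lt(max(abs(cva0$eigenvalues)), 3)
})

test_that("a single planted discriminant band is top-ranked consistently", {
  set.seed(14)
  n_samp <- 30
  sample_ids <- rep(sprintf("s%02d", 1:n_samp), each = 2)
  lab_s <- rep(c("control", "UC", "IBS"), each = n_samp / 3)
  labs <- rep(lab_s, each = 2)
  p <- 200
  rf_axis <- seq(0.1, 0.8, length.out = p)
  X <- matrix(rnorm(2 * n_samp * p, 0, 0.05), 2 * n_samp, p)
  X[, 120] <- X[, 120] + ifelse(labs == "control", 1, 0)  # controls only
  cv <- cross_validate_plsda(X, labs, sample_ids, max_components = 2)
  rk <- rank_discriminant_bands(cv$fold_models, rf_axis, top_n = 1)
  expect_equal(rk$bands$rf[1], rf_axis[120], tolerance = 1e-9)
  expect_true(rk$consistent)
  expect_true(rk$bands$range_low[1] <= rk$bands$mean_loading[1])
  empty <- rank_discriminant_bands(cv$fold_models, rf_axis, top_n = 0)
  expect_equal(nrow(empty$bands), 0)
})
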