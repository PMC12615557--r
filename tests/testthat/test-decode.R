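# SVR solver, per-bin decoding, permutation inference, clusters,
# meaningfulness, and group comparison.

test_that("the coordinate-descent SVR agrees with LIBSVM (e1071)", {
  skip_if_not_installed("e1071")
  set.seed(3)
  n <- 200; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(scale(X %*% rnorm(p) * 0.3 + rnorm(n)))
  fit <- svr_fit(X, y, max_sweeps = 2000, tol = 1e-5)
  ref <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                    cost = 1, epsilon = 0.1, scale = FALSE, fitted = FALSE)
  w_ref <- drop(crossprod(ref$SV, ref$coefs))
  Xt <- matrix(rnorm(300 * p), 300, p)
  pred <- svr_predict(fit, Xt)
  pred_ref <- drop(Xt %*% w_ref - ref$rho)
  expect_gt(cor(pred, pred_ref), 0.999)
  expect_lt(max(abs(fit$w - w_ref)), 0.05)
})

test_that("decoding recovers a perfect signal and stays null on noise", {
  set.seed(4)
  n <- 200
  y <- rnorm(n)
  X <- cbind(y, matrix(rnorm(n * 7), n, 7))
  expect_gt(decode_bin(X, y, seed = 1), 0.95)

  # null features: mean observed r across seeds stays near zero
  rs <- vapply(1:50, function(s) {
    set.seed(s)
    decode_bin(matrix(rnorm(n * 8), n, 8), rnorm(n), repetitions = 2,
               seed = s)
  }, 0.0)
  expect_gt(mean(rs), -0.07)
  expect_lt(mean(rs), 0.07)

  expect_error(decode_bin(X, rep(1, n)), "constant")
})

test_that("a planted multivariate effect decodes near its population level", {
  set.seed(6)
  n <- 400; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  signal <- as.numeric(scale(X %*% rep(1, p)))
  r_pop <- 0.3
  y <- r_pop * signal + sqrt(1 - r_pop^2) * rnorm(n)
  r <- decode_bin(X, y, seed = 2)
  expect_gte(r, 0.2)
  expect_lte(r, 0.4)
})

test_that("decode_spectrum is per-bin decode_bin and handles aperiodic shape", {
  set.seed(7)
  n <- 60
  feats <- array(rnorm(n * 4 * 3), c(n, 4, 3))
  y <- rnorm(n)
  rs <- decode_spectrum(feats, y, folds = 5, repetitions = 2, seed = 9)
  expect_length(rs, 3)
  expect_equal(rs[2], decode_bin(feats[, , 2], y, folds = 5,
                                 repetitions = 2, seed = 9),
               tolerance = 1e-10)
  # aperiodic-parameter tensors have exactly two slices
  ap <- array(rnorm(n * 4 * 2), c(n, 4, 2))
  expect_length(decode_spectrum(ap, y, folds = 5, repetitions = 2, seed = 1),
                2)
})

test_that("an alpha-band association peaks inside 8-13 Hz", {
  coh <- planted_cohort(n = 300, r = 0.5, seed = 31)
  feats <- total_features(coh, "pre_open")
  r <- decode_spectrum(feats, coh$behavioral$fluid, repetitions = 3,
                       seed = 8)
  expect_true(which.max(r) %in% 8:13)
})

test_that("permutation p-values follow the add-one rule and are valid", {
  set.seed(11)
  n <- 120
  feats <- array(rnorm(n * 4 * 5), c(n, 4, 5))
  y <- rnorm(n)
  pn <- permutation_null(feats, y, B = 100, seed = 12, repetitions = 2,
                         perm_repetitions = 1)
  expect_equal(dim(pn$null), c(100, 5))
  recomputed <- (1 + colSums(pn$null >=
    matrix(pn$observed, 100, 5, byrow = TRUE))) / 101
  expect_equal(pn$p, recomputed)
  expect_true(all(pn$p > 0 & pn$p <= 1))
  # a strong effect beats every permutation: p at the add-one floor
  y2 <- as.numeric(scale(feats[, 1, 1])) + rnorm(n, 0, 0.1)
  pn2 <- permutation_null(feats, y2, B = 100, seed = 13, repetitions = 2,
                          perm_repetitions = 1)
  expect_equal(pn2$p[1], 1 / 101)
})

test_that("cluster correction keeps only runs of adjacent significant bins", {
  p <- rep(0.5, 30)
  p[1:2] <- c(0.005, 0.008)
  cl <- cluster_correction(p)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(1, 2))

  p2 <- rep(0.5, 30); p2[10] <- 0.005
  expect_equal(nrow(cluster_correction(p2)), 0)
  expect_equal(nrow(cluster_correction(rep(0.5, 30))), 0)

  p3 <- rep(0.5, 30); p3[5:9] <- 0.001; p3[20:21] <- 0.009
  cl3 <- cluster_correction(p3)
  expect_equal(cl3$start, c(5, 20))
  expect_equal(cl3$size, c(5, 2))
})

test_that("meaningfulness requires the threshold in every condition", {
  r <- matrix(0.1, 4, 30)
  r[, 10] <- 0.25
  expect_true(meaningful_effects(r)[10])
  expect_equal(sum(meaningful_effects(r)), 1)
  r[4, 10] <- 0.19
  expect_false(meaningful_effects(r)[10])
  # sensitivity threshold variant
  expect_true(meaningful_effects(r, threshold = 0.13)[10])
  r[1, 1] <- NA
  expect_error(meaningful_effects(r), "missing")
})

test_that("gender z-test matches the Fisher-z difference formula", {
  eq <- compare_groups(0.2, 100, 0.2, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  out <- compare_groups(0.3, 386, 0.1, 386)
  z_hand <- (atanh(0.3) - atanh(0.1)) / sqrt(2 / 383)
  expect_equal(out$z, z_hand, tolerance = 1e-12)
  expect_equal(out$p_holm, out$p)       # single test: Holm is identity
  expect_error(compare_groups(1, 100, 0.2, 100))
})

test_that("decoding is deterministic under a fixed seed", {
  coh <- null_cohort(n = 60, seed = 5)
  feats <- total_features(coh, "pre_open")
  y <- coh$behavioral$fluid
  a <- permutation_null(feats[, , 1:4, drop = FALSE], y, B = 100, seed = 3,
                        repetitions = 2, perm_repetitions = 1, folds = 5)
  b <- permutation_null(feats[, , 1:4, drop = FALSE], y, B = 100, seed = 3,
                        repetitions = 2, perm_repetitions = 1, folds = 5)
  expect_identical(a, b)
})
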