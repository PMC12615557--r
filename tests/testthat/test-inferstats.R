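# Score construction, reliability, outlier screen, rank correlations,
# multiple-testing adjustment, topography, descriptive tests.

test_that("sleepiness composites match a hand computation (pooled z)", {
  pre <- data.frame(tired = c(1, 2, 3, 4, 5), exhaust = c(2, 2, 3, 5, 5))
  post <- data.frame(tired = c(3, 4, 5, 6, 7), exhaust = c(3, 3, 5, 6, 7))
  comp <- build_sleepiness(pre, post)
  # hand computation with pooled mean/SD per item
  zt <- function(x) (x - mean(c(pre$tired, post$tired))) /
    sd(c(pre$tired, post$tired))
  ze <- function(x) (x - mean(c(pre$exhaust, post$exhaust))) /
    sd(c(pre$exhaust, post$exhaust))
  expect_equal(comp$pre, (zt(pre$tired) + ze(pre$exhaust)) / 2)
  expect_equal(comp$post, (zt(post$tired) + ze(post$exhaust)) / 2)
  # pooled composite mean ~ 0; post level difference preserved
  expect_equal(mean(c(comp$pre, comp$post)), 0, tolerance = 1e-12)
  expect_gt(mean(comp$post), mean(comp$pre))
  # composite rank order follows perfectly correlated items
  expect_equal(order(comp$pre), order(pre$tired))
  # zero-variance item is an error
  expect_error(build_sleepiness(data.frame(a = rep(3, 5), b = 1:5),
                                data.frame(a = rep(3, 5), b = 1:5)),
               "zero-variance")
})

test_that("Spearman-Brown prophecy formula", {
  expect_equal(round(spearman_brown(0.67), 2), 0.80)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(0.999999), 1, tolerance = 1e-5)
  expect_error(spearman_brown(1.2))
})

test_that("outlier screen is one-sided below the mean", {
  set.seed(21)
  x <- rnorm(200)
  x[7] <- -5
  keep <- exclude_outliers(x)
  expect_false(keep[7])
  expect_equal(sum(!keep), 1)
  expect_true(all(exclude_outliers(rep(3, 10))))
  x2 <- rnorm(200)
  x2[5] <- mean(x2) + 5 * sd(x2)
  expect_true(exclude_outliers(x2)[5])               # high tail kept
  expect_false(exclude_outliers(x2, side = "both")[5])
})

test_that("spearman_ci equals brute-force rank Pearson with a sane CI", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  ct <- spearman_ci(x, y)
  expect_equal(ct$rho, cor(rank(x), rank(y)))
  expect_equal(ct$rho, cor(x, y, method = "spearman"))
  expect_true(ct$ci_lo <= ct$rho && ct$rho <= ct$ci_hi)

  xx <- c(1.2, 3.4, 2.2, 5.5, 4.1, 7.7, 6.3, 8.8, 9.9, 10.1)
  expect_equal(spearman_ci(xx, xx * 2 + 1)$rho, 1)
  expect_equal(spearman_ci(xx, -xx)$rho, -1)
  expect_error(spearman_ci(xx, rep(1, 10)), "zero rank")
})

test_that("spearman_ci coverage is adequate at rho = 0.3", {
  rho <- 0.3
  covered <- vapply(1:500, function(s) {
    set.seed(s)
    z <- rnorm(200)
    x <- z
    y <- rho * z + sqrt(1 - rho^2) * rnorm(200)
    ct <- spearman_ci(x, y)
    # population Spearman rho of a bivariate normal
    rs <- 6 / pi * asin(rho / 2)
    ct$ci_lo <= rs && rs <= ct$ci_hi
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("partial Spearman removes a shared covariate", {
  set.seed(30)
  n <- 500
  z <- rnorm(n)
  # z independent of both: partial ~ plain
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  expect_equal(partial_spearman(x, y, z)$rho, spearman_ci(x, y)$rho,
               tolerance = 0.02)
  # x and y related only through z: partial ~ 0
  x2 <- z + rnorm(n); y2 <- z + rnorm(n)
  expect_lt(abs(partial_spearman(x2, y2, z)$rho), 0.1)
  expect_gt(spearman_ci(x2, y2)$rho, 0.3)
  # covariate equal to a variable is degenerate
  expect_error(partial_spearman(x, y, y), "degenerate")
})

test_that("Holm and BH match hand-stepped references", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(rep(0.02, 4)), rep(0.08, 4))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  # permutation equivariance
  p <- c(0.3, 0.01, 0.8, 0.04)
  perm <- c(3, 1, 4, 2)
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
  # adjusted >= raw, both monotone
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(fdr_adjust(p) >= p))
})

test_that("correlation topography flags planted electrodes under FDR", {
  set.seed(40)
  n <- 400
  scores <- rnorm(n)
  mk <- function() matrix(rnorm(n * 12), n, 12,
                          dimnames = list(NULL, sprintf("E%02d", 1:12)))
  bp <- list(pre = list(theta = mk(), alpha = mk()),
             post = list(theta = mk(), alpha = mk()))
  # plant a sleepiness-theta effect at five frontal electrodes (pre)
  for (e in 1:5)
    bp$pre$theta[, e] <- 0.4 * scores + sqrt(1 - 0.16) * rnorm(n)
  topo <- correlation_topography(bp, scores)
  expect_equal(nrow(topo), 2 * 2 * 12)        # bands x conditions x electrodes
  hit <- topo$significant[topo$condition == "pre" & topo$band == "theta"][1:5]
  expect_gte(sum(hit), 3)
  rest <- topo$significant[!(topo$condition == "pre" & topo$band == "theta" &
                             topo$electrode %in% sprintf("E%02d", 1:5))]
  expect_lt(mean(rest), 0.1)

  # null battery: flagged fraction ~ 0
  bp0 <- list(pre = list(theta = mk(), alpha = mk()))
  topo0 <- correlation_topography(bp0, scores)
  expect_lte(mean(topo0$significant), 0.05)
})

test_that("variance-ratio F reproduces the printed descriptive", {
  vt <- variance_ratio_test(11.16, 478, 7.02, 772)
  expect_equal(round(vt$F, 2), 1.59)
  expect_equal(vt$df1, 477)
  expect_equal(vt$df2, 771)
  expect_lt(vt$p, 0.001)
  expect_equal(variance_ratio_test(4, 50, 4, 50)$F, 1)
  # order invariance
  expect_equal(variance_ratio_test(7.02, 772, 11.16, 478)$F, vt$F)
})

test_that("paired t and d_av behave on shifted and fixture data", {
  set.seed(50)
  pre <- rnorm(20, 10, 2)
  post <- pre + 1.5 + rnorm(20, 0, 0.4)
  out <- paired_t_and_d(pre, post)
  t_hand <- mean(post - pre) / (sd(post - pre) / sqrt(20))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 19)
  d_hand <- mean(post - pre) / ((sd(pre) + sd(post)) / 2)
  expect_equal(out$d, d_hand)
  expect_true(out$d_lo <= out$d && out$d <= out$d_hi)
  # near-pure shift: d ~ shift / sd
  post2 <- pre + 2 + rnorm(20, 0, 1e-3)
  expect_equal(paired_t_and_d(pre, post2)$d, 2 / sd(pre), tolerance = 0.01)
  expect_error(paired_t_and_d(pre, pre), "zero difference")
})
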