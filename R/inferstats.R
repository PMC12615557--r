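# Behavioral-score construction and the univariate statistics battery:
# sleepiness composites, reliability step-up, outlier screening, Spearman
# and partial Spearman correlations with Bonett-Wright CIs, Holm and BH
# adjustment, per-electrode correlation topography, and descriptive tests.

#' Build pre/post sleepiness composites from two Likert items
#'
#' Each item (tiredness, exhaustion) is z-standardized and the composite is
#' the mean of the two z-scores. By default standardization uses the mean
#' and SD pooled over both timepoints, so the pooled composite mean is ~0
#' while pre and post retain their level difference (a within-timepoint
#' variant is available but removes that difference by construction).
#'
#' @param pre,post Data frames or matrices with two columns each
#'   (tiredness, exhaustion) for the same participants.
#' @param scope `"pooled"` (default) or `"within"` timepoint
#'   standardization.
#' @return List with numeric vectors `pre` and `post`; participants with a
#'   missing item get `NA`.
#' @export
build_sleepiness <- function(pre, post, scope = c("pooled", "within")) {
  scope <- match.arg(scope)
  pre <- as.matrix(pre); post <- as.matrix(post)
  stopifnot(ncol(pre) == 2, ncol(post) == 2, nrow(pre) == nrow(post))
  zit <- function(x, mu, sdv) {
    if (sdv == 0) stop("zero-variance item; composite undefined")
    (x - mu) / sdv
  }
  zpre <- zpost <- matrix(NA_real_, nrow(pre), 2)
  for (j in 1:2) {
    if (scope == "pooled") {
      pooled <- c(pre[, j], post[, j])
      mu <- mean(pooled, na.rm = TRUE); sdv <- sd(pooled, na.rm = TRUE)
      zpre[, j] <- zit(pre[, j], mu, sdv)
      zpost[, j] <- zit(post[, j], mu, sdv)
    } else {
      zpre[, j] <- zit(pre[, j], mean(pre[, j], na.rm = TRUE),
                       sd(pre[, j], na.rm = TRUE))
      zpost[, j] <- zit(post[, j], mean(post[, j], na.rm = TRUE),
                        sd(post[, j], na.rm = TRUE))
    }
  }
  list(pre = rowMeans(zpre), post = rowMeans(zpost))
}

#' Spearman-Brown stepped-up reliability
#'
#' `k r / (1 + (k - 1) r)`: the projected reliability of a test lengthened
#' k-fold from an inter-part correlation (k = 2 for a two-item composite).
#'
#' @param r Inter-part correlation in (-1, 1).
#' @param k Lengthening factor.
#' @return Stepped-up reliability.
#' @export
spearman_brown <- function(r, k = 2) {
  stopifnot(r > -1, r < 1)
  denom <- 1 + (k - 1) * r
  if (abs(denom) < 1e-12) stop("undefined at r = -1/(k-1)")
  k * r / denom
}

#' Low-tail outlier screen on a score vector
#'
#' Drops scores more than `sd_mult` SDs below the sample mean (one-sided by
#' default, matching a floor-effects screen; `side = "both"` also drops the
#' upper tail). Zero-variance input keeps everyone.
#'
#' @param scores Numeric vector, n >= 3.
#' @param sd_mult SD multiplier (default 3.3).
#' @param side `"below"` or `"both"`.
#' @return Logical keep mask.
#' @export
exclude_outliers <- function(scores, sd_mult = 3.3,
                             side = c("below", "both")) {
  side <- match.arg(side)
  stopifnot(length(scores) >= 3)
  mu <- mean(scores); sdv <- sd(scores)
  if (sdv == 0) return(rep(TRUE, length(scores)))
  keep <- scores >= mu - sd_mult * sdv
  if (side == "both") keep <- keep & scores <= mu + sd_mult * sdv
  keep
}

#' Spearman correlation with Bonett-Wright confidence interval
#'
#' rho is the Pearson correlation of average ranks; the 95% CI uses the
#' Fisher transform with the Bonett-Wright standard error
#' `sqrt((1 + rho^2/2) / (n - 3))`; the two-sided p comes from the
#' t approximation with n - 2 df.
#'
#' @param x,y Paired numeric vectors, n >= 10; ties allowed.
#' @param conf Confidence level.
#' @return Data frame (one row): `rho`, `ci_lo`, `ci_hi`, `p`, `n`, `method`.
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 10)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop("zero rank variance")
  rho <- cor(rx, ry)
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(atanh(rho) + c(-1, 1) * zc * se)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(rho = rho, ci_lo = ci[1], ci_hi = ci[2], p = p, n = n,
             method = "spearman")
}

#' Partial Spearman correlation controlling for one covariate
#'
#' Rank-transforms all three variables and applies the first-order partial
#' correlation formula
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`; p from the t
#' approximation with n - 3 df and CI via Bonett-Wright on the partial rho.
#'
#' @param x,y Variables of interest; `z` the controlled covariate. n >= 10.
#' @param conf Confidence level.
#' @return Data frame as in [spearman_ci()] with `method = "partial-spearman"`.
#' @export
partial_spearman <- function(x, y, z, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  stopifnot(n >= 10)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate: covariate collinear with a variable")
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  se <- sqrt((1 + rho^2 / 2) / (n - 4))
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(atanh(rho) + c(-1, 1) * zc * se)
  tstat <- rho * sqrt((n - 3) / max(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 3)
  data.frame(rho = rho, ci_lo = ci[1], ci_hi = ci[2], p = p, n = n,
             method = "partial-spearman")
}

#' Holm (step-down Bonferroni) adjusted p-values
#'
#' @param pvals p-values in \[0, 1\].
#' @return Adjusted p-values (same order), capped at 1.
#' @export
holm_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "holm")
}

#' Benjamini-Hochberg (FDR) adjusted p-values
#'
#' @param pvals p-values in \[0, 1\].
#' @return Adjusted p-values (same order), capped at 1.
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "BH")
}

#' Per-electrode band-power correlation topography with joint FDR
#'
#' Spearman-correlates each electrode's mean band power with a behavioral
#' score, for every band x condition combination, and adjusts the whole
#' band x condition x electrode family jointly by Benjamini-Hochberg at
#' `alpha`.
#'
#' @param band_powers Named list: condition -> (bands x electrodes matrix of
#'   mean power per participant is not expected here; instead supply
#'   condition -> named list band -> participants x electrodes matrix).
#' @param scores Behavioral score vector (one per participant).
#' @param alpha FDR level.
#' @return Long data frame: `band`, `condition`, `electrode`, `rho`, `p`,
#'   `p_fdr`, `significant`.
#' @export
correlation_topography <- function(band_powers, scores, alpha = 0.05) {
  rows <- list()
  for (cond in names(band_powers)) {
    for (bd in names(band_powers[[cond]])) {
      mat <- band_powers[[cond]][[bd]]
      stopifnot(nrow(mat) == length(scores))
      eln <- colnames(mat)
      if (is.null(eln)) eln <- sprintf("E%02d", seq_len(ncol(mat)))
      for (e in seq_len(ncol(mat))) {
        ct <- spearman_ci(mat[, e], scores)
        rows[[length(rows) + 1]] <-
          data.frame(band = bd, condition = cond, electrode = eln[e],
                     rho = ct$rho, p = ct$p)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  out$significant <- out$p_fdr < alpha
  out
}

#' Two-sided variance-ratio F test from summary statistics
#'
#' F is the larger variance over the smaller, with the matching degrees of
#' freedom order; two-sided p from the F distribution.
#'
#' @param var1,var2 Sample variances (> 0).
#' @param n1,n2 Sample sizes (> 1).
#' @return Data frame: `F`, `df1`, `df2`, `p`.
#' @export
variance_ratio_test <- function(var1, n1, var2, n2) {
  stopifnot(var1 > 0, var2 > 0, n1 > 1, n2 > 1)
  if (var1 >= var2) {
    F <- var1 / var2; df1 <- n1 - 1; df2 <- n2 - 1
  } else {
    F <- var2 / var1; df1 <- n2 - 1; df2 <- n1 - 1
  }
  p <- 2 * min(pf(F, df1, df2, lower.tail = FALSE), 0.5)
  data.frame(F = F, df1 = df1, df2 = df2, p = p)
}

#' Paired t test with Cohen's d (average-SD variant) and CI
#'
#' Paired t on the differences; the effect size is `d_av = mean(post - pre)
#' / ((sd(pre) + sd(post)) / 2)` (variant selectable), with a normal-
#' approximation CI using
#' `SE(d) = sqrt(2 (1 - r) / n + d^2 / (2 (n - 1)))` where r is the pre-post
#' correlation.
#'
#' @param pre,post Paired vectors, n >= 3.
#' @param variant `"d_av"` (default) or `"d_z"` (mean diff / SD of diffs).
#' @param conf Confidence level.
#' @return Data frame: `t`, `df`, `p`, `d`, `d_lo`, `d_hi`, `n`.
#' @export
paired_t_and_d <- function(pre, post, variant = c("d_av", "d_z"),
                           conf = 0.95) {
  variant <- match.arg(variant)
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  stopifnot(n >= 3)
  d_i <- post - pre
  if (sd(d_i) == 0) stop("zero difference variance")
  tt <- t.test(post, pre, paired = TRUE)
  d <- if (variant == "d_av") mean(d_i) / ((sd(pre) + sd(post)) / 2)
       else mean(d_i) / sd(d_i)
  r <- cor(pre, post)
  se_d <- sqrt(2 * (1 - r) / n + d^2 / (2 * (n - 1)))
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = d, d_lo = d - zc * se_d,
             d_hi = d + zc * se_d, n = n)
}
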