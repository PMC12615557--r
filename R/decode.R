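# Per-frequency-bin multivariate decoding: linear epsilon-SVR with repeated
# stratified 10-fold cross-validation, Fisher-Z aggregation, permutation
# inference, cluster correction, the meaningfulness rule, and the Fisher-z
# group-difference test.

#' Linear epsilon-insensitive SVR
#'
#' Solves `min_w 0.5 ||w||^2 + C sum_i max(0, |w.x_i + b - y_i| - eps)` by
#' dual coordinate descent (deterministic sequential sweeps; the intercept
#' is carried as an augmented constant feature). This is the same primal
#' objective as a linear-kernel LIBSVM epsilon-SVR with `cost = C`.
#'
#' @param X n x p numeric matrix (standardize beforehand).
#' @param y Numeric response.
#' @param cost Box constraint C.
#' @param epsilon Insensitivity half-width.
#' @param tol Stopping tolerance on the maximum dual-gradient violation.
#' @param max_sweeps Cap on coordinate-descent sweeps.
#' @return List with `w` (length p) and `b` (intercept).
#' @export
svr_fit <- function(X, y, cost = 1, epsilon = 0.1, tol = 1e-3,
                    max_sweeps = 200) {
  stopifnot(nrow(X) == length(y))
  v <- svr_linear_cd(X, y, cost, epsilon, tol, max_sweeps)
  list(w = v[-length(v)], b = v[length(v)])
}

#' @rdname svr_fit
#' @param fit An `svr_fit()` result.
#' @param newdata Matrix of rows to predict.
#' @export
svr_predict <- function(fit, newdata) {
  drop(newdata %*% fit$w + fit$b)
}

# fold assignment; stratified = balanced across 5 y-quantile strata
assign_folds <- function(y, folds, stratified = TRUE) {
  n <- length(y)
  id <- integer(n)
  if (!stratified) return(sample(rep(seq_len(folds), length.out = n)))
  strata <- cut(rank(y, ties.method = "random"), breaks = 5, labels = FALSE)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  id
}

# standardize train columns, apply to test; zero-variance columns -> 0
standardize_pair <- function(tr, te) {
  mu <- colMeans(tr)
  sdv <- apply(tr, 2, sd)
  zero <- sdv == 0
  sdv[zero] <- 1
  trs <- sweep(sweep(tr, 2, mu), 2, sdv, `/`)
  tes <- sweep(sweep(te, 2, mu), 2, sdv, `/`)
  trs[, zero] <- 0
  tes[, zero] <- 0
  list(train = trs, test = tes)
}

#' Decode a score from one feature matrix by repeated cross-validated SVR
#'
#' For each repetition the fold assignment is re-randomized (seeded);
#' within each fold, features (and the scores) are standardized by
#' training-fold mean/SD, a linear epsilon-SVR (C = 1, eps = 0.1, in score-SD
#' units) is fit on the training folds, and held-out participants are
#' predicted on the raw score scale. Decoding performance per repetition
#' is the Pearson correlation between the pooled out-of-fold predictions and
#' the true scores; the per-repetition values are Fisher-Z transformed,
#' averaged, and transformed back.
#'
#' @param X Participants x features matrix (e.g. channels at one frequency
#'   bin).
#' @param y Scores; must vary, and `length(y) >= 3 * folds`.
#' @param folds,repetitions CV layout (default tenfold x 10).
#' @param seed Integer seed.
#' @param cost,epsilon SVR hyperparameters.
#' @param stratified Stratify fold assignment by y quintile.
#' @param metric `"pooled"` (one r over pooled out-of-fold predictions per
#'   repetition) or `"per_fold"` (Fisher-Z average of per-fold r).
#' @return Observed decoding performance r (not clipped; may be negative).
#' @export
decode_bin <- function(X, y, folds = 10, repetitions = 10, seed = 1,
                       cost = 1, epsilon = 0.1, stratified = TRUE,
                       metric = c("pooled", "per_fold")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, n >= 3 * folds)
  if (var(y) == 0) stop("constant scores cannot be decoded")
  if (metric == "pooled") {
    return(decode_spectrum(array(X, dim = c(n, ncol(X), 1)), y,
                           folds = folds, repetitions = repetitions,
                           seed = seed, cost = cost, epsilon = epsilon,
                           stratified = stratified))
  }
  zs <- numeric(repetitions)
  for (rep_i in seq_len(repetitions)) {
    fold_id <- with_seed(seed_for(seed, "fold", rep_i),
                         assign_folds(y, folds, stratified))
    pred <- numeric(n)
    fold_z <- numeric(folds)
    for (k in seq_len(folds)) {
      te <- which(fold_id == k)
      tr <- which(fold_id != k)
      sp <- standardize_pair(X[tr, , drop = FALSE], X[te, , drop = FALSE])
      # scores are trained in training-fold SD units (so epsilon is
      # scale-free) and predictions mapped back to the raw scale
      mu_y <- mean(y[tr]); sd_y <- sd(y[tr])
      fit <- svr_fit(sp$train, (y[tr] - mu_y) / sd_y, cost, epsilon)
      pred[te] <- svr_predict(fit, sp$test) * sd_y + mu_y
      if (metric == "per_fold")
        fold_z[k] <- fisher_z(safe_cor(pred[te], y[te]))
    }
    zs[rep_i] <- if (metric == "pooled") fisher_z(safe_cor(pred, y))
                 else mean(fold_z)
  }
  fisher_z_inv(mean(zs))
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Decode a score independently within every frequency bin
#'
#' Applies [decode_bin()] to each slice of the feature tensor along its
#' third axis (30 one-Hz bins for spectral features; 2 slices -- offset and
#' exponent -- for aperiodic-parameter features).
#'
#' @param features Participants x channels x bins array.
#' @param y Scores.
#' @param folds,repetitions,seed,cost,epsilon,stratified As [decode_bin()].
#' @return Numeric vector of observed r, one per bin.
#' @export
decode_spectrum <- function(features, y, folds = 10, repetitions = 10,
                            seed = 1, cost = 1, epsilon = 0.1,
                            stratified = TRUE) {
  stopifnot(length(dim(features)) == 3, dim(features)[1] == length(y),
            all(is.finite(features)))
  n <- length(y)
  stopifnot(n >= 3 * folds)
  if (var(y) == 0) stop("constant scores cannot be decoded")
  fold_ids <- vapply(seq_len(repetitions), function(rep_i)
    with_seed(seed_for(seed, "fold", rep_i),
              assign_folds(y, folds, stratified)),
    integer(n))
  r_mat <- cv_decode_batch(features, y, fold_ids, folds, cost, epsilon)
  fisher_z_inv(colMeans(fisher_z(r_mat)))
}

#' Permutation null distribution and p-values for per-bin decoding
#'
#' Scores are randomly reassigned to participants `B` times; the full
#' decoding analysis is re-run on each permuted cohort (with
#' `perm_repetitions` CV repetitions, by default fewer than the observed
#' analysis to bound compute). One-sided upper-tail p-values use the
#' add-one rule `p = (1 + #{null >= r_obs}) / (1 + B)`, so p is never zero.
#'
#' @param features Participants x channels x bins array.
#' @param y Scores.
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param observed Optional precomputed per-bin observed r; computed with
#'   `repetitions` CV repetitions when missing.
#' @param repetitions CV repetitions for the observed analysis.
#' @param perm_repetitions CV repetitions inside each permutation.
#' @param folds,cost,epsilon,stratified As [decode_bin()].
#' @return List with `observed`, `null` (B x bins matrix), `p` (per bin).
#' @export
permutation_null <- function(features, y, B = 1000, seed = 1,
                             observed = NULL, repetitions = 10,
                             perm_repetitions = 2, folds = 10, cost = 1,
                             epsilon = 0.1, stratified = TRUE) {
  stopifnot(B >= 100)
  if (is.null(observed))
    observed <- decode_spectrum(features, y, folds = folds,
                                repetitions = repetitions, seed = seed,
                                cost = cost, epsilon = epsilon,
                                stratified = stratified)
  nb <- dim(features)[3]
  n <- length(y)
  yperm <- matrix(NA_real_, n, B)
  fold_ids <- matrix(NA_integer_, n, perm_repetitions * B)
  for (b in seq_len(B)) {
    yp <- with_seed(seed_for(seed, "perm", b), y[sample(n)])
    yperm[, b] <- yp
    ps <- seed_for(seed, "permseed", b)
    for (r in seq_len(perm_repetitions))
      fold_ids[, (b - 1) * perm_repetitions + r] <-
        with_seed(seed_for(ps, "fold", r), assign_folds(yp, folds, stratified))
  }
  null <- cv_perm_null_batch(features, yperm, fold_ids, perm_repetitions,
                             folds, cost, epsilon)
  p <- (1 + colSums(null >= matrix(observed, B, nb, byrow = TRUE))) / (1 + B)
  list(observed = observed, null = null, p = p)
}

#' Clusters of adjacent significant frequency bins
#'
#' Maximal runs of adjacent bins with `p < alpha`; runs shorter than
#' `min_size` are discarded.
#'
#' @param pvals Per-bin p-values, ordered by bin.
#' @param alpha Cluster-forming threshold (default .01).
#' @param min_size Minimum run length (default 2).
#' @return Data frame with columns `start`, `end`, `size` (bin indices);
#'   zero rows when nothing survives.
#' @export
cluster_correction <- function(pvals, alpha = 0.01, min_size = 2) {
  sig <- pvals < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_size
  data.frame(start = starts[keep], end = ends[keep], size = r$lengths[keep])
}

#' Meaningful-effect mask across conditions
#'
#' A bin is flagged iff observed decoding r reaches `threshold` in every
#' condition (default r = .20; the sensitivity variant r = .13 is available
#' via `threshold`).
#'
#' @param r_by_condition Conditions x bins matrix of observed r (all
#'   conditions on the same bin grid).
#' @param threshold Meaningfulness threshold.
#' @return Logical vector, one flag per bin.
#' @export
meaningful_effects <- function(r_by_condition, threshold = 0.20) {
  r_by_condition <- as.matrix(r_by_condition)
  if (any(!is.finite(r_by_condition)))
    stop("missing condition values in the decoding matrix")
  apply(r_by_condition >= threshold, 2, all)
}

#' Fisher-z group comparison of cluster decoding performance
#'
#' For each cluster, `z = (Z(rA) - Z(rB)) / sqrt(1/(nA-3) + 1/(nB-3))` with
#' Z the Fisher transform; two-sided p, Holm-adjusted across clusters.
#'
#' @param rA,rB Mean cluster decoding r per group (|r| < 1).
#' @param nA,nB Group sizes (> 3).
#' @return Data frame with `z`, `p`, `p_holm`, one row per cluster.
#' @export
compare_groups <- function(rA, nA, rB, nB) {
  stopifnot(all(abs(c(rA, rB)) < 1), all(c(nA, nB) > 3),
            length(rA) == length(rB))
  z <- (atanh(rA) - atanh(rB)) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  p <- 2 * pnorm(-abs(z))
  data.frame(z = z, p = p, p_holm = holm_adjust(p))
}
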