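# End-to-end orchestration: simulate -> (parameterize) -> decode ->
# permutation inference -> clusters -> meaningfulness -> statistics, over
# the full analysis matrix (signal types x conditions x scores x
# subsamples), with per-cell derived seeds and a reproducible manifest.

#' Pipeline run configuration
#'
#' @param cohort A [cohort_config()] (its seed is overridden by a seed
#'   derived from `seed` so one master seed drives the whole run).
#' @param signals Subset of `c("total", "periodic", "aperiodic")`.
#' @param scores Behavioral columns to decode.
#' @param conditions Conditions to analyse (default: all in the cohort).
#' @param subsamples Subset of `c("full", "male", "female")`.
#' @param folds,repetitions CV layout for the observed decoding.
#' @param perm_repetitions CV repetitions inside permutations.
#' @param B Permutations per cell.
#' @param cluster_alpha,cluster_min_size Cluster correction settings.
#' @param meaningful_threshold Meaningfulness threshold on r.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            signals = c("total", "periodic"),
                            scores = "fluid", conditions = NULL,
                            subsamples = "full", folds = 10,
                            repetitions = 10, perm_repetitions = 2,
                            B = 200, cluster_alpha = 0.01,
                            cluster_min_size = 2,
                            meaningful_threshold = 0.20, seed = 1) {
  stopifnot(all(signals %in% c("total", "periodic", "aperiodic")),
            all(subsamples %in% c("full", "male", "female")), B >= 100)
  if (is.null(conditions)) conditions <- cohort$conditions
  stopifnot(all(conditions %in% cohort$conditions))
  structure(list(cohort = cohort, signals = signals, scores = scores,
                 conditions = conditions, subsamples = subsamples,
                 folds = folds, repetitions = repetitions,
                 perm_repetitions = perm_repetitions, B = B,
                 cluster_alpha = cluster_alpha,
                 cluster_min_size = cluster_min_size,
                 meaningful_threshold = meaningful_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

subsample_idx <- function(behav, sub) {
  switch(sub,
         full = seq_len(nrow(behav)),
         male = which(behav$gender == "male"),
         female = which(behav$gender == "female"))
}

# mean linear band power over channels, per participant/condition/band
cohort_band_table <- function(cohort, bands = list(delta = c(0.5, 4),
                                                   theta = c(4, 8),
                                                   alpha = c(8.5, 13),
                                                   beta = c(13.5, 30))) {
  out <- list()
  for (cond in names(cohort$spectra)) {
    arr <- 10^cohort$spectra[[cond]]
    for (bd in names(bands)) {
      idx <- which(cohort$freqs >= bands[[bd]][1] &
                   cohort$freqs <= bands[[bd]][2])
      out[[cond]][[bd]] <- apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
    }
  }
  out
}

#' Run the full analysis matrix on a synthetic cohort
#'
#' Validates the configuration, simulates the cohort, parameterizes spectra
#' when periodic/aperiodic signals are requested, then runs every cell of
#' the matrix: per-bin decoding, permutation p-values, cluster correction.
#' Across conditions it derives the meaningful-bin mask per signal x score x
#' subsample, and (when both male and female subsamples are analysed)
#' Fisher-z group comparisons over detected clusters. A univariate
#' statistics table and a manifest with per-file MD5 checksums are written
#' alongside.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; files are overwritten).
#' @return Invisibly, the manifest list; side effect: `cells/*.json`,
#'   `summary.json`, `stats.tsv`, `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(out_dir, "cells"), recursive = TRUE,
             showWarnings = FALSE)
  cc <- config$cohort
  cc$seed <- seed_for(config$seed, "cohort")
  cohort <- simulate_cohort(cc)
  for (sc in config$scores)
    if (is.null(cohort$behavioral[[sc]]))
      stop("config names a score missing from the behavioral table: ", sc)

  fits <- NULL
  if (any(config$signals %in% c("periodic", "aperiodic")))
    fits <- lapply(setNames(config$conditions, config$conditions),
                   function(cond) parameterize_cohort(cohort, cond))

  cell_features <- function(signal, cond) {
    switch(signal,
           total = total_features(cohort, cond),
           periodic = fits[[cond]]$periodic,
           aperiodic = fits[[cond]]$aperiodic)
  }

  cells <- expand.grid(signal = config$signals, condition = config$conditions,
                       score = config$scores, subsample = config$subsamples,
                       stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  any_failed <- FALSE
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    cell_id <- paste(cl$signal, cl$condition, cl$score, cl$subsample,
                     sep = "_")
    res <- tryCatch({
      idx <- subsample_idx(cohort$behavioral, cl$subsample)
      y <- cohort$behavioral[[cl$score]][idx]
      feats <- cell_features(cl$signal, cl$condition)[idx, , , drop = FALSE]
      pn <- permutation_null(feats, y, B = config$B,
                             seed = seed_for(config$seed, "cell", cell_id),
                             repetitions = config$repetitions,
                             perm_repetitions = config$perm_repetitions,
                             folds = config$folds)
      cls <- cluster_correction(pn$p, config$cluster_alpha,
                                config$cluster_min_size)
      list(id = cell_id, signal = cl$signal, condition = cl$condition,
           score = cl$score, subsample = cl$subsample, n = length(idx),
           observed_r = pn$observed, p = pn$p,
           null_mean = colMeans(pn$null), null_q95 = apply(pn$null, 2,
             quantile, 0.95, names = FALSE),
           clusters = cls, status = "ok")
    }, error = function(e) {
      list(id = cell_id, status = "failed", error = conditionMessage(e))
    })
    if (!identical(res$status, "ok")) any_failed <- TRUE
    results[[i]] <- res
    jsonlite::write_json(res, file.path(out_dir, "cells",
                                        paste0(cell_id, ".json")),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "columns")
  }

  # meaningful-bin masks across conditions, per signal x score x subsample
  masks <- list()
  combos <- unique(cells[, c("signal", "score", "subsample")])
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    sel <- Filter(function(r) identical(r$status, "ok") &&
                    r$signal == cb$signal && r$score == cb$score &&
                    r$subsample == cb$subsample, results)
    if (length(sel) < length(config$conditions)) next
    rmat <- do.call(rbind, lapply(sel, `[[`, "observed_r"))
    key <- paste(cb$signal, cb$score, cb$subsample, sep = "_")
    masks[[key]] <- list(
      mask = unname(meaningful_effects(rmat, config$meaningful_threshold)),
      max_r = max(rmat), conditions = vapply(sel, `[[`, "", "condition"))
  }

  # gender comparison on clusters found in either gender subsample
  gender_tests <- NULL
  if (all(c("male", "female") %in% config$subsamples)) {
    rows <- list()
    for (sg in config$signals) for (sc in config$scores)
      for (cond in config$conditions) {
        rm_ <- Filter(function(r) identical(r$status, "ok") &&
                        r$signal == sg && r$score == sc &&
                        r$condition == cond, results)
        rmale <- Filter(function(r) r$subsample == "male", rm_)
        rfem <- Filter(function(r) r$subsample == "female", rm_)
        if (length(rmale) != 1 || length(rfem) != 1) next
        cl2 <- unique(rbind(rmale[[1]]$clusters, rfem[[1]]$clusters))
        if (nrow(cl2) == 0) next
        for (j in seq_len(nrow(cl2))) {
          bins <- cl2$start[j]:cl2$end[j]
          rows[[length(rows) + 1]] <- data.frame(
            signal = sg, score = sc, condition = cond,
            start = cl2$start[j], end = cl2$end[j],
            r_male = tanh(mean(atanh(rmale[[1]]$observed_r[bins]))),
            r_female = tanh(mean(atanh(rfem[[1]]$observed_r[bins]))),
            n_male = rmale[[1]]$n, n_female = rfem[[1]]$n)
        }
      }
    if (length(rows) > 0) {
      gender_tests <- do.call(rbind, rows)
      zt <- compare_groups(gender_tests$r_male, gender_tests$n_male,
                           gender_tests$r_female, gender_tests$n_female)
      gender_tests <- cbind(gender_tests, zt)
    }
  }

  stats_tab <- pipeline_stats(cohort)
  write.table(stats_tab, file.path(out_dir, "stats.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  summary <- list(n_cells = nrow(cells),
                  n_failed = sum(!vapply(results, function(r)
                    identical(r$status, "ok"), TRUE)),
                  meaningful = masks, gender_tests = gender_tests,
                  threshold = config$meaningful_threshold,
                  seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")

  files <- sort(c(file.path("cells", list.files(file.path(out_dir, "cells"))),
                  "summary.json", "stats.tsv"))
  manifest <- list(schema = "specdecode-run/1", seed = config$seed,
                   n_cells = nrow(cells), any_failed = any_failed,
                   files = setNames(
                     as.list(unname(tools::md5sum(file.path(out_dir, files)))),
                     files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# univariate battery on the cohort's behavioral table + band powers
pipeline_stats <- function(cohort) {
  behav <- cohort$behavioral
  rows <- list()
  add <- function(label, ct, family) {
    rows[[length(rows) + 1]] <<- cbind(test = label, family = family, ct)
  }
  for (sc in c("fluid", "crystallized"))
    for (sl in c("sleep_pre", "sleep_post"))
      add(paste(sc, "x", sl), spearman_ci(behav[[sc]], behav[[sl]]),
          "intelligence_sleepiness")

  bt <- cohort_band_table(cohort)
  conds <- names(bt)
  pre <- conds[grepl("pre", conds)]; if (length(pre) == 0) pre <- conds
  post <- conds[grepl("post", conds)]; if (length(post) == 0) post <- conds
  mean_band <- function(cs, bd)
    rowMeans(vapply(cs, function(cn) rowMeans(bt[[cn]][[bd]]),
                    numeric(nrow(behav))))
  add("fluid x theta", spearman_ci(behav$fluid, mean_band(conds, "theta")),
      "six_tests")
  add("fluid x alpha", spearman_ci(behav$fluid, mean_band(conds, "alpha")),
      "six_tests")
  add("sleep_pre x theta_pre",
      spearman_ci(behav$sleep_pre, mean_band(pre, "theta")), "six_tests")
  add("sleep_pre x alpha_pre",
      spearman_ci(behav$sleep_pre, mean_band(pre, "alpha")), "six_tests")
  add("sleep_post x theta_post",
      spearman_ci(behav$sleep_post, mean_band(post, "theta")), "six_tests")
  add("sleep_post x alpha_post",
      spearman_ci(behav$sleep_post, mean_band(post, "alpha")), "six_tests")
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_adj[sel] <- holm_adjust(out$p[sel])
  }
  out
}

#' Summarize a completed pipeline run from its stored files
#'
#' Re-derives the report purely from the JSON written by [run_pipeline()]
#' (no recomputation): per cell the peak per-bin r and its bin plus the
#' cluster list, the meaningful-bin masks, and the gender comparison table.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List with `cells` (data frame), `meaningful`, `gender_tests`.
#' @export
pipeline_report <- function(run_dir) {
  cell_files <- list.files(file.path(run_dir, "cells"), full.names = TRUE)
  if (length(cell_files) == 0) stop("no cells found under ", run_dir)
  rows <- list()
  for (f in sort(cell_files)) {
    cj <- jsonlite::read_json(f, simplifyVector = TRUE)
    if (!identical(cj$status, "ok")) {
      warning("cell failed: ", cj$id)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      id = cj$id, signal = cj$signal, condition = cj$condition,
      score = cj$score, subsample = cj$subsample, n = cj$n,
      max_r = max(cj$observed_r), max_r_bin = which.max(cj$observed_r),
      n_clusters = if (is.null(cj$clusters$start)) 0L
                   else length(cj$clusters$start),
      clusters = if (is.null(cj$clusters$start)) ""
                 else paste(sprintf("%d-%d", cj$clusters$start,
                                    cj$clusters$end), collapse = ","))
  }
  summ <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                              simplifyVector = TRUE)
  list(cells = do.call(rbind, rows), meaningful = summ$meaningful,
       gender_tests = summ$gender_tests)
}
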