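# Synthetic EEG cohorts with known spectral ground truth.
#
# Spectra follow the standard 1/f-plus-peaks model in log10 power:
#   log10 P(f) = offset - exponent * log10(f)
#                + sum_k height_k * exp(-(f - center_k)^2 / (2 * width_k^2))
#                + N(0, noise_sd^2)
# Recordings are produced by spectral shaping of white noise, so oscillatory
# peaks appear as narrowband-filtered Gaussian noise rather than pure
# sinusoids (non-phase-locked, like real resting EEG).

#' Spectrum model (aperiodic background plus Gaussian peaks)
#'
#' @param offset Aperiodic log10-power intercept (log10 uV^2/Hz).
#' @param exponent Aperiodic slope (unitless, >= 0 expected).
#' @param peaks `NULL` or data frame with columns `center` (Hz, in (0.5, 30)),
#'   `height` (log10 power above the background, >= 0) and `width`
#'   (Gaussian SD, Hz).
#' @param noise_sd SD of additive log10-power noise.
#' @return Object of class `spectrum_model`.
#' @export
spectrum_model <- function(offset, exponent, peaks = NULL, noise_sd = 0) {
  if (is.null(peaks)) {
    peaks <- data.frame(center = numeric(0), height = numeric(0),
                        width = numeric(0))
  }
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "height", "width") %in% names(peaks)),
            all(peaks$center > 0.5), all(peaks$center < 30),
            all(peaks$height >= 0), all(peaks$width > 0),
            noise_sd >= 0)
  structure(list(offset = offset, exponent = exponent, peaks = peaks,
                 noise_sd = noise_sd),
            class = "spectrum_model")
}

# noiseless model evaluation, log10 power
eval_spectrum_model <- function(model, freqs) {
  lp <- model$offset - model$exponent * log10(freqs)
  for (k in seq_len(nrow(model$peaks))) {
    pk <- model$peaks[k, ]
    lp <- lp + pk$height * exp(-(freqs - pk$center)^2 / (2 * pk$width^2))
  }
  lp
}

#' Simulate a log10 power spectrum from a spectrum model
#'
#' @param model A [spectrum_model()].
#' @param freqs Strictly increasing positive frequency grid (Hz), within
#'   (0, 30].
#' @param seed Optional integer seed for the additive log-power noise.
#' @return Numeric vector of log10 power, one value per frequency.
#' @export
simulate_spectrum <- function(model, freqs = freq_grid(), seed = NULL) {
  if (any(freqs <= 0)) stop("frequencies must be positive")
  if (any(diff(freqs) <= 0)) stop("frequency grid must be strictly increasing")
  if (any(freqs > 30)) stop("frequency grid must lie within (0, 30]")
  lp <- eval_spectrum_model(model, freqs)
  if (model$noise_sd > 0) {
    eps <- if (is.null(seed)) rnorm(length(freqs), 0, model$noise_sd)
           else with_seed(seed, rnorm(length(freqs), 0, model$noise_sd))
    lp <- lp + eps
  }
  lp
}

#' Simulate a single-channel voltage trace matching a spectrum model
#'
#' White Gaussian noise is shaped in the frequency domain so that its
#' one-sided power spectral density follows the (noiseless) model between
#' 0.5 and 30 Hz and is zero outside. Gaussian spectral peaks therefore
#' become narrowband Gaussian noise components.
#'
#' @param model A [spectrum_model()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param seconds Duration in s (>= 4).
#' @param seed Integer seed.
#' @param scale Overall amplitude multiplier (0 gives an all-zero trace).
#' @return Numeric vector of length `fs * seconds`, in uV.
#' @export
simulate_recording <- function(model, fs = 500, seconds = 60, seed = 1,
                               scale = 1) {
  stopifnot(fs >= 100, seconds >= 4)
  n <- round(fs * seconds)
  if (scale == 0) return(numeric(n))
  f <- (0:(n %/% 2)) * fs / n
  amp <- numeric(length(f))
  # shape slightly beyond the analysis band so Welch estimates at the band
  # edges (0.5 and 30 Hz) are not attenuated by spectral leakage
  in_band <- f >= 0.25 & f <= 32
  # |H|^2 = target one-sided density / one-sided density of unit white noise
  amp[in_band] <- sqrt(10^eval_spectrum_model(model, f[in_band]) * fs / 2)
  u <- with_seed(seed, rnorm(n))
  U <- fft(u)
  H <- numeric(n)
  H[seq_along(f)] <- amp
  if (n %% 2 == 0) {
    H[n:(n %/% 2 + 2)] <- amp[2:(n %/% 2)]
    H[n %/% 2 + 1] <- 0       # drop Nyquist
  } else {
    H[n:(n %/% 2 + 2)] <- amp[2:(n %/% 2 + 1)]
  }
  H[1] <- 0                   # drop DC
  scale * Re(fft(U * H, inverse = TRUE)) / n
}

#' Multichannel EEG recording container
#'
#' @param data Channels x samples matrix, uV.
#' @param fs Sampling rate, Hz.
#' @param labels Unique channel labels.
#' @param condition Condition tag (e.g. `"pre_open"`).
#' @param block_onsets Sample indices (1-based) of resting-block onsets.
#' @return Object of class `eeg_recording`.
#' @export
recording <- function(data, fs, labels = NULL, condition = NA_character_,
                      block_onsets = 1L) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  stopifnot(fs > 0, all(is.finite(data)), !anyDuplicated(labels),
            length(labels) == nrow(data), all(block_onsets >= 1),
            all(block_onsets <= ncol(data)))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, condition = condition,
                 block_onsets = as.integer(block_onsets)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s), %d block(s)\n",
              nrow(x$data), ncol(x$data), x$fs,
              ifelse(is.na(x$condition), "no condition", x$condition),
              length(x$block_onsets)))
  invisible(x)
}

#' Inject artifacts that violate named rejection criteria
#'
#' Each planned event is built to trip exactly the epoch-rejection criterion
#' it names (criteria of [reject_epochs()]): 1 = per-ms voltage gradient
#' above 50 uV/ms (a one-sample 150-uV spike), 2 = more than 200 uV
#' peak-to-peak within 200 ms (a smooth 250-uV half-sine over 300 ms whose
#' gradient stays far below criterion 1), 3 = less than 0.5 uV peak-to-peak
#' over 100 ms (a 120-ms flatline). Events are centered 1 s into the named
#' epoch on the epoch grid implied by `delay_s` (2-s epochs starting every
#' 1 s after the per-block delay).
#'
#' @param rec An [recording()].
#' @param plan Data frame with columns `epoch` (1-based epoch index within
#'   the first block), `channel` (label or index) and `criterion` (1, 2 or 3).
#'   An empty plan returns the recording unchanged.
#' @param delay_s Epoching delay after block onset, s.
#' @return List with elements `recording` (modified) and `ledger` (the plan
#'   augmented with the sample index of each event).
#' @export
inject_artifacts <- function(rec, plan, delay_s = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  plan <- as.data.frame(plan)
  if (nrow(plan) == 0) {
    return(list(recording = rec,
                ledger = data.frame(epoch = integer(0), channel = character(0),
                                    criterion = integer(0), sample = integer(0))))
  }
  stopifnot(all(c("epoch", "channel", "criterion") %in% names(plan)),
            all(plan$criterion %in% 1:3))
  fs <- rec$fs
  x <- rec$data
  ch_idx <- if (is.numeric(plan$channel)) as.integer(plan$channel)
            else match(as.character(plan$channel), rec$labels)
  if (anyNA(ch_idx) || any(ch_idx < 1) || any(ch_idx > nrow(x)))
    stop("artifact plan references a nonexistent channel")
  onset <- rec$block_onsets[1]
  sample0 <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    ep <- plan$epoch[i]
    start <- onset + round(delay_s * fs) + (ep - 1) * fs        # epoch start
    s0 <- start + fs                                            # 1 s in
    if (start + 2 * fs - 1 > ncol(x))
      stop("artifact epoch lies beyond the recording duration")
    ch <- ch_idx[i]
    if (plan$criterion[i] == 1) {
      x[ch, s0] <- x[ch, s0] + 150
    } else if (plan$criterion[i] == 2) {
      L <- round(0.3 * fs)
      idx <- s0 - L %/% 2 + seq_len(L) - 1
      x[ch, idx] <- x[ch, idx] + 250 * sin(pi * (seq_len(L) - 1) / (L - 1))
    } else {
      L <- round(0.12 * fs)
      idx <- s0 + seq_len(L) - 1
      x[ch, idx] <- x[ch, idx[1]]
    }
    sample0[i] <- s0
  }
  rec$data <- x
  list(recording = rec,
       ledger = cbind(plan, sample = sample0))
}

#' Plant a score-power association into a stack of spectra
#'
#' Shifts per-participant log10 band power (or the whole-spectrum offset,
#' for aperiodic associations) so that mean log band power over the named
#' channels correlates with `scores` at `target_r` in the population, while
#' preserving the original marginal spread. `target_r = 0` returns the input
#' unchanged.
#'
#' @param spectra Participants x channels x frequencies array of log10 power,
#'   with frequencies on `freqs`.
#' @param scores Numeric score vector, one per participant.
#' @param band Length-2 Hz range (inclusive at the raw grid).
#' @param channels Channel indices carrying the association (non-empty).
#' @param target_r Target population correlation, |r| < 1.
#' @param freqs Frequency grid of the third array dimension.
#' @param parameter `"band"` shifts log power inside `band` only;
#'   `"offset"` shifts the whole spectrum (an aperiodic-offset association).
#' @return Modified spectra array.
#' @export
plant_association <- function(spectra, scores, band = c(8.5, 13),
                              channels = seq_len(dim(spectra)[2]),
                              target_r = 0.3, freqs = freq_grid(),
                              parameter = c("band", "offset")) {
  parameter <- match.arg(parameter)
  stopifnot(length(dim(spectra)) == 3, dim(spectra)[1] == length(scores),
            abs(target_r) < 1, band[1] >= 0.5, band[2] <= 30,
            dim(spectra)[3] == length(freqs))
  if (length(channels) == 0) stop("empty channel set")
  if (target_r == 0) return(spectra)
  idx <- which(freqs >= band[1] & freqs <= band[2])
  b <- apply(spectra[, channels, idx, drop = FALSE], 1, mean)
  zb <- as.numeric(scale(b))
  zs <- as.numeric(scale(scores))
  bnew <- mean(b) + sd(b) * (target_r * zs + sqrt(1 - target_r^2) * zb)
  delta <- bnew - b
  tgt <- if (parameter == "band") idx else seq_along(freqs)
  for (i in seq_along(delta))
    spectra[i, channels, tgt] <- spectra[i, channels, tgt] + delta[i]
  spectra
}

#' Cohort configuration
#'
#' Defaults describe the package's standard simulation scenario: 300
#' participants, 16 channels, 500 Hz, 60-s blocks, two conditions. The
#' full 59-channel, four-condition layout of a multi-site resting-state
#' study is available by configuration.
#'
#' @param n_participants Cohort size.
#' @param n_channels Channel count (>= 1).
#' @param fs Sampling rate, Hz.
#' @param block_seconds Resting-block duration, s.
#' @param conditions Character vector of condition labels.
#' @param associations List of association specs, each a list with elements
#'   `score` (column of the behavioral table), `r` (target correlation,
#'   |r| < 1), and either `band` (Hz range; periodic association) or
#'   `parameter = "offset"` (aperiodic association), plus optional
#'   `channels` (indices; default all).
#' @param noise_sd Log10-power noise SD per spectrum.
#' @param seed Master seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 300, n_channels = 16, fs = 500,
                          block_seconds = 60,
                          conditions = c("pre_open", "pre_closed"),
                          associations = list(), noise_sd = 0.05, seed = 1) {
  stopifnot(n_participants >= 2, n_channels >= 1, fs >= 100,
            block_seconds >= 4, length(conditions) >= 1)
  for (a in associations) stopifnot(abs(a$r) < 1)
  structure(list(n_participants = n_participants, n_channels = n_channels,
                 fs = fs, block_seconds = block_seconds,
                 conditions = conditions, associations = associations,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

# behavioral table with realistic marginals for a young student sample
simulate_behavioral <- function(n, seed) {
  with_seed(seed, {
    fluid <- pmin(pmax(round(rnorm(n, 13, sqrt(7.02))), 0), 20)
    crystallized <- pmin(pmax(round(rnorm(n, 55, 9)), 0), 84)
    tired_pre <- pmin(pmax(round(rnorm(n, 3.0, 1.2)), 1), 7)
    exhaust_pre <- pmin(pmax(round(0.7 * tired_pre + rnorm(n, 1.0, 0.9)), 1), 7)
    tired_post <- pmin(pmax(round(tired_pre + rnorm(n, 0.9, 1.0)), 1), 7)
    exhaust_post <- pmin(pmax(round(0.7 * tired_post + rnorm(n, 1.0, 0.9)), 1), 7)
    gender <- ifelse(rbinom(n, 1, 0.49) == 1, "female", "male")
    age <- sample(18:30, n, replace = TRUE)
    data.frame(participant = sprintf("P%04d", seq_len(n)),
               fluid = fluid, crystallized = crystallized,
               tired_pre = tired_pre, exhaust_pre = exhaust_pre,
               tired_post = tired_post, exhaust_post = exhaust_post,
               gender = gender, age = age)
  })
}

#' Simulate a synthetic EEG cohort (spectrum-level fast path)
#'
#' Draws per-participant, per-channel spectrum models (offset U(0.5, 2),
#' exponent U(0.8, 2), an alpha peak for every participant and a theta peak
#' for a random 30%), simulates noisy log10 spectra for every condition,
#' builds a behavioral table (with sleepiness composites via
#' [build_sleepiness()]), and plants the configured associations. All
#' randomness derives hierarchically from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Object of class `eeg_cohort`: list with `spectra` (named list,
#'   condition -> participants x channels x 60 log10-power array), `freqs`,
#'   `behavioral` (with `sleep_pre` / `sleep_post` composites), `models`
#'   (ground-truth spectrum models) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  nc <- config$n_channels
  freqs <- freq_grid()
  behav <- simulate_behavioral(n, seed_for(config$seed, "behavioral"))
  comp <- build_sleepiness(behav[, c("tired_pre", "exhaust_pre")],
                           behav[, c("tired_post", "exhaust_post")])
  behav$sleep_pre <- comp$pre
  behav$sleep_post <- comp$post

  models <- with_seed(seed_for(config$seed, "models"), {
    lapply(seq_len(n), function(i) {
      offset <- runif(1, 0.5, 2)
      exponent <- runif(1, 0.8, 2)
      ac <- min(max(rnorm(1, 10, 0.8), 8.5), 12)
      ah <- runif(1, 0.3, 0.8)
      aw <- runif(1, 1, 2)
      has_theta <- runif(1) < 0.3
      lapply(seq_len(nc), function(ch) {
        peaks <- data.frame(center = ac + rnorm(1, 0, 0.1),
                            height = pmax(ah + rnorm(1, 0, 0.05), 0.05),
                            width = aw)
        if (has_theta) {
          peaks <- rbind(peaks,
                         data.frame(center = runif(1, 5, 7),
                                    height = runif(1, 0.15, 0.4),
                                    width = runif(1, 1, 2)))
        }
        spectrum_model(offset + rnorm(1, 0, 0.05), exponent + rnorm(1, 0, 0.03),
                       peaks, config$noise_sd)
      })
    })
  })

  spectra <- list()
  for (cond in config$conditions) {
    arr <- array(NA_real_, dim = c(n, nc, length(freqs)))
    closed_boost <- if (grepl("closed", cond)) 0.15 else 0
    for (i in seq_len(n)) {
      for (ch in seq_len(nc)) {
        m <- models[[i]][[ch]]
        lp <- eval_spectrum_model(m, freqs) +
          closed_boost * exp(-(freqs - m$peaks$center[1])^2 /
                               (2 * m$peaks$width[1]^2))
        eps <- with_seed(seed_for(config$seed, "noise", cond, i, ch),
                         rnorm(length(freqs), 0, m$noise_sd))
        arr[i, ch, ] <- lp + eps
      }
    }
    for (a in config$associations) {
      chs <- if (is.null(a$channels)) seq_len(nc) else a$channels
      if (!is.null(a$band)) {
        arr <- plant_association(arr, behav[[a$score]], band = a$band,
                                 channels = chs, target_r = a$r,
                                 freqs = freqs, parameter = "band")
      } else {
        arr <- plant_association(arr, behav[[a$score]],
                                 channels = chs, target_r = a$r,
                                 freqs = freqs, parameter = "offset")
      }
    }
    spectra[[cond]] <- arr
  }

  structure(list(spectra = spectra, freqs = freqs, behavioral = behav,
                 models = models, config = config),
            class = "eeg_cohort")
}

#' Write a cohort to disk as TSV spectra plus JSON sidecar
#'
#' Spectra go to `spectra.tsv` (long format: participant, condition,
#' channel, freq_hz, log10_power), the behavioral table to `behavioral.tsv`,
#' and the configuration plus ground-truth association list to
#' `cohort.json`.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cond in names(cohort$spectra)) {
    arr <- cohort$spectra[[cond]]
    for (ch in seq_len(dim(arr)[2])) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = rep(cohort$behavioral$participant,
                          each = length(cohort$freqs)),
        condition = cond, channel = ch,
        freq_hz = rep(cohort$freqs, dim(arr)[1]),
        log10_power = as.vector(t(arr[, ch, ])))
    }
  }
  write.table(do.call(rbind, rows), file.path(dir, "spectra.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(cohort$behavioral, file.path(dir, "behavioral.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(config = unclass(cohort$config), schema = "specdecode-cohort/1"),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = 10)
  invisible(dir)
}

#' Binned total-power features for decoding
#'
#' Converts a cohort condition's log10 spectra to linear power and averages
#' them into the 30 one-Hz bins.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param condition Condition label.
#' @return Participants x channels x 30 array.
#' @export
total_features <- function(cohort, condition) {
  arr <- cohort$spectra[[condition]]
  if (is.null(arr)) stop("unknown condition: ", condition)
  n <- dim(arr)[1]; nc <- dim(arr)[2]
  out <- array(NA_real_, dim = c(n, nc, dim(arr)[3] / 2))
  for (i in seq_len(n)) out[i, , ] <- bin_spectrum(10^arr[i, , ])
  out
}
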