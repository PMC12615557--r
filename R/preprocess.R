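# Preprocessing chain: FIR band-pass, bad-channel screen, epoching, the
# three artifact-rejection criteria, Hamming-tapered FFT, 1-Hz binning.

# FIR band-pass coefficients; transition half-width ~0.4 Hz so that the
# passband is intact from 1 Hz and 0.1 / 40 Hz are deep in the stopband.
fir_bandpass_coef <- function(fs, low = 0.5, high = 30) {
  ntaps <- 2 * ceiling(4.125 * fs / 2) + 1        # odd, ~4.125 s of taps
  signal::fir1(ntaps - 1, c(low, high) / (fs / 2), type = "pass")
}

# zero-phase application of a linear-phase FIR (forward-backward, FFT-based)
zero_phase_fir <- function(x, b) {
  nb <- length(b)
  n <- length(x)
  xp <- c(rep(x[1], nb), x, rep(x[n], nb))
  y <- signal::fftfilt(b, xp)
  y <- rev(signal::fftfilt(b, rev(y)))
  y[(nb + 1):(nb + n)]
}

#' Band-pass filter a recording (0.5-30 Hz FIR, zero phase)
#'
#' Linear-phase Hamming-window FIR, applied forward and backward so the net
#' filter has zero phase. Passband ripple is below 1 dB within 1-29 Hz and
#' attenuation exceeds 20 dB at 0.1 and 40 Hz.
#'
#' @param rec An [recording()].
#' @param low,high Band edges, Hz; `low < high < fs/2`.
#' @return Filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 30) {
  stopifnot(inherits(rec, "eeg_recording"), low < high, high < rec$fs / 2)
  b <- fir_bandpass_coef(rec$fs, low, high)
  if (ncol(rec$data) < 3 * length(b))
    stop("recording shorter than 3x the filter length")
  rec$data <- t(apply(rec$data, 1, zero_phase_fir, b = b))
  rec
}

#' Screen channels with deviant variance, amplitude or mean offset
#'
#' A channel is flagged bad iff |z| > `z_thresh` on any of three statistics
#' computed across channels: (i) log variance, (ii) median absolute
#' amplitude, (iii) absolute deviation of the channel mean from the grand
#' channel mean. When a statistic has zero spread across channels its
#' z-scores are all zero (identical channels flag nothing).
#'
#' @param rec An [recording()] with at least 8 channels.
#' @param z_thresh z threshold (default 3).
#' @return List with `bad` (labels), `bad_idx`, and `z` (3 x channels matrix).
#' @export
detect_bad_channels <- function(rec, z_thresh = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 8) stop("need >= 8 channels for the z screen")
  x <- rec$data
  s1 <- log(pmax(apply(x, 1, var), 1e-12))
  s2 <- apply(abs(x), 1, median)
  mu <- rowMeans(x)
  s3 <- abs(mu - mean(mu))
  zmat <- rbind(variance = safe_z(s1), amplitude = safe_z(s2),
                deviation = safe_z(s3))
  colnames(zmat) <- rec$labels
  bad <- which(apply(abs(zmat) > z_thresh, 2, any))
  list(bad = rec$labels[bad], bad_idx = unname(bad), z = zmat)
}

safe_z <- function(s) {
  sdv <- sd(s)
  if (!is.finite(sdv) || sdv == 0) return(rep(0, length(s)))
  (s - mean(s)) / sdv
}

#' Participant inclusion decision from the bad-channel count
#'
#' Keep iff at most four channels were labeled bad.
#'
#' @param bad_channels Character or integer vector of bad channels.
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
participant_exclusion <- function(bad_channels) {
  length(bad_channels) <= 4
}

#' Cut a recording into overlapping 2-s epochs within resting blocks
#'
#' Each block (from its onset plus `delay_s` up to the next onset or the end
#' of the recording) is segmented into `epoch_s`-long epochs starting every
#' `epoch_s - overlap_s` seconds; partial trailing epochs are dropped.
#'
#' @param rec An [recording()].
#' @param delay_s Delay after each block onset before the first epoch, s.
#' @param epoch_s Epoch length, s (2 s gives the 0.5-Hz FFT resolution).
#' @param overlap_s Overlap between consecutive epochs, s.
#' @return Object of class `epoch_set`: list with `epochs` (list of channels
#'   x samples matrices), `start` (sample indices), `fs`, `labels`,
#'   `retained`, `reasons`.
#' @export
segment_epochs <- function(rec, delay_s = 0.5, epoch_s = 2, overlap_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"), epoch_s > overlap_s)
  fs <- rec$fs
  nsamp <- ncol(rec$data)
  onsets <- rec$block_onsets
  if (any(onsets > nsamp)) stop("block onset beyond recording end")
  ends <- c(onsets[-1] - 1, nsamp)
  len <- round(epoch_s * fs)
  step <- round((epoch_s - overlap_s) * fs)
  starts <- integer(0)
  for (bi in seq_along(onsets)) {
    s0 <- onsets[bi] + round(delay_s * fs)
    ss <- seq(s0, by = step, length.out = max(0, (ends[bi] - s0 + 1 - len) %/% step + 1))
    if (length(ss) == 0)
      warning(sprintf("block %d too short for a single epoch", bi))
    starts <- c(starts, ss)
  }
  epochs <- lapply(starts, function(s) rec$data[, s:(s + len - 1), drop = FALSE])
  structure(list(epochs = epochs, start = starts, fs = fs,
                 labels = rec$labels,
                 retained = rep(TRUE, length(epochs)),
                 reasons = vector("list", length(epochs))),
            class = "epoch_set")
}

#' Apply the three artifact-rejection criteria to an epoch set
#'
#' An epoch is rejected iff any channel violates any criterion:
#' (1) per-ms voltage gradient above `grad_uv_ms` (|dv| between consecutive
#' samples, expressed in uV/ms), (2) peak-to-peak range above `range2_uv`
#' inside any sliding 200-ms window, (3) peak-to-peak range below `flat_uv`
#' inside any sliding 100-ms window. Windows advance sample by sample.
#'
#' @param eps An [segment_epochs()] result.
#' @param grad_uv_ms,range2_uv,flat_uv Criterion thresholds.
#' @return The epoch set with `retained` and per-epoch `reasons`
#'   (integer vector of violated criteria) filled in.
#' @export
reject_epochs <- function(eps, grad_uv_ms = 50, range2_uv = 200,
                          flat_uv = 0.5) {
  stopifnot(inherits(eps, "epoch_set"))
  for (i in seq_along(eps$epochs)) {
    fl <- epoch_criteria(t(eps$epochs[[i]]), eps$fs,
                         grad_uv_ms = grad_uv_ms, range2_uv = range2_uv,
                         flat_uv = flat_uv)
    hit <- which(fl == 1L)
    eps$reasons[[i]] <- hit
    eps$retained[i] <- length(hit) == 0
  }
  eps
}

#' Average Hamming-tapered FFT power over retained epochs, then bin to 1 Hz
#'
#' Per channel, the power spectral density (uV^2/Hz, one-sided, window power
#' compensated) of each retained 2-s epoch is averaged in linear power;
#' frequencies run 0.5-30 Hz in 0.5-Hz steps, and the 30 one-Hz bins follow
#' [bin_spectrum()].
#'
#' @param eps A rejected/filtered [segment_epochs()] result.
#' @return Object of class `binned_spectrum`: list with `raw` (channels x 60
#'   linear PSD), `binned` (channels x 30), `freqs`, `n_epochs_used`; or
#'   `NULL` (with a warning) when no epoch survives.
#' @export
compute_spectrum <- function(eps) {
  stopifnot(inherits(eps, "epoch_set"))
  keep <- which(eps$retained)
  if (length(keep) == 0) {
    warning("no retained epochs; spectrum marked missing")
    return(NULL)
  }
  fs <- eps$fs
  N <- ncol(eps$epochs[[1]])
  stopifnot(N == round(2 * fs))                  # 0.5-Hz resolution
  w <- signal::hamming(N)
  U <- mean(w^2)
  kf <- 1:60                                     # 0.5 .. 30 Hz
  acc <- matrix(0, nrow = nrow(eps$epochs[[1]]), ncol = length(kf))
  for (i in keep) {
    xw <- sweep(eps$epochs[[i]], 2, w, `*`)
    X <- t(apply(xw, 1, fft))
    acc <- acc + 2 * abs(X[, kf + 1, drop = FALSE])^2 / (fs * N * U)
  }
  raw <- acc / length(keep)
  rownames(raw) <- eps$labels
  colnames(raw) <- paste0(freq_grid(), "Hz")
  structure(list(raw = raw, binned = bin_spectrum(raw), freqs = freq_grid(),
                 n_epochs_used = length(keep)),
            class = "binned_spectrum")
}

#' Mean band power per channel
#'
#' Mean of the raw-resolution power values with frequency inside
#' `[band[1], band[2]]`, endpoints inclusive on the 0.5-Hz grid (theta
#' 4-8 Hz uses 9 grid values; alpha 8.5-13 Hz uses 10).
#'
#' @param spectrum A [compute_spectrum()] result, or a channels x frequencies
#'   matrix with `freqs` supplied.
#' @param band Length-2 Hz range within 0.5-30.
#' @param freqs Frequency grid when `spectrum` is a bare matrix.
#' @return List with `per_channel` (named vector) and `mean` (grand mean).
#' @export
band_power <- function(spectrum, band, freqs = NULL) {
  if (inherits(spectrum, "binned_spectrum")) {
    mat <- spectrum$raw
    freqs <- spectrum$freqs
  } else {
    mat <- as.matrix(spectrum)
    stopifnot(!is.null(freqs))
  }
  stopifnot(length(band) == 2, band[1] <= band[2],
            band[1] >= min(freqs), band[2] <= max(freqs))
  idx <- which(freqs >= band[1] & freqs <= band[2])
  if (length(idx) == 0) stop("empty band")
  pc <- rowMeans(mat[, idx, drop = FALSE])
  list(per_channel = pc, mean = mean(pc))
}
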