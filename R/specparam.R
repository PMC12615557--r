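# Spectral parameterization: decompose a total power spectrum into an
# aperiodic background (offset, exponent; "fixed" mode, i.e. no knee) and
# Gaussian periodic peaks, in log10 power throughout.

#' Fit the aperiodic background of a log10 power spectrum
#'
#' Fixed-mode model: `L(f) = offset - exponent * log10(f)`, fit by least
#' squares in (log10 f, log10 P). The robust variant re-fits using only the
#' frequencies that are not elevated above the first-pass line (residuals
#' floored at zero; points at or below the low-percentile threshold of the
#' floored residuals are kept), which removes the influence of oscillatory
#' peaks.
#'
#' @param freqs Positive frequencies, >= 5 points.
#' @param log_power log10 power at `freqs`.
#' @param robust Use the peak-resistant two-pass fit.
#' @return Named vector `c(offset, exponent)`.
#' @export
fit_aperiodic <- function(freqs, log_power, robust = FALSE) {
  stopifnot(length(freqs) >= 5, all(freqs > 0),
            length(freqs) == length(log_power))
  lf <- log10(freqs)
  fit1 <- stats::lsfit(lf, log_power)$coefficients
  out <- c(offset = unname(fit1[1]), exponent = -unname(fit1[2]))
  if (!robust) return(out)
  resid <- log_power - (out["offset"] - out["exponent"] * lf)
  flat <- pmax(resid, 0)
  thr <- quantile(flat, 0.025 / 100, names = FALSE)
  mask <- flat <= thr
  if (sum(mask) < 5) {
    warning("fewer than 5 points after robust masking; plain fit kept")
    return(out)
  }
  fit2 <- stats::lsfit(lf[mask], log_power[mask])$coefficients
  c(offset = unname(fit2[1]), exponent = -unname(fit2[2]))
}

gaussian_sum <- function(freqs, peaks) {
  g <- numeric(length(freqs))
  for (k in seq_len(nrow(peaks)))
    g <- g + peaks$height[k] *
      exp(-(freqs - peaks$center[k])^2 / (2 * peaks$width[k]^2))
  g
}

#' Extract Gaussian peaks from an aperiodic-flattened spectrum
#'
#' Iteratively takes the residual maximum, stops when its height falls below
#' `threshold_sd` times the SD of the current residual (or below
#' `min_height`), estimates the width from the half-height extent (falling
#' back to twice the frequency resolution when unresolvable), bounds the
#' Gaussian SD to `width_limits / 2`, and subtracts the fitted Gaussian.
#' Candidates whose centers lie within `edge_margin` Hz of the grid edges
#' are discarded. All retained peaks are then refined jointly by bounded
#' nonlinear least squares (centers within +/- 1.5 SD of their guess,
#' heights >= 0, SDs within limits).
#'
#' @param flat Residual log10 power (total minus aperiodic fit).
#' @param freqs Frequency grid.
#' @param max_peaks Maximum number of peaks (default unlimited).
#' @param min_height Minimum absolute peak height (log10 power).
#' @param threshold_sd Relative detection threshold, in residual SDs.
#' @param width_limits Allowed 2*SD width range in Hz; Gaussian SDs are
#'   bounded to `width_limits / 2`.
#' @param edge_margin Exclusion zone at the grid edges, Hz.
#' @return Data frame with columns `center`, `height`, `width` (Gaussian SD),
#'   possibly empty.
#' @export
extract_peaks <- function(flat, freqs, max_peaks = Inf, min_height = 0,
                          threshold_sd = 2, width_limits = c(1, 12),
                          edge_margin = 1) {
  sd_lim <- width_limits / 2
  res <- flat
  guesses <- data.frame(center = numeric(0), height = numeric(0),
                        width = numeric(0))
  hard_cap <- min(max_peaks, 12)
  banned <- rep(FALSE, length(flat))
  while (nrow(guesses) < hard_cap) {
    cand <- res
    cand[banned] <- -Inf
    ind <- which.max(cand)
    if (!is.finite(cand[ind])) break
    h <- res[ind]
    if (h < threshold_sd * sd(res) || h <= min_height) break
    # noise guard: a resolvable peak (SD >= half the grid step bound) keeps
    # its immediate neighbours above half height; an isolated one-point
    # spike is sampling noise, not an oscillation
    nb <- c(if (ind > 1) res[ind - 1], if (ind < length(res)) res[ind + 1])
    if (any(nb < h / 2)) { banned[ind] <- TRUE; next }
    c0 <- freqs[ind]
    half <- h / 2
    ri <- ind; while (ri < length(res) && res[ri] > half) ri <- ri + 1
    li <- ind; while (li > 1 && res[li] > half) li <- li - 1
    ext <- c(if (res[li] <= half) c0 - freqs[li] else NA,
             if (res[ri] <= half) freqs[ri] - c0 else NA)
    fwhm <- 2 * min(ext, na.rm = TRUE)
    sd0 <- if (is.finite(fwhm) && fwhm > 0) fwhm / 2.355
           else 2 * (freqs[2] - freqs[1])
    sd0 <- min(max(sd0, sd_lim[1]), sd_lim[2])
    res <- res - h * exp(-(freqs - c0)^2 / (2 * sd0^2))
    guesses <- rbind(guesses,
                     data.frame(center = c0, height = h, width = sd0))
  }
  keep <- guesses$center >= min(freqs) + edge_margin &
          guesses$center <= max(freqs) - edge_margin
  guesses <- guesses[keep, , drop = FALSE]
  if (nrow(guesses) == 0) return(guesses)

  # joint bounded refinement on the original flattened spectrum
  p0 <- as.numeric(t(as.matrix(guesses)))
  lower <- as.numeric(t(cbind(pmax(guesses$center - 1.5 * guesses$width,
                                   min(freqs)),
                              0, sd_lim[1])))
  upper <- as.numeric(t(cbind(pmin(guesses$center + 1.5 * guesses$width,
                                   max(freqs)),
                              Inf, sd_lim[2])))
  resid_fun <- function(p) {
    pk <- as.data.frame(matrix(p, ncol = 3, byrow = TRUE))
    names(pk) <- c("center", "height", "width")
    flat - gaussian_sum(freqs, pk)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-8, ptol = 1e-8, maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    refined <- as.data.frame(matrix(fit$par, ncol = 3, byrow = TRUE))
    names(refined) <- c("center", "height", "width")
    guesses <- refined
  }
  guesses[order(guesses$center), , drop = FALSE]
}

# single-channel full parameterization loop
parameterize_channel <- function(power, freqs, max_peaks = Inf,
                                 min_height = 0, threshold_sd = 2,
                                 width_limits = c(1, 12), edge_margin = 1) {
  if (any(power <= 0)) return(NULL)
  lp <- log10(power)
  # plain fit -> peaks -> peak-removed robust refit -> final peaks
  ap0 <- fit_aperiodic(freqs, lp, robust = FALSE)
  flat0 <- lp - (ap0["offset"] - ap0["exponent"] * log10(freqs))
  pk0 <- extract_peaks(flat0, freqs, max_peaks, min_height, threshold_sd,
                       width_limits, edge_margin)
  peak_rm <- lp - gaussian_sum(freqs, pk0)
  ap <- fit_aperiodic(freqs, peak_rm, robust = TRUE)
  ap_fit <- ap["offset"] - ap["exponent"] * log10(freqs)
  periodic <- lp - ap_fit
  peaks <- extract_peaks(periodic, freqs, max_peaks, min_height,
                         threshold_sd, width_limits, edge_margin)
  model <- ap_fit + gaussian_sum(freqs, peaks)
  list(offset = unname(ap["offset"]), exponent = unname(ap["exponent"]),
       peaks = peaks, periodic = periodic,
       r_squared = if (sd(lp) > 0 && sd(model) > 0) cor(lp, model)^2 else NA_real_,
       mae = mean(abs(lp - model)))
}

#' Parameterize power spectra into periodic and aperiodic components
#'
#' Full per-channel loop: plain aperiodic fit, peak extraction on the
#' residual, subtraction of the peak model, robust aperiodic re-fit, and a
#' final peak pass on the final residual. The periodic spectrum is defined
#' as `log10(total) - aperiodic fit`, so aperiodic fit + periodic spectrum
#' reconstructs the total log spectrum exactly.
#'
#' @param power Channels x frequencies matrix (or single vector) of linear
#'   power; all values must be positive (non-positive channels are skipped
#'   and flagged).
#' @param freqs Frequency grid (default [freq_grid()]).
#' @param ... Passed to [extract_peaks()] (`max_peaks`, `min_height`,
#'   `threshold_sd`, `width_limits`, `edge_margin`).
#' @return Object of class `spectral_fit`: list with `aperiodic` (data frame:
#'   channel, offset, exponent, r_squared, mae), `peaks` (data frame with
#'   channel column), `periodic` (channels x frequencies log10 residual),
#'   `periodic_binned` (channels x 30), `freqs`, `failed` (channel indices).
#' @export
parameterize <- function(power, freqs = freq_grid(), ...) {
  if (!is.matrix(power)) power <- matrix(power, nrow = 1)
  nc <- nrow(power)
  ap <- data.frame(channel = seq_len(nc), offset = NA_real_,
                   exponent = NA_real_, r_squared = NA_real_, mae = NA_real_)
  peaks <- data.frame(channel = integer(0), center = numeric(0),
                      height = numeric(0), width = numeric(0))
  periodic <- matrix(NA_real_, nc, length(freqs))
  failed <- integer(0)
  for (ch in seq_len(nc)) {
    fit <- parameterize_channel(power[ch, ], freqs, ...)
    if (is.null(fit)) { failed <- c(failed, ch); next }
    ap$offset[ch] <- fit$offset
    ap$exponent[ch] <- fit$exponent
    ap$r_squared[ch] <- fit$r_squared
    ap$mae[ch] <- fit$mae
    periodic[ch, ] <- fit$periodic
    if (nrow(fit$peaks) > 0)
      peaks <- rbind(peaks, cbind(channel = ch, fit$peaks))
  }
  structure(list(aperiodic = ap, peaks = peaks, periodic = periodic,
                 periodic_binned = bin_spectrum(periodic), freqs = freqs,
                 failed = failed),
            class = "spectral_fit")
}

#' Parameterize every participant/channel spectrum of a cohort condition
#'
#' @param cohort An [simulate_cohort()] result.
#' @param condition Condition label.
#' @param ... Passed to [parameterize()].
#' @return List with `periodic` (participants x channels x 30 binned periodic
#'   log power), `aperiodic` (participants x channels x 2, offset and
#'   exponent).
#' @export
parameterize_cohort <- function(cohort, condition, ...) {
  arr <- cohort$spectra[[condition]]
  if (is.null(arr)) stop("unknown condition: ", condition)
  n <- dim(arr)[1]; nc <- dim(arr)[2]
  periodic <- array(NA_real_, dim = c(n, nc, dim(arr)[3] / 2))
  aperiodic <- array(NA_real_, dim = c(n, nc, 2),
                     dimnames = list(NULL, NULL, c("offset", "exponent")))
  for (i in seq_len(n)) {
    fit <- parameterize(10^arr[i, , ], cohort$freqs, ...)
    periodic[i, , ] <- fit$periodic_binned
    aperiodic[i, , 1] <- fit$aperiodic$offset
    aperiodic[i, , 2] <- fit$aperiodic$exponent
  }
  list(periodic = periodic, aperiodic = aperiodic)
}
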