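# Shared helpers: frequency grid, binning, Fisher transform, seed derivation.

#' Analysis frequency grid
#'
#' The raw spectral grid used throughout: 0.5 to 30 Hz in 0.5-Hz steps
#' (60 frequencies), matching a 2-s FFT epoch.
#'
#' @param fmin,fmax,step Grid limits and step in Hz.
#' @return Numeric vector of frequencies.
#' @export
freq_grid <- function(fmin = 0.5, fmax = 30, step = 0.5) {
  seq(fmin, fmax, by = step)
}

#' Average a 0.5-Hz-resolution spectrum into 1-Hz bins
#'
#' Bin i (i = 1..30) is the mean of the raw values at i - 0.5 and i Hz, so
#' the 1-Hz bin contains the 0.5-Hz and 1-Hz grid points.
#'
#' @param x Numeric vector (length 60) or matrix (channels x 60) on the
#'   [freq_grid()] grid.
#' @return Vector of 30 bin values, or channels x 30 matrix.
#' @export
bin_spectrum <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) %% 2 == 0)
    nb <- ncol(x) / 2
    out <- (x[, seq(1, ncol(x), by = 2), drop = FALSE] +
            x[, seq(2, ncol(x), by = 2), drop = FALSE]) / 2
    colnames(out) <- paste0("bin", seq_len(nb))
    out
  } else {
    stopifnot(length(x) %% 2 == 0)
    (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]) / 2
  }
}

#' Fisher Z transform and inverse
#'
#' `fisher_z()` is `atanh` with inputs clipped just inside (-1, 1) so that a
#' numerically perfect correlation does not map to infinity;
#' `fisher_z_inv()` is `tanh`.
#'
#' @param r Correlation(s).
#' @param z Fisher-Z value(s).
#' @return Transformed values.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Derive a child RNG seed from a master seed and a key path
#'
#' Deterministic polynomial string hash; used so that every cell / repetition
#' / permutation of a run has its own reproducible stream and adding cells
#' never perturbs existing ones.
#'
#' @param seed Master integer seed.
#' @param ... Key components (coerced to character).
#' @return Integer in \[1, 2^31).
#' @export
seed_for <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

#' Read a long-format spectra TSV into per-condition arrays
#'
#' Inverse of [write_cohort()]'s `spectra.tsv`: expects columns
#' `participant`, `condition`, `channel`, `freq_hz`, `log10_power`.
#'
#' @param path TSV file path.
#' @return List with `spectra` (condition -> participants x channels x
#'   frequencies array of log10 power), `freqs`, `participants`.
#' @export
read_spectra_tsv <- function(path) {
  d <- read.delim(path)
  stopifnot(all(c("participant", "condition", "channel", "freq_hz",
                  "log10_power") %in% names(d)))
  parts <- sort(unique(d$participant))
  freqs <- sort(unique(d$freq_hz))
  chans <- sort(unique(d$channel))
  out <- list()
  for (cond in sort(unique(d$condition))) {
    arr <- array(NA_real_, c(length(parts), length(chans), length(freqs)))
    dc <- d[d$condition == cond, ]
    pi_ <- match(dc$participant, parts)
    ci <- match(dc$channel, chans)
    fi <- match(dc$freq_hz, freqs)
    arr[cbind(pi_, ci, fi)] <- dc$log10_power
    out[[cond]] <- arr
  }
  list(spectra = out, freqs = freqs, participants = parts)
}

# internal: run code under a local RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
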