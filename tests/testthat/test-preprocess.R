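# Filtering, bad-channel screening, epoching, artifact rejection, spectra.

test_that("band-pass filter passes 10 Hz, kills 45 Hz and DC", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)[-1]
  mk <- function(x) recording(matrix(x, 1), fs)
  amp <- function(x) (max(x) - min(x)) / 2

  in10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass_filter(mk(in10))$data[1, ]
  mid <- 2000:8000                      # away from edges
  expect_gte(amp(out10[mid]), 0.89)
  expect_lte(amp(out10[mid]), 1.12)

  out45 <- bandpass_filter(mk(sin(2 * pi * 45 * t)))$data[1, ]
  expect_lt(amp(out45[mid]), 0.1)

  outdc <- bandpass_filter(mk(rep(100, length(t))))$data[1, ]
  expect_lt(abs(mean(outdc[mid])), 1)

  expect_error(bandpass_filter(recording(matrix(rnorm(100), 1), fs)),
               "shorter")
})

test_that("bad-channel screen flags scaled, flat, and spares identical channels", {
  set.seed(1)
  base <- matrix(rnorm(16 * 5000), 16, 5000)
  scaled <- base
  scaled[7, ] <- scaled[7, ] * 20
  det <- detect_bad_channels(recording(scaled, 500))
  expect_equal(det$bad_idx, 7)

  det0 <- detect_bad_channels(recording(base[rep(1, 10), ], 500))
  expect_equal(length(det0$bad), 0)

  flat <- base
  flat[3, ] <- 0
  detf <- detect_bad_channels(recording(flat, 500))
  expect_true(3 %in% detf$bad_idx)

  expect_error(detect_bad_channels(recording(base[1:4, ], 500)), ">= 8")
})

test_that("participant exclusion applies the more-than-four rule", {
  expect_true(participant_exclusion(paste0("Ch", 1:4)))   # 4 bad: keep
  expect_false(participant_exclusion(paste0("Ch", 1:5)))  # 5 bad: drop
  expect_true(participant_exclusion(character(0)))
})

test_that("epoch segmentation arithmetic matches the 2-s/1-s grid", {
  fs <- 500
  mk <- function(secs) recording(matrix(0, 1, secs * fs), fs)
  expect_equal(length(segment_epochs(mk(60), delay_s = 0)$epochs), 59)
  expect_equal(length(segment_epochs(mk(10), delay_s = 0)$epochs), 9)
  expect_warning(ep0 <- segment_epochs(mk(2), delay_s = 0.5), "too short")
  expect_equal(length(ep0$epochs), 0)
  # epochs are 2 s long and overlap by exactly 1 s
  ep <- segment_epochs(mk(10), delay_s = 0)
  expect_true(all(vapply(ep$epochs, ncol, 0L) == 2 * fs))
  expect_true(all(diff(ep$start) == fs))
})

test_that("rejection criteria: step, constant, and clean sinusoid epochs", {
  fs <- 500
  t <- seq_len(2 * fs) / fs
  clean <- 10 * sin(2 * pi * 10 * t)          # max gradient ~0.63 uV/ms
  step <- clean
  step[600:1000] <- step[600:1000] + 300      # 300 uV step
  flat <- c(clean[1:500], rep(5, 600), clean[1101:(2 * fs)])
  eps <- structure(list(epochs = list(matrix(clean, 1), matrix(step, 1),
                                      matrix(flat, 1)),
                        start = c(1, 1, 1), fs = fs, labels = "Ch01",
                        retained = rep(TRUE, 3),
                        reasons = vector("list", 3)),
                   class = "epoch_set")
  out <- reject_epochs(eps)
  expect_true(out$retained[1])
  expect_false(out$retained[2])
  expect_true(2 %in% out$reasons[[2]])        # 200 uV / 200 ms range
  expect_false(out$retained[3])
  expect_true(3 %in% out$reasons[[3]])        # flatline
  # bookkeeping: retained + rejected = all; every rejection has a reason
  expect_equal(sum(out$retained) + sum(!out$retained), 3)
  expect_true(all(vapply(out$reasons[!out$retained], length, 0L) >= 1))
})

test_that("spectral estimation obeys Parseval and the binning rule", {
  fs <- 500
  t <- seq_len(60 * fs) / fs
  A <- 5
  x <- A * sin(2 * pi * 10 * t)
  eps <- segment_epochs(recording(matrix(x, 1), fs), delay_s = 0)
  sp <- compute_spectrum(eps)
  # sinusoid: integrated 8.5-13 Hz power ~ A^2/2 within 5%
  idx <- which(freq_grid() >= 8.5 & freq_grid() <= 13)
  expect_equal(sum(sp$raw[1, idx]) * 0.5, A^2 / 2, tolerance = 0.05)

  # band-limited noise: integrated power ~ variance within 10%
  xn <- simulate_recording(spectrum_model(0.5, 0.8), 500, 60, seed = 9)
  epn <- segment_epochs(recording(matrix(xn, 1), fs), delay_s = 0)
  spn <- compute_spectrum(epn)
  expect_equal(sum(spn$raw[1, ]) * 0.5, var(xn), tolerance = 0.1)

  # binning: 30 bins; bin 1 = mean of the 0.5 and 1.0 Hz values
  expect_equal(ncol(sp$binned), 30)
  expect_equal(sp$binned[1, 1], mean(sp$raw[1, 1:2]))

  # epoch order does not matter
  eps2 <- eps
  eps2$epochs <- rev(eps2$epochs)
  expect_equal(compute_spectrum(eps2)$raw, sp$raw, tolerance = 1e-12)

  # no retained epochs -> missing
  eps3 <- eps
  eps3$retained[] <- FALSE
  expect_warning(expect_null(compute_spectrum(eps3)), "missing")
})

test_that("band_power uses inclusive endpoints on the 0.5-Hz grid", {
  mat <- matrix(rep(c(2, 4), each = 60), 2, 60, byrow = TRUE)
  # flat spectra: band power equals the level for any band
  expect_equal(unname(band_power(mat, c(4, 8), freqs = freq_grid())$per_channel),
               c(2, 4))
  # theta grid has 9 values, alpha 10
  expect_equal(sum(freq_grid() >= 4 & freq_grid() <= 8), 9)
  expect_equal(sum(freq_grid() >= 8.5 & freq_grid() <= 13), 10)
  expect_error(band_power(mat, c(31, 35), freqs = freq_grid()))
})

test_that("band-power ordering across participants preserves planted ordering", {
  # noiseless single-channel cohort with graded alpha heights
  heights <- seq(0.1, 0.9, length.out = 9)
  est <- truth <- numeric(9)
  for (i in seq_along(heights)) {
    m <- alpha_model(height = heights[i])
    x <- simulate_recording(m, 500, 30, seed = 20 + i)
    sp <- compute_spectrum(segment_epochs(recording(matrix(x, 1), 500),
                                          delay_s = 0))
    est[i] <- band_power(sp, c(8.5, 13))$mean
    truth[i] <- mean(10^simulate_spectrum(m, freq_grid()[freq_grid() >= 8.5 &
                                                         freq_grid() <= 13]))
  }
  expect_gt(cor(est, truth, method = "spearman"), 0.9)
})
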