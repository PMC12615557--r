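# Synthetic cohort generation: spectra, recordings, planted associations,
# injected artifacts, reproducibility.

test_that("simulate_spectrum follows the closed-form 1/f-plus-peaks model", {
  # pure power law
  expect_equal(simulate_spectrum(spectrum_model(2, 1.5), freqs = 10), 0.5)
  # flat spectrum at exponent 0
  expect_equal(simulate_spectrum(spectrum_model(1.3, 0), freqs = c(1, 5, 20)),
               rep(1.3, 3))
  # Gaussian peak adds exactly its height at the center
  m <- alpha_model(offset = 1, exponent = 1, height = 0.6)
  ap <- 1 - 1 * log10(10)
  expect_equal(simulate_spectrum(m, freqs = 10), ap + 0.6)
  # input validation
  expect_error(simulate_spectrum(m, freqs = c(-1, 5)), "positive")
  expect_error(simulate_spectrum(m, freqs = c(5, 4)), "increasing")
})

test_that("simulate_recording's Welch spectrum matches the model target", {
  m <- alpha_model()
  x <- simulate_recording(m, fs = 500, seconds = 60, seed = 2)
  eps <- reject_epochs(segment_epochs(recording(matrix(x, 1), 500),
                                      delay_s = 0))
  est <- log10(compute_spectrum(eps)$raw[1, ])
  target <- simulate_spectrum(alpha_model(noise_sd = 0), freq_grid())
  sel <- freq_grid() >= 3
  expect_lt(mean(abs(est[sel] - target[sel])), 0.15)
  # exponent recovered through the full spectral-fit path
  fit <- parameterize(10^est)
  expect_lt(abs(fit$aperiodic$exponent - 1.5), 0.1)
})

test_that("a pure narrowband peak model concentrates power at its center", {
  m <- spectrum_model(-2, 0, data.frame(center = 10, height = 3, width = 0.5))
  x <- simulate_recording(m, fs = 500, seconds = 20, seed = 4)
  eps <- segment_epochs(recording(matrix(x, 1), 500), delay_s = 0)
  sp <- compute_spectrum(eps)
  expect_lt(abs(freq_grid()[which.max(sp$raw[1, ])] - 10), 0.51)
})

test_that("zero-scale models give all-zero traces; generation is reproducible", {
  expect_equal(simulate_recording(alpha_model(), 500, 4, seed = 1, scale = 0),
               numeric(2000))
  a <- simulate_recording(alpha_model(), 500, 10, seed = 7)
  b <- simulate_recording(alpha_model(), 500, 10, seed = 7)
  expect_identical(a, b)
  coh1 <- null_cohort(n = 20, seed = 3)
  coh2 <- null_cohort(n = 20, seed = 3)
  expect_identical(coh1$spectra, coh2$spectra)
  expect_identical(coh1$behavioral, coh2$behavioral)
})

test_that("plant_association reaches its target correlation", {
  set.seed(10)
  n <- 500
  spectra <- array(rnorm(n * 4 * 60, sd = 0.3), c(n, 4, 60))
  spectra <- sweep(spectra, 3, simulate_spectrum(alpha_model(), freq_grid()),
                   `+`)
  scores <- rnorm(n)
  band_mean <- function(arr) {
    idx <- which(freq_grid() >= 8.5 & freq_grid() <= 13)
    apply(arr[, , idx], 1, mean)
  }
  # target 0 is the identity
  expect_identical(plant_association(spectra, scores, target_r = 0), spectra)
  # strong positive association
  sp2 <- plant_association(spectra, scores, target_r = 0.9)
  rho <- cor(band_mean(sp2), scores, method = "spearman")
  expect_gte(rho, 0.8)
  expect_lte(rho, 1.0)
  # negative association
  sp3 <- plant_association(spectra, scores, target_r = -0.3)
  expect_lt(cor(band_mean(sp3), scores, method = "spearman"), 0)
  # marginal spread approximately preserved, empty channel set rejected
  expect_equal(sd(band_mean(sp2)), sd(band_mean(spectra)), tolerance = 0.05)
  expect_error(plant_association(spectra, scores, channels = integer(0),
                                 target_r = 0.5), "empty channel set")
})

test_that("injected artifacts trip exactly their named criteria", {
  rec <- noise_recording(4, seconds = 30, seed = 5)
  plan <- data.frame(epoch = c(3, 9, 15), channel = c(1, 2, 3),
                     criterion = 1:3)
  inj <- inject_artifacts(rec, plan)
  eps <- reject_epochs(segment_epochs(inj$recording))
  for (i in 1:3)
    expect_true(plan$criterion[i] %in% eps$reasons[[plan$epoch[i]]],
                label = sprintf("criterion %d found in epoch %d",
                                plan$criterion[i], plan$epoch[i]))
  # empty plan leaves the recording untouched
  empty <- inject_artifacts(rec, data.frame())
  expect_identical(empty$recording$data, rec$data)
  expect_equal(nrow(empty$ledger), 0)
  # unknown channel rejected
  expect_error(inject_artifacts(rec, data.frame(epoch = 1, channel = 99,
                                                criterion = 1)),
               "nonexistent channel")
})

test_that("write_cohort round-trips spectra through the TSV format", {
  coh <- null_cohort(n = 5, channels = 2)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  sp <- read.delim(file.path(d, "spectra.tsv"))
  expect_equal(nrow(sp), 5 * 2 * 60)
  one <- sp[sp$participant == "P0003" & sp$channel == 2, ]
  expect_equal(one$log10_power, coh$spectra$pre_open[3, 2, ],
               tolerance = 1e-12)
  behav <- read.delim(file.path(d, "behavioral.tsv"))
  expect_equal(behav$fluid, coh$behavioral$fluid)
})
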