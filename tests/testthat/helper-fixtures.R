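# Shared fixtures, all generated in code.

# single-channel model with one alpha peak
alpha_model <- function(offset = 1, exponent = 1.5, height = 0.6,
                        center = 10, width = 1.5, noise_sd = 0) {
  spectrum_model(offset, exponent,
                 data.frame(center = center, height = height, width = width),
                 noise_sd)
}

# multichannel iid band-limited noise recording
noise_recording <- function(n_channels = 8, fs = 500, seconds = 60,
                            seed = 1, model = spectrum_model(1, 1.5)) {
  dat <- t(vapply(seq_len(n_channels), function(ch)
    simulate_recording(model, fs, seconds, seed = seed * 1000 + ch),
    numeric(round(fs * seconds))))
  recording(dat, fs)
}

# small planted-effect cohort for decoding tests
planted_cohort <- function(n = 400, r = 0.4, seed = 1, channels = 8,
                           conditions = "pre_open", band = c(8, 13)) {
  cfg <- cohort_config(n_participants = n, n_channels = channels,
                       conditions = conditions,
                       associations = list(list(score = "fluid",
                                                band = band, r = r)),
                       seed = seed)
  simulate_cohort(cfg)
}

null_cohort <- function(n = 300, seed = 1, channels = 8,
                        conditions = "pre_open") {
  simulate_cohort(cohort_config(n_participants = n, n_channels = channels,
                                conditions = conditions, seed = seed))
}

# brute-force multiple-testing references (independent of stats::p.adjust)
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (i in seq_len(m)) {
    rank_i <- m - i + 1
    running <- min(running, m * p[o[i]] / rank_i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}
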