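# Shared fixtures, all built in code.

# A "flat" series: no stimulus, so the model potential is exactly V_K.
flat_series <- function(values, sigma = 1, id = "flat") {
  mp_series(values, series_id = id,
            condition = condition_params(S_max = 0), sigma = sigma)
}

# Small noiseless synthetic dataset (fast fixture for structural tests).
quiet_spec <- function(seed = 1, n_control = 1, n_dnds = 1, n_stx = 0,
                       length_s = 120, white_sd = 0) {
  synthetic_spec(design = c(control = n_control, DNDS = n_dnds, STX = n_stx),
                 noise = list(white_sd = white_sd, spike_rate = 0,
                              spike_amp = 0, step_prob = 0, step_amp = 0,
                              step_dur = 0),
                 length_s = length_s, seed = seed)
}

# Dataset with sigma forced (needed when generated without noise).
with_sigma <- function(dataset, sigma) {
  dataset$series <- lapply(dataset$series, function(s) {
    s$sigma <- sigma
    s
  })
  dataset
}

fast_opt <- function(seed = 1, n_starts = 1, rounds = 2, maxit = 40) {
  opt_config(n_starts = n_starts, rounds = rounds, maxit = maxit,
             seed = seed)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
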