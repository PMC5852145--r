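test_that("default design reproduces the 16-series study layout", {
  gd <- generate_dataset(synthetic_spec(seed = 2))
  expect_length(gd$raw, 16)
  labs <- vapply(gd$raw, `[[`, character(1), "condition_label")
  expect_identical(sum(labs == "control"), 7L)
  expect_identical(sum(labs == "DNDS"), 5L)
  expect_identical(sum(labs == "STX"), 4L)
  # condition semantics: DNDS blocks ClC, STX blocks NaC
  for (r in gd$raw) {
    if (r$condition_label == "DNDS") expect_identical(r$condition$eta_Cl, 0)
    if (r$condition_label == "STX") expect_identical(r$condition$eta_Na, 0)
    if (r$condition_label == "control") {
      expect_identical(r$condition$eta_Cl, 1)
      expect_identical(r$condition$eta_Na, 1)
    }
  }
  # ground truth is complete
  expect_length(gd$truth$phi, 16)
  expect_identical(gd$truth$topology$index, 7L)
})

test_that("generation is bit-identical given the seed", {
  a <- generate_dataset(synthetic_spec(seed = 33))
  b <- generate_dataset(synthetic_spec(seed = 33))
  expect_identical(a$raw, b$raw)
  c <- generate_dataset(synthetic_spec(seed = 34))
  expect_false(identical(a$raw[[1]]$values, c$raw[[1]]$values))
})

test_that("zero noise reproduces the clean trajectory exactly", {
  gd <- generate_dataset(quiet_spec(seed = 7, length_s = 100))
  for (i in seq_along(gd$raw)) {
    r <- gd$raw[[i]]
    tr <- conewire:::sim_vhat(conewire:::topology_codes(gd$truth$topology),
                              conewire:::theta_vec(gd$truth$theta),
                              conewire:::phi_vec(gd$truth$phi[[i]]),
                              conewire:::cond_vec(r$condition), r$times)
    expect_equal(r$values, tr, tolerance = 1e-12)
  }
})

test_that("artifact injection has the declared statistics", {
  times <- seq(0, 600, by = 0.1)
  clean <- rep(-75, length(times))
  nz0 <- list(white_sd = 0, spike_rate = 0, spike_amp = 0,
              step_prob = 0, step_amp = 0, step_dur = 0)
  out0 <- inject_artifacts(times, clean, nz0, seed = 1)
  expect_identical(out0$values, clean)
  # white noise s.d. within 5 percent at this length
  nzw <- nz0; nzw$white_sd <- 2
  outw <- inject_artifacts(times, clean, nzw, seed = 2)
  expect_lt(abs(sd(outw$values - clean) - 2), 0.1)
  # spike count over 10 seeds ~ Poisson(120) central range
  nzs <- nz0; nzs$spike_rate <- 0.02; nzs$spike_amp <- 40
  counts <- vapply(1:10, function(sd0)
    length(inject_artifacts(times, clean, nzs, seed = sd0)$spikes),
    numeric(1))
  expect_gte(sum(counts), qpois(0.005, 120))
  expect_lte(sum(counts), qpois(0.995, 120))
})

test_that("PKG-inhibited data never depolarizes above baseline", {
  gd <- generate_alternative_dataset(quiet_spec(seed = 5, n_control = 2,
                                                n_dnds = 1, n_stx = 1,
                                                length_s = 150),
                                     mode = "pkg_inhibited")
  for (i in seq_along(gd$raw)) {
    vk <- gd$truth$phi[[i]]$V_K
    expect_true(all(gd$raw[[i]]$values <= vk + 1e-8))
    expect_identical(gd$raw[[i]]$condition$pkg_active, 0)
  }
})

test_that("alternative-core generator rewires rather than relabels", {
  spec <- quiet_spec(seed = 6, length_s = 100)
  gd <- generate_alternative_dataset(spec, mode = "different_core")
  expect_identical(gd$truth$topology$index, 1L)
  expect_equal(gd$truth$theta$K_Y, gd$truth$theta$K_X)
  expect_equal(gd$truth$theta$n_Y, gd$truth$theta$n_X)
  gd2 <- generate_alternative_dataset(spec, mode = "different_core")
  expect_identical(gd$raw, gd2$raw)
})

test_that("round trip: preprocessing recovers the injected noise level", {
  spec <- synthetic_spec(seed = 14,
                         noise = list(white_sd = 2, spike_rate = 0,
                                      spike_amp = 0, step_prob = 0,
                                      step_amp = 0, step_dur = 0))
  ds <- preprocess_dataset(generate_dataset(spec))
  sig <- vapply(ds$series, `[[`, numeric(1), "sigma")
  expect_true(all(abs(sig - 2) < 0.2))
  expect_length(ds, 16)
  expect_length(ds$series[[1]]$values, 601)
})
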