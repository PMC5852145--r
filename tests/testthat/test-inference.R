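test_that("truncated-normal log prior: half-normal values and truncation", {
  pr <- default_priors(g_WtoCl = truncated_normal_prior(0, 1, 0))
  lay <- param_layout(7, 0, pr)
  par <- conewire:::default_init(lay)
  # zero-peaked half-normal at x = 0: log(2 / sqrt(2 pi))
  par["g_WtoCl"] <- 0
  one <- log_prior_density(par, lay, subset = "g_WtoCl")
  expect_equal(one, log(2 / sqrt(2 * pi)), tolerance = 1e-12)
  par["g_WtoCl"] <- -0.1
  expect_identical(log_prior_density(par, lay, subset = "g_WtoCl"), -Inf)
  # additivity over independent parameters
  par["g_WtoCl"] <- 0.7
  a <- log_prior_density(par, lay, subset = "g_WtoCl")
  b <- log_prior_density(par, lay, subset = "K_X")
  expect_equal(log_prior_density(par, lay, subset = c("g_WtoCl", "K_X")),
               a + b, tolerance = 1e-12)
  # missing prior is a configuration error
  expect_error(param_layout(7, 1, pr[names(pr) != "tau_S"]),
               "configuration-error")
})

test_that("hierarchical peripheral priors are centered on the core means", {
  lay <- param_layout(1, 1, default_priors())
  par <- conewire:::default_init(lay)
  par["A_Cl0"] <- 14
  par["A_Cl.1"] <- 14
  got <- log_prior_density(par, lay, subset = "A_Cl.1")
  expect_equal(got, conewire:::dtnorm_log(14, 14, 5, 0), tolerance = 1e-12)
})

test_that("series log likelihood matches the Gaussian formula and oracle", {
  s1 <- flat_series(0)                 # one point, sigma 1, Vhat = V_K
  expect_equal(log_likelihood_series(s1, 0), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(log_likelihood_series(s1, 1), -0.5 * log(2 * pi) - 0.5,
               tolerance = 1e-12)
  set.seed(2)
  v <- rnorm(50, -70, 3)
  vhat <- rnorm(50, -70, 1)
  s <- flat_series(v, sigma = 1.7)
  oracle <- sum(dnorm(v, vhat, 1.7, log = TRUE))   # brute-force product
  expect_equal(log_likelihood_series(s, vhat), oracle, tolerance = 1e-12)
  s_bad <- flat_series(v, sigma = NA)
  expect_error(log_likelihood_series(s_bad, vhat), "invalid-input")
})

test_that("total log likelihood sums per-series terms", {
  set.seed(3)
  gd <- generate_dataset(quiet_spec(seed = 3, length_s = 100, white_sd = 1))
  ds <- with_sigma(preprocess_dataset(gd), 1.5)
  th <- gd$truth$theta
  phi <- gd$truth$phi
  ll <- total_log_likelihood(ds, 7, th, phi)
  # brute-force oracle: simulate each series and sum dnorm terms
  oracle <- 0
  for (i in seq_along(ds$series)) {
    s <- ds$series[[i]]
    tr <- simulate_mpts(7, th, phi[[i]], s$condition,
                        T_end = length(s$values) - 1)
    oracle <- oracle + sum(dnorm(s$values, tr$V_mV, 1.5, log = TRUE))
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
  # two identical series double the value
  ds1 <- ds[1]
  s2 <- ds$series[[1]]; s2$series_id <- "copy"
  ds2 <- mp_dataset(list(ds$series[[1]], s2))
  expect_equal(total_log_likelihood(ds2, 7, th, phi[c(1, 1)]),
               2 * total_log_likelihood(ds1, 7, th, phi[1]),
               tolerance = 1e-10)
  expect_identical(total_log_likelihood(mp_dataset(list()), 7, th, list()), 0)
})

test_that("posterior sampling recovers a conjugate-normal toy", {
  set.seed(9)
  vals <- rnorm(50, -70, 1)
  ds <- mp_dataset(list(flat_series(vals)))
  pr <- default_priors()
  lay <- param_layout(1, 1, pr)
  fixed <- conewire:::default_init(lay)
  fixed <- fixed[names(fixed) != "V_K.1"]
  ch <- sample_posterior(ds, 1, pr, mcmc_config(n_steps = 1500,
                                                burn_in = 400, seed = 2),
                         fixed = fixed)
  post_var <- 1 / (1 / 100 + 50)
  post_mean <- post_var * (-75 / 100 + sum(vals))
  est <- posterior_mean_estimate(ch)$phi[[1]]$V_K
  expect_lt(abs(est - post_mean), 3 * sqrt(post_var))
  # determinism contract
  ch2 <- sample_posterior(ds, 1, pr, mcmc_config(n_steps = 150,
                                                 burn_in = 50, seed = 5),
                          fixed = fixed)
  ch3 <- sample_posterior(ds, 1, pr, mcmc_config(n_steps = 150,
                                                 burn_in = 50, seed = 5),
                          fixed = fixed)
  expect_identical(ch2$draws, ch3$draws)
})

test_that("posterior draws never violate truncation bounds", {
  gd <- generate_dataset(quiet_spec(seed = 4, length_s = 80, white_sd = 1))
  ds <- with_sigma(preprocess_dataset(gd), 1)
  ch <- sample_posterior(ds, 7, config = mcmc_config(n_steps = 150,
                                                     burn_in = 100, seed = 1))
  lay <- ch$layout
  for (nm in colnames(ch$draws)) {
    lo <- lay[nm, "lower"]
    if (is.finite(lo)) expect_true(all(ch$draws[, nm] >= lo))
  }
})

test_that("posterior mean estimate reduces chains correctly", {
  m <- matrix(rep(c(1, 3), each = 4), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_equal(unname(posterior_mean_estimate(m)), rep(2, 4))
  one <- matrix(5, 10, 1, dimnames = list(NULL, "x"))
  expect_equal(unname(posterior_mean_estimate(one)), 5)
  expect_error(posterior_mean_estimate(matrix(numeric(0), 0, 1)),
               "invalid-input")
})

test_that("optimizer solves the flat model exactly and is deterministic", {
  set.seed(12)
  vals <- rnorm(80, -68, 1)
  ds <- mp_dataset(list(flat_series(vals)))
  fit <- maximize_log_likelihood(ds, 1, config = fast_opt())
  expect_lt(abs(fit$phi[[1]]$V_K - mean(vals)), 1e-6)
  fit2 <- maximize_log_likelihood(ds, 1, config = fast_opt())
  expect_identical(fit$par, fit2$par)
})

test_that("perfect-fit data reaches the Gaussian likelihood ceiling", {
  gd <- generate_dataset(quiet_spec(seed = 6, length_s = 150))
  ds <- with_sigma(preprocess_dataset(gd), 2)
  ll <- total_log_likelihood(ds, 7, gd$truth$theta, gd$truth$phi)
  ceiling_ll <- -sum(vapply(ds$series, function(s)
    length(s$values) * log(sqrt(2 * pi) * s$sigma), numeric(1)))
  expect_lt(abs(ll - ceiling_ll), 1e-3)
})

test_that("information criteria implement the textbook formulas", {
  ic <- information_criteria(-100, 2, 100)
  expect_equal(unname(ic["AIC"]), 204)
  expect_equal(unname(ic["BIC"]), 2 * log(100) + 200, tolerance = 1e-9)
  expect_equal(unname(information_criteria(-50, 0, 10)["AIC"]), 100)
})
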