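test_that("stimulus time course matches its closed form", {
  expect_equal(stimulus_concentration(0, 10), 0)
  expect_equal(stimulus_concentration(30, 10, tau_S = 30),
               10 * (1 - exp(-1)))
  expect_equal(stimulus_concentration(1e6, 10), 10, tolerance = 1e-12)
  t <- seq(0, 300, by = 7)
  s <- stimulus_concentration(t, 5, tau_S = 20)
  expect_true(all(diff(s) >= 0))
  expect_error(stimulus_concentration(-1, 10), "invalid-argument")
  expect_error(stimulus_concentration(1, 10, tau_S = 0), "invalid-argument")
})

test_that("bath permeation is Hill-saturating", {
  expect_equal(bath_corrected_stimulus(0), 0)
  expect_equal(bath_corrected_stimulus(10, list(P_max = 10, K_p = 10, n_p = 1)),
               5)
  expect_equal(bath_corrected_stimulus(1e9), 20, tolerance = 1e-6)
  s <- bath_corrected_stimulus(seq(0, 50, by = 1))
  expect_true(all(diff(s) > 0))
  expect_true(all(s <= 20))
  expect_error(bath_corrected_stimulus(-1), "invalid-argument")
  expect_error(bath_corrected_stimulus(1, list(P_max = 1, K_p = 0, n_p = 1)),
               "invalid-argument")
})

test_that("no stimulus or fully blocked channels leave V at baseline", {
  tr <- simulate_mpts(81, cond = condition_params(S_max = 0), T_end = 100)
  expect_equal(tr$V_mV, rep(-75, 101), tolerance = 1e-9)
  cond <- condition_params(S_max = 10)
  cond$eta_Cl <- 0; cond$eta_Na <- 0
  tr2 <- simulate_mpts(7, core_params(g_WtoCl = 2), cond = cond, T_end = 100)
  expect_equal(tr2$V_mV, rep(-75, 101), tolerance = 1e-9)
  expect_equal(tr2$V_mV[1], -75)           # V(0) = V_K always
  expect_true(all(tr2$X >= 0 & tr2$X <= 1))
  expect_true(all(tr2$Z >= 0 & tr2$W >= 0))
})

test_that("blocker flags constrain the sign of the shift for any topology", {
  set.seed(7)
  for (i in 1:12) {
    m <- sample(1:81, 1)
    th <- core_params(g_ZtoW = runif(1, 0, 2), g_WtoCl = runif(1, 0, 2),
                      g_ZtoNa = runif(1, 0, 2), g_WtoZ = runif(1, 0, 1),
                      K_X = runif(1, 0.5, 5), K_Y = runif(1, 5, 30))
    ph <- peripheral_params(A_Cl = runif(1, 0, 20), A_Na = runif(1, 0, 20))
    dnds <- simulate_mpts(m, th, ph, condition_params(eta_Cl = 0), T_end = 150)
    expect_true(all(dnds$V_mV >= ph$V_K - 1e-8))   # DNDS: depolarizing only
    stx <- simulate_mpts(m, th, ph, condition_params(eta_Na = 0), T_end = 150)
    expect_true(all(stx$V_mV <= ph$V_K + 1e-8))    # STX: hyperpolarizing only
    kt <- simulate_mpts(m, th, ph, condition_params(pkg_active = 0),
                        T_end = 150)
    expect_true(all(kt$V_mV <= ph$V_K + 1e-8))     # KT5823: PKG arm silent
    expect_true(all(kt$W == 0))
    expect_true(all(kt$Na_act == 0))
  }
})

test_that("V_K is a pure additive bias", {
  th <- core_params(g_WtoCl = 2)
  tr1 <- simulate_mpts(7, th, peripheral_params(V_K = -75), T_end = 200)
  tr2 <- simulate_mpts(7, th, peripheral_params(V_K = -63.5), T_end = 200)
  expect_equal(tr2$V_mV, tr1$V_mV + 11.5, tolerance = 1e-9)
  s1 <- steady_state_shift(7, th, peripheral_params(V_K = -75))
  s2 <- steady_state_shift(7, th, peripheral_params(V_K = -63.5))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("zero gains reproduce the no-interaction model (nesting)", {
  set.seed(11)
  for (m in sample(2:81, 5)) {
    tr <- simulate_mpts(m, core_params(), T_end = 200)   # all gains 0
    tr1 <- simulate_mpts(1, core_params(), T_end = 200)
    expect_equal(tr$V_mV, tr1$V_mV, tolerance = 1e-6)
  }
})

test_that("tightening the integrator tolerance barely moves the output", {
  th <- core_params(g_WtoCl = 2, g_ZtoW = 1)
  a <- simulate_mpts(34, th, T_end = 600, rtol = 1e-6, atol = 1e-8)
  b <- simulate_mpts(34, th, T_end = 600, rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(a$V_mV - b$V_mV)), 1e-3)
})

test_that("M_7 with high cGMP hyperpolarizes then depolarizes", {
  th <- core_params(g_WtoCl = 2)        # K_X = 1.15 << K_Y = 16.61
  tr <- simulate_mpts(7, th, cond = condition_params(S_max = 20), T_end = 600)
  expect_lt(min(tr$V_mV[tr$time_s < 100]), -75)
  expect_gt(tr$V_mV[601], -75)
  # reference integration at much finer tolerance agrees
  ref <- simulate_mpts(7, th, cond = condition_params(S_max = 20),
                       T_end = 600, rtol = 1e-9, atol = 1e-11)
  expect_lt(max(abs(tr$V_mV - ref$V_mV)), 1e-3)
})

test_that("steady-state shift: trivial signs and dual-route agreement", {
  th <- core_params(g_WtoCl = 2)
  expect_equal(steady_state_shift(7, th, cond = condition_params(S_max = 0)), 0)
  expect_lte(steady_state_shift(7, th, cond = condition_params(eta_Na = 0)), 0)
  expect_gte(steady_state_shift(7, th, cond = condition_params(eta_Cl = 0)), 0)
  # fixed point vs long integration (independent route through the model)
  set.seed(3)
  for (i in 1:5) {
    m <- sample(1:81, 1)
    th <- core_params(g_ZtoW = runif(1, 0, 1.5), g_WtoCl = runif(1, 0, 1.5),
                      g_ZtoNa = runif(1, 0, 1.5), g_WtoZ = runif(1, 0, 0.5))
    sh <- steady_state_shift(m, th, cond = condition_params(S_max = 15))
    tr <- simulate_mpts(m, th, cond = condition_params(S_max = 15),
                        T_end = 4000, dt = 10)
    expect_equal(sh, tr$V_mV[nrow(tr)] - tr$V_mV[1], tolerance = 1e-3)
  }
})

test_that("dose-response is bidirectional for M_7 and not for M_1", {
  th <- core_params(g_WtoCl = 2)
  expect_equal(dose_response(7, th, doses = 0)$shift_mV, 0)
  doses <- c(0.1, 0.3, 1, 3, 6, 10, 20, 30)
  dr7 <- dose_response(7, th, doses = doses)
  expect_lt(dr7$shift_mV[1], 0)
  expect_lt(min(dr7$shift_mV), -1)
  expect_gt(dr7$shift_mV[length(doses)], 0)        # crossover on the grid
  # M_1 oracle: no interactions, so the fixed point is closed form
  th1 <- core_params()
  phi <- peripheral_params()
  sat <- function(u) u / (1 + u)
  hill <- function(S, K, n) ifelse(S > 0, 1 / (1 + (K / S)^n), 0)
  expected <- vapply(doses, function(d) {
    Z <- phi$A_Z * hill(d, th1$K_X, th1$n_X)
    W <- phi$A_W * hill(d, th1$K_Y, th1$n_Y)
    -phi$A_Cl * sat(Z) + phi$A_Na * sat(W)
  }, numeric(1))
  dr1 <- dose_response(1, th1, doses = doses)
  expect_equal(dr1$shift_mV, expected, tolerance = 1e-8)
  expect_true(all(dr1$shift_mV <= 0))  # ClC arm dominates at every dose here
})
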