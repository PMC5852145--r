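#' Gaussian log likelihood of one series
#'
#' Under the observation model `V_i(t) ~ Normal(Vhat(t), sigma_i)` the log
#' likelihood of a series is
#' `-T_i log(sqrt(2 pi) sigma_i) - sum_t dV_i(t)^2 / (2 sigma_i^2)`,
#' with `dV_i(t) = V_i(t) - Vhat(t)`.  Each series is standardized by its
#' own noise level `sigma_i` estimated during preprocessing.
#'
#' @param series `mp_series` with `sigma` set.
#' @param vhat model potential on the same grid (numeric vector or an
#'   `mp_trajectory`, whose `V_mV` column is used).
#' @return Scalar log likelihood.
#' @export
log_likelihood_series <- function(series, vhat) {
  if (inherits(vhat, "mp_trajectory")) vhat <- vhat$V_mV
  if (is.na(series$sigma) || series$sigma <= 0)
    stop("invalid-input: series sigma must be positive (run estimate_noise_sd)")
  if (length(vhat) < length(series$values))
    stop("invalid-input: trajectory does not cover the series grid")
  .loglik_series_cpp(series$values, vhat[seq_along(series$values)],
                     series$sigma)
}

#' Total log likelihood of a dataset under one topology
#'
#' Product over series of the per-series Gaussian likelihoods, in logs:
#' each series is simulated under its own condition and peripheral
#' parameters, with the shared core parameters.
#'
#' @param dataset `mp_dataset` (all series need `sigma`).
#' @param topology `model_topology` or index.
#' @param theta `core_params`.
#' @param phi_list list of `peripheral_params`, one per series.
#' @param rtol,atol integrator tolerances.
#' @return Scalar log likelihood (0 for an empty dataset).
#' @export
total_log_likelihood <- function(dataset, topology, theta, phi_list,
                                 rtol = 1e-6, atol = 1e-8) {
  n <- length(dataset)
  if (n == 0) return(0)
  if (length(phi_list) != n)
    stop("invalid-input: need one peripheral parameter set per series")
  topology <- as_topology(topology)
  codes <- topology_codes(topology)
  thv <- theta_vec(theta)
  ll <- 0
  for (i in seq_len(n)) {
    s <- dataset$series[[i]]
    vhat <- sim_vhat(codes, thv, phi_vec(phi_list[[i]]),
                     cond_vec(s$condition), seq_along(s$values) - 1,
                     rtol, atol)
    ll <- ll + log_likelihood_series(s, vhat)
  }
  ll
}

# Closure used by the samplers/optimizers: precomputes per-series static
# data and returns f(par, idx) -> per-series log likelihoods for the series
# in idx (default all).  `par` is a flat named vector under `layout`.
#
# With `vk_marginal = TRUE` the per-series baseline V_K (which enters the
# model potential purely additively and carries an untruncated normal
# prior) is integrated out in closed form: writing r_t = V_t - g_t with
# g_t the simulated potential at V_K = 0, and V_K ~ N(m0, s0),
#   ln p(V_i | rest) = -(T/2) ln(2 pi sigma^2) + (1/2) ln(2 pi sigma^2 / T)
#                      - SS_res / (2 sigma^2)
#                      + ln N(rbar | m0, sqrt(s0^2 + sigma^2 / T)).
# This Rao-Blackwellization leaves the evidence integral unchanged while
# removing the stiffest coordinate of every peripheral block.
make_loglik <- function(dataset, topology, layout, rtol = 1e-6, atol = 1e-8,
                        vk_marginal = FALSE, vk_prior = NULL) {
  topology <- as_topology(topology)
  codes <- topology_codes(topology)
  n <- length(dataset)
  vals <- lapply(dataset$series, `[[`, "values")
  sig <- vapply(dataset$series, `[[`, numeric(1), "sigma")
  if (n > 0 && any(is.na(sig) | sig <= 0))
    stop("invalid-input: all series need positive sigma")
  conds <- lapply(dataset$series, function(s) cond_vec(s$condition))
  times <- lapply(vals, function(v) seq_along(v) - 1)
  core_nm <- layout$name[layout$block == 0L]
  gain_nm <- intersect(c("g_ZtoW", "g_WtoCl", "g_ZtoNa", "g_WtoZ"), core_nm)
  phi_nm <- lapply(seq_len(n), function(i) paste0(PERIPHERAL_FIELDS, ".", i))

  if (vk_marginal && is.null(vk_prior))
    stop("configuration-error: vk_marginal needs the V_K prior")

  function(par, idx = seq_len(n)) {
    thv <- c(par[["K_X"]], par[["n_X"]], par[["K_Y"]], par[["n_Y"]],
             par[["k_Z"]], par[["k_W"]], 0, 0, 0, 0)
    if (length(gain_nm)) {
      pos <- match(gain_nm, c("g_ZtoW", "g_WtoCl", "g_ZtoNa", "g_WtoZ")) + 6L
      thv[pos] <- par[gain_nm]
    }
    out <- numeric(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      phv <- unname(par[phi_nm[[i]]])
      if (vk_marginal) phv[1] <- 0
      vhat <- tryCatch(
        sim_vhat(codes, thv, phv, conds[[i]], times[[i]], rtol, atol),
        error = function(e) NULL)
      if (is.null(vhat) || anyNA(vhat)) {
        out[k] <- -Inf
      } else if (vk_marginal) {
        r <- vals[[i]] - vhat
        Ti <- length(r)
        rbar <- mean(r)
        ss_res <- sum((r - rbar)^2)
        s2 <- sig[[i]]^2
        out[k] <- -(Ti / 2) * log(2 * pi * s2) +
          0.5 * log(2 * pi * s2 / Ti) - ss_res / (2 * s2) +
          dnorm(rbar, vk_prior$mu, sqrt(vk_prior$sigma^2 + s2 / Ti),
                log = TRUE)
      } else {
        out[k] <- .loglik_series_cpp(vals[[i]], vhat, sig[[i]])
      }
    }
    out
  }
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2 k - 2 lnL_max`, `BIC = k ln(n) - 2 lnL_max`.
#'
#' @param log_lik_max maximized log likelihood, or a `fit_result` (its
#'   `log_likelihood` is used).
#' @param k_params number of free parameters, `>= 0`.
#' @param n_points number of data points, `>= 1`.
#' @return Named numeric vector `c(AIC = , BIC = )`.
#' @export
information_criteria <- function(log_lik_max, k_params, n_points) {
  if (inherits(log_lik_max, "fit_result"))
    log_lik_max <- log_lik_max$log_likelihood
  stopifnot(k_params >= 0, n_points >= 1)
  c(AIC = 2 * k_params - 2 * log_lik_max,
    BIC = k_params * log(n_points) - 2 * log_lik_max)
}
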