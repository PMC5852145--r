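#' Optimizer configuration for fast (non-MCMC) fitting
#'
#' @param n_starts number of starts (first start is the deterministic
#'   prior-mean initialization, further starts are seeded prior draws).
#' @param rounds maximum alternating rounds (peripherals given core, core
#'   given peripherals).
#' @param reltol stop when a round improves the log likelihood by less.
#' @param maxit iteration cap per inner `optim` call.
#' @param seed integer seed (determinism contract).
#' @return List of class `opt_config`.
#' @export
opt_config <- function(n_starts = 3, rounds = 6, reltol = 1e-3, maxit = 100,
                       seed = 1) {
  structure(list(n_starts = n_starts, rounds = rounds, reltol = reltol,
                 maxit = maxit, seed = seed), class = "opt_config")
}

# Finite optimizer bounds from the prior supports.
opt_bounds <- function(layout) {
  mu <- layout$mu
  h <- !is.na(layout$hyper)
  mu[h] <- layout$mu[match(layout$hyper[h], layout$name)]
  lo <- ifelse(is.finite(layout$lower), layout$lower, mu - 8 * layout$sigma)
  hi <- pmax(mu, layout$lower) + 8 * layout$sigma
  list(lower = lo, upper = hi)
}

# Data-driven peripheral initialization for one series.
phi_init_series <- function(values, par, i) {
  v0 <- median(values[seq_len(min(10, length(values)))])
  c(setNames(v0, paste0("V_K.", i)),
    setNames(30, paste0("tau_S.", i)),
    setNames(unname(par["A_Cl0"]), paste0("A_Cl.", i)),
    setNames(unname(par["A_Na0"]), paste0("A_Na.", i)),
    setNames(unname(par["A_Z0"]), paste0("A_Z.", i)),
    setNames(unname(par["A_W0"]), paste0("A_W.", i)))
}

neg_wrap <- function(f) function(x) {
  v <- f(x)
  if (!is.finite(v)) 1e10 else -v
}

#' Maximize the total log likelihood of a topology on a dataset
#'
#' Multi-start bounded local optimization over the joint
#' `(theta, phi_1, ..., phi_I)` space, with bounds taken from the priors'
#' supports.  Each start alternates per-series peripheral fits (6-d
#' L-BFGS-B, core frozen) with a core fit (peripherals frozen) until the
#' log likelihood stops improving; the best start wins.  Deterministic
#' given the seed.
#'
#' @inheritParams sample_posterior
#' @param config `opt_config`.
#' @param fixed optional named vector of parameters held fixed (e.g. a
#'   frozen core for specificity testing).
#' @return List of class `fit_result`: `topology`, `theta`, `phi`,
#'   `log_likelihood`, `par`, `per_series_loglik`, `diagnostics`.
#' @export
maximize_log_likelihood <- function(dataset, topology,
                                    priors = default_priors(),
                                    config = opt_config(), fixed = NULL) {
  if (length(dataset) == 0) stop("invalid-input: dataset is empty")
  topology <- as_topology(topology)
  layout <- param_layout(topology, length(dataset), priors)
  loglik_fn <- make_loglik(dataset, topology, layout)
  bounds <- opt_bounds(layout)
  n <- length(dataset)
  free <- rep(TRUE, nrow(layout))
  template <- default_init(layout)
  if (!is.null(fixed)) {
    stopifnot(all(names(fixed) %in% layout$name))
    template[names(fixed)] <- pmin(pmax(fixed, bounds$lower[match(names(fixed), layout$name)]),
                                   bounds$upper[match(names(fixed), layout$name)])
    free[layout$name %in% names(fixed)] <- FALSE
  }
  core_idx <- which(free & layout$block == 0L)
  phi_idx <- lapply(seq_len(n), function(i) which(free & layout$block == i))

  set.seed(config$seed)
  starts <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    par <- if (s == 1) template else {
      p <- sample_prior_free(layout, free, template)
      p
    }
    par[!free] <- template[!free]
    for (i in seq_len(n)) {
      ini <- phi_init_series(dataset$series[[i]]$values, par, i)
      ini <- ini[names(ini) %in% layout$name[free]]
      par[names(ini)] <- pmin(pmax(ini, bounds$lower[match(names(ini), layout$name)]),
                              bounds$upper[match(names(ini), layout$name)])
    }
    starts[[s]] <- par
  }

  best <- NULL
  for (par in starts) {
    ll_old <- -Inf
    for (r in seq_len(config$rounds)) {
      for (i in seq_len(n)) {                      # peripheral sweeps
        idx <- phi_idx[[i]]
        if (length(idx) == 0) next
        fn <- function(x) { par[idx] <- x; loglik_fn(par, i) }
        o <- optim(par[idx], neg_wrap(fn), method = "L-BFGS-B",
                   lower = bounds$lower[idx], upper = bounds$upper[idx],
                   control = list(maxit = config$maxit,
                                  parscale = layout$sigma[idx]))
        par[idx] <- o$par
      }
      if (length(core_idx)) {                      # core sweep
        fn <- function(x) { par[core_idx] <- x; sum(loglik_fn(par)) }
        o <- optim(par[core_idx], neg_wrap(fn), method = "L-BFGS-B",
                   lower = bounds$lower[core_idx],
                   upper = bounds$upper[core_idx],
                   control = list(maxit = config$maxit,
                                  parscale = layout$sigma[core_idx]))
        par[core_idx] <- o$par
      }
      ll_new <- sum(loglik_fn(par))
      if (ll_new - ll_old < config$reltol) { ll_old <- max(ll_new, ll_old); break }
      ll_old <- ll_new
    }
    if (is.null(best) || ll_old > best$ll) best <- list(par = par, ll = ll_old)
  }
  if (is.null(best) || !is.finite(best$ll))
    stop("optimization-failure: no start converged to a finite likelihood")

  par <- best$par
  structure(list(
    topology = topology$index,
    theta = theta_from_par(par, layout),
    phi = lapply(seq_len(n), function(i) phi_from_par(par, layout, i)),
    log_likelihood = best$ll,
    per_series_loglik = loglik_fn(par),
    par = par, layout = layout,
    diagnostics = list(seed = config$seed, n_starts = config$n_starts,
                       rounds = config$rounds)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result M_%d: lnL = %.2f (%d series)\n",
              x$topology, x$log_likelihood, length(x$phi)))
  invisible(x)
}

# Fit the peripherals of a single series with the core frozen; returns the
# flat peripheral vector (unsuffixed names) and the achieved log likelihood.
fit_phi_series <- function(series, topology, theta,
                           priors = default_priors(),
                           config = opt_config(n_starts = 1), n_points = NULL) {
  vals <- series$values
  if (!is.null(n_points)) {
    s2 <- series
    s2$values <- vals[seq_len(n_points)]
    series <- s2
  }
  ds <- mp_dataset(list(series))
  layout <- param_layout(topology, 1, priors)
  thn <- layout$name[layout$block == 0L]
  fixed <- vapply(thn, function(k) theta[[k]], numeric(1))
  names(fixed) <- thn
  fit <- maximize_log_likelihood(ds, topology, priors, config, fixed = fixed)
  list(phi = fit$phi[[1]], log_likelihood = fit$log_likelihood)
}
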