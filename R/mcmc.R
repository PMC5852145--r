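#' MCMC configuration
#'
#' @param n_steps post-burn-in sweeps to keep (one sweep = one update of
#'   the core block plus one update of every peripheral block).
#' @param burn_in sweeps discarded; proposal scales are adapted (toward
#'   20-40 percent acceptance) during burn-in only, then frozen so detailed
#'   balance holds for the kept draws.
#' @param adapt adapt proposal scales during burn-in.
#' @param seed integer seed; identical seed + config gives identical chains.
#' @param thin keep every `thin`-th sweep.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_steps = 2000, burn_in = 500, adapt = TRUE,
                        seed = 1, thin = 1) {
  structure(list(n_steps = n_steps, burn_in = burn_in, adapt = adapt,
                 seed = seed, thin = thin), class = "mcmc_config")
}

# Names whose prior terms enter the target: the free parameters plus any
# fixed hierarchical children of a free population mean.
target_prior_names <- function(layout, free) {
  free_nm <- layout$name[free]
  union(free_nm, layout$name[!is.na(layout$hyper) & layout$hyper %in% free_nm])
}

# Blocked random-walk Metropolis over the joint (theta, phi_1..phi_n) space
# at inverse temperature beta (target: prior x likelihood^beta).  Proposals
# are reflected at the truncation bounds.  Returns kept parameter draws,
# the per-sweep total log likelihood, final state and acceptance rates.
mh_blocks <- function(loglik_fn, layout, free, init, beta, cfg,
                      scales = NULL, store_pars = TRUE) {
  n_series <- max(layout$block)
  free_idx <- which(free)
  if (length(free_idx) == 0) stop("invalid-input: no free parameters")
  # one block per layout block that contains free parameters
  blocks <- lapply(0:n_series, function(b) which(free & layout$block == b))
  affected <- lapply(0:n_series, function(b)
    if (b == 0L) seq_len(max(n_series, 1L)) else b)
  keep <- lengths(blocks) > 0
  blocks <- blocks[keep]; affected <- affected[keep]
  prior_nm <- target_prior_names(layout, free)

  par <- pmax(init[layout$name], layout$lower)  # guard fp dust below a bound
  names(par) <- layout$name
  ll <- loglik_fn(par)                      # per-series vector
  lp <- log_prior_density(par, layout, prior_nm)
  if (!is.finite(lp)) stop("invalid-input: initial state has zero prior density")
  if (is.null(scales)) scales <- pmax(0.1 * layout$sigma, 1e-4)
  log_mult <- numeric(length(blocks))       # per-block adaptive multiplier
  acc <- int <- numeric(length(blocks))
  # running moments for per-coordinate scale adaptation during burn-in
  rn <- 0; rmean <- par; rM2 <- numeric(length(par))

  n_keep <- ceiling(cfg$n_steps / cfg$thin)
  draws <- if (store_pars)
    matrix(NA_real_, n_keep, length(free_idx),
           dimnames = list(NULL, layout$name[free_idx]))
  ll_draws <- numeric(n_keep)
  kept <- 0L
  total <- cfg$burn_in + cfg$n_steps

  for (s in seq_len(total)) {
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      par2 <- par
      step <- exp(log_mult[b]) * scales[idx] * rnorm(length(idx))
      x <- par2[idx] + step
      lo <- layout$lower[idx]
      refl <- is.finite(lo) & x < lo
      x[refl] <- 2 * lo[refl] - x[refl]
      par2[idx] <- x
      lp2 <- log_prior_density(par2, layout, prior_nm)
      int[b] <- int[b] + 1
      if (is.finite(lp2)) {
        ll2 <- loglik_fn(par2, affected[[b]])
        la <- beta * (sum(ll2) - sum(ll[affected[[b]]])) + lp2 - lp
        if (is.finite(la) && log(runif(1)) < la) {
          par <- par2
          ll[affected[[b]]] <- ll2
          lp <- lp2
          acc[b] <- acc[b] + 1
        }
      }
    }
    if (cfg$adapt && s <= cfg$burn_in) {
      rn <- rn + 1
      d <- par - rmean
      rmean <- rmean + d / rn
      rM2 <- rM2 + d * (par - rmean)
      if (s %% 25 == 0) {
        rate <- acc / pmax(int, 1)
        log_mult <- log_mult + 0.6 * (rate - 0.3)
        acc[] <- int[] <- 0
        if (rn > 50) {   # per-coordinate scales from the chain's own spread
          sd_est <- sqrt(rM2 / (rn - 1))
          for (b in seq_along(blocks)) {
            idx <- blocks[[b]]
            tgt <- 2.4 / sqrt(length(idx)) *
              pmax(sd_est[idx], 0.02 * layout$sigma[idx])
            scales[idx] <- pmin(pmax(tgt, 1e-5), 10 * layout$sigma[idx])
          }
        }
      }
    }
    if (s > cfg$burn_in && (s - cfg$burn_in) %% cfg$thin == 0) {
      kept <- kept + 1L
      if (store_pars) draws[kept, ] <- par[free_idx]
      ll_draws[kept] <- sum(ll)
    }
  }
  rate <- acc / pmax(int, 1)
  if (cfg$n_steps > 0 && all(rate < 0.01))
    warning("diagnostics-error: acceptance rate below 1% in every block")
  list(draws = if (store_pars) draws[seq_len(kept), , drop = FALSE],
       loglik = ll_draws[seq_len(kept)], final = par, final_ll = ll,
       acceptance = rate, scales = scales * exp(mean(log_mult)),
       log_mult = log_mult)
}

#' Sample the joint posterior of core and peripheral parameters
#'
#' Random-walk Metropolis over the joint `(theta, phi_1, ..., phi_I)` space
#' targeting prior x likelihood, updated in blocks (core, then each
#' series' peripherals).  Proposals are reflected at truncation bounds;
#' block step scales are adapted during burn-in only.
#'
#' @param dataset `mp_dataset` with per-series `sigma` set.
#' @param topology `model_topology` or index.
#' @param priors `prior_set`.
#' @param config `mcmc_config`.
#' @param fixed optional named numeric vector of parameters to hold fixed
#'   (removed from the sampled space).
#' @param init optional named starting vector (defaults to prior means,
#'   with zero-peaked gains started at half a prior s.d.).
#' @return List of class `posterior_chain`: `draws` (matrix, one column per
#'   free parameter), `loglik`, `layout`, `acceptance`, `config`.
#' @export
sample_posterior <- function(dataset, topology, priors = default_priors(),
                             config = mcmc_config(), fixed = NULL,
                             init = NULL) {
  if (length(dataset) == 0) stop("invalid-input: dataset is empty")
  layout <- param_layout(topology, length(dataset), priors)
  loglik_fn <- make_loglik(dataset, topology, layout)
  set.seed(config$seed)
  par0 <- data_informed_init(dataset, layout)
  if (!is.null(init)) par0[names(init)] <- init
  free <- rep(TRUE, nrow(layout))
  if (!is.null(fixed)) {
    stopifnot(all(names(fixed) %in% layout$name))
    par0[names(fixed)] <- fixed
    free[layout$name %in% names(fixed)] <- FALSE
  }
  res <- mh_blocks(loglik_fn, layout, free, par0, beta = 1, cfg = config)
  structure(list(draws = res$draws, loglik = res$loglik, layout = layout,
                 acceptance = res$acceptance, config = config,
                 topology = as_topology(topology)$index),
            class = "posterior_chain")
}

# Deterministic starting point: prior means, but zero-peaked parameters a
# little inside the support and hierarchical means resolved.
default_init <- function(layout) {
  par <- layout$mu
  zerop <- layout$mu == layout$lower
  par[zerop] <- layout$lower[zerop] + 0.5 * layout$sigma[zerop]
  names(par) <- layout$name
  h <- !is.na(layout$hyper)
  par[h] <- par[layout$hyper[h]]
  par
}

#' Posterior-mean ("mean a posteriori") estimate from a chain
#'
#' The representative point estimate of this framework is the posterior
#' mean of each parameter (the study's "MAP" is defined as mean a
#' posteriori, not the mode).
#'
#' @param chain `posterior_chain` (or a draws matrix).
#' @return List with `theta` (`core_params`), `phi` (list of
#'   `peripheral_params`) and `par` (the flat named mean vector), or the
#'   column means when given a bare matrix.
#' @export
posterior_mean_estimate <- function(chain) {
  if (is.matrix(chain)) {
    if (nrow(chain) == 0) stop("invalid-input: empty chain")
    return(colMeans(chain))
  }
  if (nrow(chain$draws) == 0) stop("invalid-input: empty chain")
  m <- colMeans(chain$draws)
  layout <- chain$layout
  par <- default_init(layout)
  par[names(m)] <- m
  list(theta = theta_from_par(par, layout),
       phi = lapply(seq_len(max(layout$block)),
                    function(i) phi_from_par(par, layout, i)),
       par = par)
}
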