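#' Left-truncated normal prior
#'
#' The workhorse prior of the framework: a Gaussian restricted to
#' `[lower, Inf)`.  Interaction gains use the zero-peaked form
#' (`mu = lower = 0`), whose density peaks at zero so that a complex model
#' can cut off unnecessary pathways by sending the corresponding gains to
#' zero — the property that makes nested model comparison by evidence
#' meaningful.  `lower = -Inf` gives an untruncated normal (used for `V_K`).
#'
#' @param mu,sigma location and scale (in the parameter's units); `sigma > 0`.
#' @param lower truncation bound (default 0).
#' @return Object of class `tnorm_prior`.
#' @export
truncated_normal_prior <- function(mu, sigma, lower = 0) {
  if (sigma <= 0) stop("invalid-argument: prior sigma must be positive")
  structure(list(mu = mu, sigma = sigma, lower = lower),
            class = "tnorm_prior")
}

#' @export
print.tnorm_prior <- function(x, ...) {
  cat(sprintf("TruncNorm(mu = %g, sigma = %g, lower = %g)\n",
              x$mu, x$sigma, x$lower))
  invisible(x)
}

# log density / sampler / quantile of the truncated normal (vectorised in x).
dtnorm_log <- function(x, mu, sigma, lower) {
  out <- dnorm(x, mu, sigma, log = TRUE) -
    pnorm(lower, mu, sigma, lower.tail = FALSE, log.p = TRUE)
  out[x < lower] <- -Inf
  out
}
rtnorm <- function(n, mu, sigma, lower) {
  if (n == 0) return(numeric(0))
  lower <- rep_len(lower, n)
  plo <- ifelse(is.finite(lower), pnorm(lower, mu, sigma), 0)
  qnorm(plo + runif(n) * (1 - plo), mu, sigma)
}

#' Default prior table
#'
#' One `tnorm_prior` per estimable parameter, keyed by field name.  Gains
#' are zero-peaked half-normals; the Hill coefficients are centered at the
#' cGMP binding-site counts of the effectors (4 for CNGC, 2 for PKG) with
#' lower bound 1; affinities get broad half-normal scales (10 uM for the
#' high-affinity CNGC arm, 30 uM for the low-affinity PKG arm); `V_K` is an
#' untruncated normal around the resting potential.  The peripheral
#' amplitudes `A_Cl`, `A_Na`, `A_Z`, `A_W` are hierarchical: their prior
#' means are the core-level population means `A_Cl0`, `A_Na0`, `A_Z0`,
#' `A_W0` (the `mu` stored here is ignored for them at evaluation time).
#'
#' @param ... named `tnorm_prior` overrides.
#' @return Named list of priors (class `prior_set`).
#' @export
default_priors <- function(...) {
  tn <- truncated_normal_prior
  p <- list(
    K_X    = tn(0, 10, 0),
    n_X    = tn(4, 1, 1),
    K_Y    = tn(0, 30, 0),
    n_Y    = tn(2, 1, 1),
    k_Z    = tn(0.1, 0.1, 0.001),
    k_W    = tn(0.01, 0.03, 0.001),
    g_ZtoW = tn(0, 1, 0),
    g_WtoCl = tn(0, 1, 0),
    g_ZtoNa = tn(0, 1, 0),
    g_WtoZ = tn(0, 1, 0),
    A_Cl0  = tn(10, 5, 0),
    A_Na0  = tn(10, 5, 0),
    A_Z0   = tn(1, 0.5, 0),
    A_W0   = tn(1, 0.5, 0),
    V_K    = tn(-75, 10, -Inf),
    tau_S  = tn(30, 20, 1),
    A_Cl   = tn(10, 5, 0),
    A_Na   = tn(10, 5, 0),
    A_Z    = tn(1, 0.5, 0),
    A_W    = tn(1, 0.5, 0)
  )
  dots <- list(...)
  if (length(dots)) {
    stopifnot(all(vapply(dots, inherits, logical(1), "tnorm_prior")))
    p <- modifyList(p, dots)
  }
  structure(p, class = c("prior_set", "list"))
}

# Peripheral fields whose prior mean is a core-level hyperparameter.
HIER_MAP <- c(A_Cl = "A_Cl0", A_Na = "A_Na0", A_Z = "A_Z0", A_W = "A_W0")

#' Parameter layout of a model on a dataset
#'
#' Builds the flat parameter vector description for joint inference: the
#' core block (kinetics, Hill constants, the gains of the topology's active
#' pathways, population means) followed by one peripheral block
#' (`V_K, tau_S, A_Cl, A_Na, A_Z, A_W`) per series, named `<field>.<i>`.
#'
#' @param topology `model_topology` (or index).
#' @param n_series number of series in the dataset.
#' @param priors `prior_set`.
#' @return Data frame with columns `name`, `base`, `series`, `block`
#'   (0 = core), `mu`, `sigma`, `lower`, `hyper` (NA or the name of the
#'   core mean the prior is centered on).
#' @export
param_layout <- function(topology, n_series, priors = default_priors()) {
  topology <- as_topology(topology)
  gains <- c("g_ZtoW", "g_WtoCl", "g_ZtoNa", "g_WtoZ")[
    topology_codes(topology) != 0L]
  core <- c("K_X", "n_X", "K_Y", "n_Y", "k_Z", "k_W", gains,
            "A_Cl0", "A_Na0", "A_Z0", "A_W0")
  base <- c(core, rep(PERIPHERAL_FIELDS, n_series))
  series <- c(rep(NA_integer_, length(core)),
              rep(seq_len(n_series), each = length(PERIPHERAL_FIELDS)))
  name <- ifelse(is.na(series), base, paste0(base, ".", series))
  missing <- setdiff(unique(base), names(priors))
  if (length(missing))
    stop("configuration-error: no prior for parameter(s): ",
         paste(missing, collapse = ", "))
  pr <- priors[base]
  layout <- data.frame(
    name = name, base = base, series = series,
    block = ifelse(is.na(series), 0L, series),
    mu = vapply(pr, `[[`, numeric(1), "mu"),
    sigma = vapply(pr, `[[`, numeric(1), "sigma"),
    lower = vapply(pr, `[[`, numeric(1), "lower"),
    hyper = ifelse(base %in% names(HIER_MAP) & !is.na(series),
                   HIER_MAP[base], NA_character_),
    stringsAsFactors = FALSE)
  # hierarchical means only apply when the hyperparameter is in the vector
  layout$hyper[!layout$hyper %in% name] <- NA_character_
  rownames(layout) <- layout$name
  layout
}

# Effective prior means given the current vector (resolves the hierarchy).
layout_mu <- function(par, layout) {
  mu <- layout$mu
  h <- !is.na(layout$hyper)
  mu[h] <- par[layout$hyper[h]]
  mu
}

#' Log prior density of a parameter vector
#'
#' Sum of per-parameter log truncated-normal densities under a layout;
#' the hierarchical peripheral amplitudes are evaluated at prior means
#' equal to the current values of their population-mean hyperparameters.
#' Returns `-Inf` below any truncation bound.
#'
#' @param par named numeric vector matching `layout$name`.
#' @param layout from [param_layout()].
#' @param subset optional character vector of names to restrict the sum to
#'   (used when some parameters are held fixed).
#' @return Scalar log density.
#' @export
log_prior_density <- function(par, layout, subset = NULL) {
  mu <- layout_mu(par, layout)
  x <- par[layout$name]
  ld <- dtnorm_log(x, mu, layout$sigma, layout$lower)
  if (!is.null(subset)) ld <- ld[layout$name %in% subset]
  sum(ld)
}

# Draw one parameter vector from the prior (core first, then hierarchical
# peripherals conditioned on the sampled population means).
sample_prior_vec <- function(layout) {
  par <- numeric(nrow(layout))
  names(par) <- layout$name
  core <- layout$block == 0L
  par[core] <- rtnorm(sum(core), layout$mu[core], layout$sigma[core],
                      layout$lower[core])
  per <- which(!core)
  mu <- layout$mu
  h <- !is.na(layout$hyper)
  mu[h] <- par[layout$hyper[h]]
  par[per] <- rtnorm(length(per), mu[per], layout$sigma[per],
                     layout$lower[per])
  par
}

# Assemble core_params / peripheral_params from a flat named vector.
theta_from_par <- function(par, layout) {
  th <- core_params()
  nm <- layout$name[layout$block == 0L]
  for (k in nm) th[[k]] <- unname(par[[k]])
  # gains of inactive pathways stay at 0 (nesting)
  th
}
phi_from_par <- function(par, layout, i) {
  nm <- layout$name[layout$block == i]
  ph <- peripheral_params()
  for (k in layout$base[layout$block == i]) ph[[k]] <- unname(par[[paste0(k, ".", i)]])
  ph
}
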