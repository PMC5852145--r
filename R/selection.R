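#' 9x9 matrix cell of a topology
#'
#' Layout convention of the evidence matrix: rows enumerate
#' `(s_ZtoW, s_ZtoNa)` (`row = 1 + s_ZtoW + 3 s_ZtoNa`), columns enumerate
#' `(s_WtoZ, s_WtoCl)` with `s_WtoCl` major (`col = 1 + s_WtoZ +
#' 3 s_WtoCl`), signs ordered NONE < ACTIVATION < INHIBITION.  Group b
#' (`s_WtoCl = INHIBITION`) therefore occupies the right-hand three
#' columns.
#'
#' @param topology `model_topology` or index.
#' @return Integer vector `c(row, col)`.
#' @export
matrix_cell <- function(topology) {
  tp <- as_topology(topology)
  c(row = 1L + tp$s_ZtoW + 3L * tp$s_ZtoNa,
    col = 1L + tp$s_WtoZ + 3L * tp$s_WtoCl)
}

#' Arrange per-topology values as the 9x9 model matrix
#'
#' @param values numeric vector indexed by model index (length 81, NAs
#'   allowed for unevaluated cells).
#' @return 9x9 matrix following the [matrix_cell()] convention.
#' @export
model_matrix_grid <- function(values) {
  stopifnot(length(values) == 81)
  g <- matrix(NA_real_, 9, 9)
  for (m in 1:81) {
    cell <- matrix_cell(m)
    g[cell[1], cell[2]] <- values[m]
  }
  g
}

#' Split the models into evidence groups a and b
#'
#' Group b: the 27 topologies containing PKG-DF -| ClC inhibition (the
#' right three columns of the matrix, minimal member M_7); group a: the
#' remaining 54 (minimal member M_1).
#'
#' @param indices model indices to split (default all 81).
#' @return List with integer vectors `group_a` and `group_b`.
#' @export
split_model_groups <- function(indices = 1:81) {
  b <- vapply(indices, function(m) in_group_b(topology_from_index(m)),
              logical(1))
  list(group_a = indices[!b], group_b = indices[b])
}

#' Evidence matrix over candidate topologies
#'
#' Runs [estimate_log_evidence()] per topology (all 81 or a stated subset)
#' and arranges the results on the 9x9 grid.  Per-cell failures are
#' recorded without aborting the remaining cells.
#'
#' @param dataset `mp_dataset`.
#' @param priors `prior_set`.
#' @param config `evidence_config` (each cell gets a seed derived from
#'   `config$seed` + model index).
#' @param model_subset integer indices (default all 81).
#' @return List of class `evidence_matrix`: `table` (data frame with
#'   `model_index`, `signs`, `log_evidence`, `mc_se`, `group`, `row`,
#'   `col`), `grid` (9x9 matrix), `errors`.
#' @export
evidence_matrix <- function(dataset, priors = default_priors(),
                            config = evidence_config(),
                            model_subset = 1:81) {
  if (length(dataset) == 0) stop("invalid-input: dataset is empty")
  stopifnot(!anyDuplicated(model_subset), all(model_subset %in% 1:81))
  vals <- rep(NA_real_, 81)
  ses <- rep(NA_real_, 81)
  errors <- list()
  for (m in model_subset) {
    cfg <- config
    cfg$seed <- config$seed + m
    res <- tryCatch(estimate_log_evidence(dataset, m, priors, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(m)]] <- conditionMessage(res)
    } else {
      vals[m] <- res$log_evidence
      ses[m] <- res$mc_se
    }
  }
  cells <- t(vapply(1:81, matrix_cell, integer(2)))
  groups <- split_model_groups()
  tab <- data.frame(
    model_index = 1:81,
    signs = vapply(1:81, function(m) topology_signs(topology_from_index(m)),
                   character(1)),
    log_evidence = vals, mc_se = ses,
    group = ifelse(1:81 %in% groups$group_b, "b", "a"),
    row = cells[, 1], col = cells[, 2])
  structure(list(table = tab, grid = model_matrix_grid(vals),
                 errors = errors, config = config),
            class = "evidence_matrix")
}

#' Group-contrast statistic of a per-model fitness (or evidence) vector
#'
#' `mean(values over group b) - mean(values over group a)`, the scalar
#' surrogate for the visual two-block structure of the model matrices.
#' Only models present (non-NA) enter the means.
#'
#' @param values numeric vector indexed by model index (length 81, NAs for
#'   unevaluated models).
#' @return Scalar contrast.
#' @export
group_contrast <- function(values) {
  stopifnot(length(values) == 81)
  g <- split_model_groups()
  mean(values[g$group_b], na.rm = TRUE) - mean(values[g$group_a], na.rm = TRUE)
}

#' Leave-one-out cross-validation of the core system
#'
#' For each fold i the core parameters are trained on all series but i
#' (giving `theta_i`), the peripherals of series i are then fit with that
#' core frozen, and the held-out fitness is the series' log likelihood
#' averaged over its data points.  Repeating over all I series yields I
#' core-parameter sets.
#'
#' @inheritParams sample_posterior
#' @param fit_mode `"fast_optimize"` (multi-start bounded optimization,
#'   the desk-scale default) or `"mcmc"` (posterior means from
#'   [sample_posterior()]).
#' @param config `opt_config` or `mcmc_config` matching `fit_mode`.
#' @return List of class `loo_result`: `theta` (list of I `core_params`),
#'   `phi` (list of I `peripheral_params`), `heldout_fitness` (per-point
#'   log likelihood per fold), `folds`.
#' @export
loo_cross_validate <- function(dataset, topology,
                               priors = default_priors(),
                               fit_mode = c("fast_optimize", "mcmc"),
                               config = NULL) {
  fit_mode <- match.arg(fit_mode)
  n <- length(dataset)
  if (n < 2) stop("invalid-input: LOO needs at least 2 series")
  if (is.null(config))
    config <- if (fit_mode == "fast_optimize") opt_config() else mcmc_config()
  thetas <- vector("list", n)
  phis <- vector("list", n)
  fitness <- numeric(n)
  for (i in seq_len(n)) {
    train <- dataset[-i]
    cfg <- config
    cfg$seed <- config$seed + i          # fold-local seed: no state leakage
    theta_i <- if (fit_mode == "fast_optimize") {
      maximize_log_likelihood(train, topology, priors, cfg)$theta
    } else {
      posterior_mean_estimate(sample_posterior(train, topology, priors, cfg))$theta
    }
    held <- dataset$series[[i]]
    pf <- fit_phi_series(held, topology, theta_i, priors)
    thetas[[i]] <- theta_i
    phis[[i]] <- pf$phi
    fitness[i] <- pf$log_likelihood / length(held$values)
  }
  structure(list(theta = thetas, phi = phis, heldout_fitness = fitness,
                 folds = n, topology = as_topology(topology)$index,
                 fit_mode = fit_mode),
            class = "loo_result")
}

#' Randomly permute the condition labels of a dataset
#'
#' Permutes the (label, blocker-flag) assignment across series uniformly at
#' random without replacement — counts are preserved, series values are
#' untouched.  Used for the label-shuffling specificity test.
#'
#' @param dataset `mp_dataset`.
#' @param seed integer seed.
#' @return `mp_dataset` with permuted conditions.
#' @export
shuffle_condition_labels <- function(dataset, seed = 1) {
  set.seed(seed)
  n <- length(dataset)
  perm <- sample.int(n)
  series <- dataset$series
  out <- lapply(seq_len(n), function(i) {
    s <- series[[i]]
    s$condition_label <- series[[perm[i]]]$condition_label
    s$condition <- series[[perm[i]]]$condition
    s
  })
  mp_dataset(out)
}

#' Per-topology fitness of a test dataset under a frozen core
#'
#' Specificity test: with the core parameters fixed (e.g. the posterior
#' mean / maximum-likelihood core trained on the 10 uM identification
#' data), only each test series' peripherals are refit, and the fitness of
#' every candidate topology is the total log likelihood per data point.
#' Gains absent from `theta_fixed` act as 0 (pathway cut off).
#'
#' @param test_dataset `mp_dataset`.
#' @param theta_fixed `core_params`.
#' @param topologies model indices to evaluate (default all 81).
#' @param priors `prior_set` (peripheral bounds).
#' @param config `opt_config` for the peripheral fits.
#' @return List of class `fitness_matrix`: `fitness` (length-81 vector,
#'   NA outside `topologies`), `grid` (9x9), `contrast`.
#' @export
specificity_fitness <- function(test_dataset, theta_fixed,
                                topologies = 1:81,
                                priors = default_priors(),
                                config = opt_config(n_starts = 1)) {
  if (length(test_dataset) == 0) stop("invalid-input: dataset is empty")
  n_pts <- vapply(test_dataset$series, function(s) length(s$values),
                  numeric(1))
  fitness <- rep(NA_real_, 81)
  for (m in topologies) {
    ll <- 0
    for (s in test_dataset$series) {
      pf <- fit_phi_series(s, m, theta_fixed, priors, config)
      ll <- ll + pf$log_likelihood
    }
    fitness[m] <- ll / sum(n_pts)
  }
  structure(list(fitness = fitness, grid = model_matrix_grid(fitness),
                 contrast = if (length(topologies) == 81) group_contrast(fitness) else NA_real_,
                 topologies = topologies),
            class = "fitness_matrix")
}

#' Normalized root-mean-squared error
#'
#' RMSE (with the unbiased `n - 1` denominator) divided by the sample s.d.
#' of the observed segment, so that predicting the observed mean for every
#' point scores exactly 1.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return Dimensionless nonnegative scalar.
#' @export
normalized_rmse <- function(observed, predicted) {
  n <- length(observed)
  if (n < 2 || length(predicted) != n)
    stop("invalid-input: need equal lengths >= 2")
  s <- sd(observed)
  if (s == 0) stop("undefined-normalization: observed segment has zero s.d.")
  sqrt(sum((observed - predicted)^2) / (n - 1)) / s
}

#' Late-phase predictability test (data assimilation)
#'
#' For each fold i: the core is trained on the other series' full length
#' (`theta_i`), the peripherals of series i are trained on the initial
#' phase only (t <= `split_s`), the trajectory is then forecast to
#' `horizon_s`, and the untrained late phase (`split_s`, `horizon_s`] is
#' scored by log likelihood per point and normalized RMSE.
#'
#' @inheritParams loo_cross_validate
#' @param split_s end of the peripheral training window, s (default 250).
#' @param horizon_s forecast horizon, s (default 800).
#' @param config `opt_config`.
#' @param thetas optional list of pre-trained per-fold cores (e.g. from a
#'   previous [loo_cross_validate()] run on the same dataset) to avoid
#'   refitting.
#' @return List of class `prediction_result`: per-series `late_loglik_per_point`,
#'   `nrmse`, `predicted` (list of late-phase trajectories), `folds`.
#' @export
predictability_test <- function(dataset, topology,
                                priors = default_priors(),
                                split_s = 250, horizon_s = 800,
                                config = opt_config(), thetas = NULL) {
  n <- length(dataset)
  if (n < 2) stop("invalid-input: need at least 2 series")
  topology <- as_topology(topology)
  codes <- topology_codes(topology)
  fitness <- nrmse <- rep(NA_real_, n)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    s <- dataset$series[[i]]
    if (length(s$values) <= split_s + 1) {
      warning("series ", s$series_id, " shorter than split; skipped")
      next
    }
    cfg <- config
    cfg$seed <- config$seed + i
    theta_i <- if (!is.null(thetas)) thetas[[i]]
               else maximize_log_likelihood(dataset[-i], topology, priors,
                                            cfg)$theta
    pf <- fit_phi_series(s, topology, theta_i, priors,
                         n_points = split_s + 1)
    horizon <- min(horizon_s, length(s$values) - 1)
    vhat <- sim_vhat(codes, theta_vec(theta_i), phi_vec(pf$phi),
                     cond_vec(s$condition), 0:horizon)
    late <- (split_s + 2):(horizon + 1)      # grid indices of (split, horizon]
    obs <- s$values[late]
    pred <- vhat[late]
    fitness[i] <- .loglik_series_cpp(obs, pred, s$sigma) / length(obs)
    nrmse[i] <- normalized_rmse(obs, pred)
    preds[[i]] <- pred
  }
  structure(list(late_loglik_per_point = fitness, nrmse = nrmse,
                 predicted = preds, folds = n, split_s = split_s,
                 horizon_s = horizon_s,
                 topology = topology$index),
            class = "prediction_result")
}
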