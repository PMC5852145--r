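#' Specification of a synthetic dataset
#'
#' Describes a simulated repeat of the study design.  Defaults emulate the
#' identification dataset: 16 growth cones stimulated with 10 uM 8-Br-cGMP
#' through the pipette (control n = 7, ClC blocked by DNDS n = 5, NaC
#' blocked by STX n = 4), generated from the minimal group-b topology M_7
#' with the reported affinities (`K_X` = 1.15 uM, `K_Y` = 16.61 uM), 600 s
#' recordings, and the three noise types of the recordings: white
#' observation noise (2 mV), sparse single-sample spikes and occasional
#' step artifacts, injected on a 10 Hz raw grid before decimation.
#'
#' @param design named integer vector of condition counts.
#' @param stimulant_uM stimulant level, uM.
#' @param topology generating topology (index or `model_topology`).
#' @param theta generating `core_params` (gains must match the topology).
#' @param phi_sd named s.d.s of the peripheral population distributions
#'   (means come from `theta`'s `A_*0` fields; `V_K` mean is `V_K_mean`).
#' @param V_K_mean,V_K_sd baseline-potential population, mV.
#' @param tau_S_mean rise-time population mean, s.
#' @param noise list: `white_sd` (mV), `spike_rate` (per s),
#'   `spike_amp` (mV), `step_prob` (per series), `step_amp` (mV),
#'   `step_dur` (s).
#' @param length_s series length, s (study range 300-900).
#' @param raw_hz raw sampling rate before decimation.
#' @param route stimulation route.
#' @param seed integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(design = c(control = 7, DNDS = 5, STX = 4),
                           stimulant_uM = 10,
                           topology = 7,
                           theta = core_params(g_WtoCl = 2),
                           phi_sd = c(tau_S = 5, A_Cl = 2, A_Na = 2,
                                      A_Z = 0.2, A_W = 0.2),
                           V_K_mean = -75, V_K_sd = 3, tau_S_mean = 30,
                           noise = list(white_sd = 2, spike_rate = 0.02,
                                        spike_amp = 40, step_prob = 0.25,
                                        step_amp = 10, step_dur = 30),
                           length_s = 600, raw_hz = 10,
                           route = "PIPETTE", seed = 1) {
  stopifnot(all(design >= 0), length_s >= 2, raw_hz >= 2, stimulant_uM >= 0)
  structure(list(design = design, stimulant_uM = stimulant_uM,
                 topology = as_topology(topology), theta = theta,
                 phi_sd = phi_sd, V_K_mean = V_K_mean, V_K_sd = V_K_sd,
                 tau_S_mean = tau_S_mean, noise = noise,
                 length_s = length_s, raw_hz = raw_hz, route = route,
                 seed = seed), class = "synthetic_spec")
}

draw_phi <- function(spec) {
  sdv <- spec$phi_sd
  peripheral_params(
    V_K = rnorm(1, spec$V_K_mean, spec$V_K_sd),
    tau_S = rtnorm(1, spec$tau_S_mean, sdv[["tau_S"]], 1),
    A_Cl = rtnorm(1, spec$theta$A_Cl0, sdv[["A_Cl"]], 0),
    A_Na = rtnorm(1, spec$theta$A_Na0, sdv[["A_Na"]], 0),
    A_Z = rtnorm(1, spec$theta$A_Z0, sdv[["A_Z"]], 0),
    A_W = rtnorm(1, spec$theta$A_W0, sdv[["A_W"]], 0))
}

#' Inject the three recording noise types into a clean raw trace
#'
#' Adds (1) single-sample spikes at Poisson times, (2) a step artifact
#' (rectangular offset of given duration) with the stated probability, and
#' (3) white Gaussian observation noise, on the raw sampling grid.
#'
#' @param times raw sample times, s.
#' @param clean clean potentials, mV.
#' @param noise noise spec (see [synthetic_spec()]).
#' @param seed optional integer seed.
#' @return List: `values` (noisy trace), `spikes` (times), `steps` (list of
#'   `onset_s`, `end_s`, `amp`).
#' @export
inject_artifacts <- function(times, clean, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- clean
  span <- max(times) - min(times)
  spikes <- numeric(0)
  if (noise$spike_rate > 0 && noise$spike_amp != 0) {
    n_sp <- rpois(1, noise$spike_rate * span)
    if (n_sp > 0) {
      spikes <- sort(runif(n_sp, min(times), max(times)))
      for (tsp in spikes) {
        j <- which.min(abs(times - tsp))
        v[j] <- v[j] + noise$spike_amp
      }
    }
  }
  steps <- list()
  if (noise$step_prob > 0 && runif(1) < noise$step_prob) {
    on <- runif(1, 0.15 * span, 0.7 * span)
    en <- min(on + noise$step_dur, max(times))
    amp <- sample(c(-1, 1), 1) * noise$step_amp
    v[times >= on & times < en] <- v[times >= on & times < en] + amp
    steps[[1]] <- list(onset_s = on, end_s = en, amp = amp)
  }
  if (noise$white_sd > 0) v <- v + rnorm(length(v), 0, noise$white_sd)
  list(values = v, spikes = spikes, steps = steps)
}

#' Generate a synthetic dataset
#'
#' For each series: draws the peripheral parameters from their population
#' distributions (the cell-to-cell variability the hierarchical model
#' assumes), simulates the clean potential on the raw grid under the
#' series' condition, injects spike/step/white noise, and records the full
#' ground truth.  Deterministic given the spec's seed.
#'
#' @param spec `synthetic_spec`.
#' @return List of class `generated_dataset` with `raw` (list of raw
#'   traces: `times`, `values`, `condition_label`, `series_id`,
#'   `annotations`), `truth` (topology, theta, per-series phi, injected
#'   artifacts), and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  labels <- rep(names(spec$design), spec$design)
  n <- length(labels)
  if (n == 0) stop("configuration-error: empty design")
  dt <- 1 / spec$raw_hz
  times <- seq(0, spec$length_s, by = dt)
  raw <- vector("list", n)
  phis <- vector("list", n)
  arts <- vector("list", n)
  codes <- topology_codes(spec$topology)
  thv <- theta_vec(spec$theta)
  for (i in seq_len(n)) {
    cond <- condition_from_label(labels[i], spec$stimulant_uM, spec$route)
    if (!is.null(spec$pkg_active)) cond$pkg_active <- spec$pkg_active
    phi <- draw_phi(spec)
    clean <- sim_vhat(codes, thv, phi_vec(phi), cond_vec(cond), times)
    nz <- inject_artifacts(times, clean, spec$noise)
    raw[[i]] <- list(times = times, values = nz$values,
                     condition_label = labels[i],
                     series_id = sprintf("%s_%02d", labels[i], i),
                     condition = cond,
                     annotations = nz$steps)
    phis[[i]] <- phi
    arts[[i]] <- list(spikes = nz$spikes, steps = nz$steps)
  }
  structure(list(raw = raw,
                 truth = list(topology = spec$topology, theta = spec$theta,
                              phi = phis, artifacts = arts),
                 spec = spec),
            class = "generated_dataset")
}

#' Generate a dataset from outside the trained core system
#'
#' Two specificity scenarios: `"pkg_inhibited"` reproduces the KT5823
#' condition (PKG off in every series, so only the CNGC-ClC arm drives the
#' potential: sustained hyperpolarization); `"different_core"` emulates a
#' netrin-like system in which NaC is driven directly by the CNGC arm with
#' no PKG pathway — implemented by giving the second arm the first arm's
#' Hill parameters (so `W` tracks `X`) and removing all cross interactions.
#'
#' @param spec base `synthetic_spec`.
#' @param mode `"pkg_inhibited"` or `"different_core"`.
#' @return `generated_dataset`.
#' @export
generate_alternative_dataset <- function(spec = synthetic_spec(),
                                         mode = c("pkg_inhibited",
                                                  "different_core")) {
  mode <- match.arg(mode)
  if (mode == "pkg_inhibited") {
    spec$pkg_active <- 0
  } else {
    spec$topology <- topology_from_index(1)
    spec$theta$K_Y <- spec$theta$K_X
    spec$theta$n_Y <- spec$theta$n_X
    spec$theta$k_W <- spec$theta$k_Z
    spec$theta$g_ZtoW <- spec$theta$g_WtoCl <- 0
    spec$theta$g_ZtoNa <- spec$theta$g_WtoZ <- 0
  }
  generate_dataset(spec)
}

#' Preprocess a generated (or loaded raw) dataset to 1 Hz series
#'
#' Runs the full preprocessing chain per series: decimation to the 1 s
#' grid, step-artifact correction (using the ground-truth annotations when
#' present, emulating the manual curation of the recordings; automatic
#' detection otherwise), and noise-s.d. estimation.
#'
#' @param gd `generated_dataset` (or a list with a compatible `raw` field).
#' @param window_s smoothing window for [estimate_noise_sd()].
#' @param use_annotations use stored step annotations instead of automatic
#'   detection.
#' @return `mp_dataset` ready for inference.
#' @export
preprocess_dataset <- function(gd, window_s = 31, use_annotations = TRUE) {
  series <- lapply(gd$raw, function(r) {
    s <- downsample_to_1hz(r$times, r$values, r$condition_label,
                           r$series_id, r$condition)
    ann <- NULL
    if (use_annotations && length(r$annotations)) {
      ann <- lapply(r$annotations, function(a) {
        on <- max(1L, floor(a$onset_s) + 1L)   # grid index of t = floor(onset)
        en <- min(length(s$values), ceiling(a$end_s) + 1L)
        list(onset_index = on, end_index = en, offset = NA_real_)
      })
    }
    s <- correct_step_artifacts(s, ann)
    estimate_noise_sd(s, window_s)
  })
  mp_dataset(series)
}

#' Default synthetic dataset of the identification design
#'
#' Convenience wrapper: [generate_dataset()] + [preprocess_dataset()] with
#' the default spec (16 series, 10 uM design).
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_spec()].
#' @return `mp_dataset`.
#' @export
synthetic_mp_dataset <- function(seed = 1, ...) {
  preprocess_dataset(generate_dataset(synthetic_spec(seed = seed, ...)))
}
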