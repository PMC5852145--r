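CORE_FIELDS <- c("K_X", "n_X", "K_Y", "n_Y", "k_Z", "k_W",
                 "g_ZtoW", "g_WtoCl", "g_ZtoNa", "g_WtoZ",
                 "A_Cl0", "A_Na0", "A_Z0", "A_W0")
PERIPHERAL_FIELDS <- c("V_K", "tau_S", "A_Cl", "A_Na", "A_Z", "A_W")

#' Core (cell-common) system parameters
#'
#' The parameter set theta shared by all cells: Hill half-activations and
#' coefficients of the cGMP-CNGC (`K_X`, `n_X`, high affinity) and cGMP-PKG
#' (`K_Y`, `n_Y`, low affinity) arms, first-order relaxation rates of the
#' downstream factors (`k_Z`, `k_W`, 1/s), the four interaction gains
#' (dimensionless, meaningful only where the topology's sign is not NONE),
#' and the population means of the peripheral amplitudes (`A_Cl0`, `A_Na0`,
#' mV; `A_Z0`, `A_W0`, dimensionless).
#'
#' Defaults follow the reported affinity estimates (`K_X` = 1.15 uM,
#' `K_Y` = 16.61 uM) with Hill coefficients at the cGMP binding-site counts
#' (4 for CNGC, 2 for PKG).  The relaxation rates are set so the CNGC arm
#' responds within tens of seconds (`k_Z` = 0.1/s) while the PKG arm
#' converts the response on the minute scale (`k_W` = 0.01/s), placing
#' steady state near 300 s as observed; amplitudes are plumbing defaults.
#' Everything is overridable.
#'
#' @param ... named overrides of any field.
#' @return Named list of class `core_params`.
#' @export
core_params <- function(...) {
  p <- list(K_X = 1.15, n_X = 4, K_Y = 16.61, n_Y = 2,
            k_Z = 0.1, k_W = 0.01,
            g_ZtoW = 0, g_WtoCl = 0, g_ZtoNa = 0, g_WtoZ = 0,
            A_Cl0 = 10, A_Na0 = 10, A_Z0 = 1, A_W0 = 1)
  p <- override(p, list(...), "core_params")
  stopifnot(all(unlist(p) >= 0), p$n_X >= 1, p$n_Y >= 1)
  structure(p, class = "core_params")
}

#' Peripheral (per-cell) parameters
#'
#' The parameter set phi_i fit to each recording: baseline potential `V_K`
#' (mV, a pure additive bias), stimulus rise time constant `tau_S` (s),
#' channel amplitudes `A_Cl`, `A_Na` (mV) and downstream-factor gains
#' `A_Z`, `A_W` (dimensionless).
#'
#' @param ... named overrides of any field.
#' @return Named list of class `peripheral_params`.
#' @export
peripheral_params <- function(...) {
  p <- list(V_K = -75, tau_S = 30, A_Cl = 10, A_Na = 10, A_Z = 1, A_W = 1)
  p <- override(p, list(...), "peripheral_params")
  if (p$tau_S <= 0) stop("invalid-argument: tau_S must be positive")
  stopifnot(p$A_Cl >= 0, p$A_Na >= 0, p$A_Z >= 0, p$A_W >= 0)
  structure(p, class = "peripheral_params")
}

#' Experimental condition parameters
#'
#' `eta_Cl = 0` models the ClC blocker DNDS, `eta_Na = 0` the NaC blocker
#' STX, `pkg_active = 0` the PKG inhibitor KT5823.  `S_max` is the stimulant
#' level (uM) and `route` is `"PIPETTE"` (direct injection) or `"BATH"`
#' (asymptotic level corrected by the Hill-like membrane-permeation model).
#'
#' @param eta_Cl,eta_Na,pkg_active binary flags (1 = functional).
#' @param S_max stimulant concentration, uM, nonnegative.
#' @param route `"PIPETTE"` or `"BATH"`.
#' @return Named list of class `condition_params`.
#' @export
condition_params <- function(eta_Cl = 1, eta_Na = 1, S_max = 10,
                             route = "PIPETTE", pkg_active = 1) {
  route <- match.arg(toupper(route), c("PIPETTE", "BATH"))
  stopifnot(eta_Cl %in% c(0, 1), eta_Na %in% c(0, 1),
            pkg_active %in% c(0, 1), S_max >= 0)
  structure(list(eta_Cl = eta_Cl, eta_Na = eta_Na, S_max = S_max,
                 route = route, pkg_active = pkg_active),
            class = "condition_params")
}

#' Condition from a standard label
#'
#' Maps the pharmacological labels of the study design onto flags:
#' `"control"` (all functional), `"DNDS"` (ClC blocked), `"STX"` (NaC
#' blocked), `"KT5823"` (PKG inhibited).
#'
#' @param label condition label.
#' @param S_max stimulant level, uM.
#' @param route stimulation route.
#' @return `condition_params`.
#' @export
condition_from_label <- function(label, S_max = 10, route = "PIPETTE") {
  switch(label,
    control = condition_params(1, 1, S_max, route, 1),
    DNDS    = condition_params(0, 1, S_max, route, 1),
    STX     = condition_params(1, 0, S_max, route, 1),
    KT5823  = condition_params(1, 1, S_max, route, 0),
    stop("load-error: unknown condition label '", label, "'"))
}

override <- function(defaults, dots, what) {
  if (length(dots) == 0) return(defaults)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
    stop("invalid-argument: unknown ", what, " field(s): ",
         paste(bad, collapse = ", "))
  modifyList(defaults, dots)
}

# Ordered numeric vectors for the C++ kernel.
theta_vec <- function(theta) {
  as.numeric(theta[c("K_X", "n_X", "K_Y", "n_Y", "k_Z", "k_W",
                     "g_ZtoW", "g_WtoCl", "g_ZtoNa", "g_WtoZ")])
}
phi_vec <- function(phi) as.numeric(phi[PERIPHERAL_FIELDS])
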