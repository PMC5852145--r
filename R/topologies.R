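#' Construct a candidate interaction topology
#'
#' A topology assigns one of three signs (no interaction, activation,
#' inhibition) to each of the four unknown pathways between the cGMP
#' effectors' downstream factors (CNGC-DF, latent Z; PKG-DF, latent W) and
#' the ion channels: Z->W, W->ClC, Z->NaC and W->Z.  The two known edges
#' (Z activates ClC, W activates NaC) are always present.  With 3 signs on
#' 4 edges there are 3^4 = 81 candidates, indexed 1..81 so that M_1 has no
#' interactions and M_7 has only W -| ClC inhibition.
#'
#' @param s_ZtoW,s_WtoCl,s_ZtoNa,s_WtoZ pathway signs: integer codes 0/1/2
#'   or strings `"NONE"`, `"ACTIVATION"`, `"INHIBITION"`.
#' @return An object of class `model_topology` with fields `s_ZtoW`,
#'   `s_WtoCl`, `s_ZtoNa`, `s_WtoZ` (integer codes) and `index` in 1..81.
#' @examples
#' model_topology(0, 2, 0, 0)$index   # 7
#' @export
model_topology <- function(s_ZtoW = 0L, s_WtoCl = 0L, s_ZtoNa = 0L,
                           s_WtoZ = 0L) {
  signs <- vapply(list(s_ZtoW, s_WtoCl, s_ZtoNa, s_WtoZ), as_sign, integer(1))
  names(signs) <- PATHWAYS
  idx <- 1L + signs[[1]] + 3L * signs[[2]] + 9L * signs[[3]] + 27L * signs[[4]]
  structure(c(as.list(signs), list(index = idx)), class = "model_topology")
}

as_sign <- function(s) {
  if (is.character(s)) {
    s <- toupper(s)
    abbr <- c(N = "NONE", A = "ACTIVATION", I = "INHIBITION")
    if (s %in% names(abbr)) s <- abbr[[s]]
    if (!s %in% names(PATHWAY_SIGNS))
      stop("invalid-argument: unknown pathway sign '", s, "'")
    return(PATHWAY_SIGNS[[s]])
  }
  s <- as.integer(s)
  if (is.na(s) || s < 0L || s > 2L)
    stop("invalid-argument: pathway sign must be 0 (NONE), 1 (ACTIVATION) or 2 (INHIBITION)")
  s
}

#' Topology from its model index
#'
#' Inverse of the index convention `index = 1 + s_ZtoW + 3 s_WtoCl +
#' 9 s_ZtoNa + 27 s_WtoZ`.
#'
#' @param index integer in 1..81.
#' @return `model_topology`.
#' @export
topology_from_index <- function(index) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > 81L)
    stop("invalid-argument: model index must lie in 1..81")
  d <- index - 1L
  model_topology(d %% 3L, (d %/% 3L) %% 3L, (d %/% 9L) %% 3L, (d %/% 27L) %% 3L)
}

#' Enumerate all 81 candidate topologies
#'
#' @return List of 81 `model_topology` objects ordered by index.
#' @export
enumerate_topologies <- function() {
  lapply(1:81, topology_from_index)
}

#' @export
print.model_topology <- function(x, ...) {
  cat(sprintf("M_%d  [%s]\n", x$index, topology_signs(x)))
  invisible(x)
}

#' Compact sign string of a topology
#'
#' Four letters in pathway order (Z->W, W->Cl, Z->Na, W->Z), one of
#' N/A/I, comma-separated, e.g. `"N,I,N,N"` for M_7.
#'
#' @param topology `model_topology`.
#' @return Character scalar.
#' @export
topology_signs <- function(topology) {
  lab <- c("N", "A", "I")
  paste(lab[unlist(topology[PATHWAYS]) + 1L], collapse = ",")
}

#' Number of active (non-NONE) pathways in a topology
#' @param topology `model_topology`.
#' @return Integer in 0..4.
#' @export
n_active_pathways <- function(topology) {
  sum(unlist(topology[PATHWAYS]) != 0L)
}

#' Does a topology belong to model group b?
#'
#' Group b is the set of 27 topologies containing PKG-DF -| ClC inhibition
#' (`s_WtoCl == INHIBITION`), the right-hand three-column block of the 9x9
#' evidence matrix; group a is the remaining 54.
#'
#' @param topology `model_topology`.
#' @return Logical.
#' @export
in_group_b <- function(topology) {
  topology$s_WtoCl == PATHWAY_SIGNS[["INHIBITION"]]
}

#' Pathway interaction modifier
#'
#' The multiplicative factor through which an upstream activity `U` acts on
#' a target: 1 for no interaction, `1 + g U` for activation and
#' `1 / (1 + g U)` for inhibition.  All three forms equal 1 at `g = 0`, so a
#' complex model nests every simpler one by sending unused gains to zero
#' (the property the zero-peaked truncated-normal priors exploit).
#'
#' @param U nonnegative upstream activity.
#' @param sign pathway sign (code or string).
#' @param g nonnegative interaction gain.
#' @return Positive factor (vectorised over `U`).
#' @examples
#' interaction_modifier(1, "ACTIVATION", 1)  # 2
#' interaction_modifier(1, "INHIBITION", 1)  # 0.5
#' @export
interaction_modifier <- function(U, sign, g) {
  if (any(U < 0)) stop("invalid-argument: activity U must be nonnegative")
  if (g < 0) stop("invalid-argument: gain g must be nonnegative")
  s <- as_sign(sign)
  if (s == 1L) 1 + g * U
  else if (s == 2L) 1 / (1 + g * U)
  else rep(1, length(U))
}
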