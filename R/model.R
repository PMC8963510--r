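# canonical state order; shared with src/pcs_rhs.c
.pcs_state_names <- c(
  "CL_m", "CL_p", "P97_m", "P97_p", "P51_m", "P51_p", "EL_m", "EL_p",
  "PIF_m", "PIF_p", "HYP", "PhyA", "PhyB", "Cry1",
  "COP1", "COP1_PhyA", "COP1_PhyB", "COP1_Cry1")

#' Default initial state
#'
#' mRNAs, proteins and free photoreceptors start at one, the COP1 pool at
#' `Ctot`, and the photoreceptor-COP1 complexes and the hypocotyl length at
#' zero.
#'
#' @param params a `pcs_params` object (supplies `Ctot`).
#' @return named numeric state vector in canonical order.
#' @export
pcs_initial_state <- function(params = pcs_params()) {
  params <- validate_params(params)
  y <- stats::setNames(rep(1, 18), .pcs_state_names)
  y[c("COP1_PhyA", "COP1_PhyB", "COP1_Cry1", "HYP")] <- 0
  y["COP1"] <- params[["Ctot"]]
  y
}

#' Total photoreceptor pools
#'
#' Totals are free photoreceptor plus its COP1 complex.
#'
#' @param state named state vector (canonical order/names).
#' @return `c(TPhyA, TPhyB, TCry1)`.
#' @export
total_photoreceptors <- function(state) {
  state <- .check_state(state)
  c(TPhyA = unname(state["PhyA"] + state["COP1_PhyA"]),
    TPhyB = unname(state["PhyB"] + state["COP1_PhyB"]),
    TCry1 = unname(state["Cry1"] + state["COP1_Cry1"]))
}

#' Light-input function
#'
#' The additive light drive on clock transcription: a phyA term gated by
#' any light plus logarithmic red and blue intensity responses weighted by
#' the total phyB and cry1 pools. Channel `"a"` (coefficients `q1a`, `q3a`,
#' `q4a`) feeds CL transcription, channel `"b"` (`q1b`, `q3b`, `q4b`) feeds
#' P97 transcription. Natural logarithm.
#'
#' @param channel `"a"` or `"b"`.
#' @param state named state vector.
#' @param I_red,I_blue intensities (umol m-2 s-1).
#' @param params a `pcs_params` object.
#' @return scalar light input.
#' @export
light_input <- function(channel, state, I_red, I_blue, params = pcs_params()) {
  channel <- match.arg(channel, c("a", "b"))
  state <- .check_state(state)
  params <- validate_params(params)
  th <- light_indicators(I_red, I_blue)
  tot <- total_photoreceptors(state)
  q <- params[paste0(c("q1", "q3", "q4"), channel)]
  unname(q[1] * tot["TPhyA"] * th["theta_phyA"] +
         q[2] * tot["TPhyB"] * log(params[["eta1"]] * I_red + 1) *
           th["theta_phyB"] +
         q[3] * tot["TCry1"] * log(params[["eta2"]] * I_blue + 1) *
           th["theta_cry1"])
}

#' Evaluate the model right-hand side
#'
#' Instantaneous derivative of all 18 states at the given light
#' intensities. The `no_binding` variant zeroes the photoreceptor-COP1
#' binding rates and the COP1-dependent EL-protein degradation activities,
#' which reduces the system to the clock with independent photoreceptor
#' turnover (the pre-COP1 formulation).
#'
#' @param state named state vector.
#' @param I_red,I_blue intensities.
#' @param params a `pcs_params` object.
#' @param variant `"full"` or `"no_binding"`.
#' @param complex_decay_uses_complex if `TRUE`, the saturable decay of the
#'   phyB and cry1 complexes is evaluated at the complex concentration
#'   rather than (as printed in the source formulation) at the free
#'   photoreceptor concentration.
#' @return named derivative vector.
#' @export
clock_rhs <- function(state, I_red, I_blue, params = pcs_params(),
                      variant = c("full", "no_binding"),
                      complex_decay_uses_complex = TRUE) {
  variant <- match.arg(variant)
  state <- .check_state(state)
  params <- validate_params(params)
  light_indicators(I_red, I_blue)  # validates intensities
  cp <- .c_parms(params, variant, I_red, I_blue, complex_decay_uses_complex)
  d <- .Call("pcs_rhs_call", as.numeric(state), cp,
             PACKAGE = "phytoclock")
  names(d) <- .pcs_state_names
  bad <- !is.finite(d)
  if (any(bad))
    stop("non-finite derivative for state(s): ",
         paste(.pcs_state_names[bad], collapse = ", "))
  d
}

.check_state <- function(state) {
  if (is.null(names(state)))
    names(state) <- .pcs_state_names
  if (!all(.pcs_state_names %in% names(state)))
    stop("state must carry the canonical names: ",
         paste(setdiff(.pcs_state_names, names(state)), collapse = ", "))
  state <- state[.pcs_state_names]
  if (any(!is.finite(state))) stop("non-finite state")
  state
}

# assemble the compiled-code parameter vector:
# 69 named parameters + ox1..ox5 + I_red + I_blue + complex-decay flag
.c_parms <- function(params, variant, I_red, I_blue,
                     complex_decay_uses_complex) {
  vals <- unclass(params)[.pcs_par_names]
  ox <- attr(params, "ox")
  if (is.null(ox)) ox <- numeric(5)
  if (variant == "no_binding") {
    vals[c("kmpac", "kmpbc", "kmpcc")] <- 0
    vals[c("de2", "de3", "de4", "de5")] <- 0
  }
  c(unname(vals), ox, I_red, I_blue,
    as.numeric(isTRUE(complex_decay_uses_complex)))
}
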