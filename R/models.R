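# Model right-hand sides, R-level mirrors of the native kernels.
# These are the printed equations; simulate_model() uses the C++ versions.

#' Core model right-hand side
#'
#' Time derivatives of the reduced cyanobacterial clock:
#' \preformatted{ dT/dt  = k1 f(S, A_T, Kd) (C_T - T - ST - S) - k2 T
#'  dST/dt = k2 T - k3 ST
#'  dS/dt  = k3 ST - k4 S }
#' with `f` the sequestration quadratic [free_kaia()].
#'
#' @param state named numeric vector with components `T`, `ST`, `S`.
#' @param p a [core_params()] object.
#' @return named derivative vector `(dT, dST, dS)`.
#' @examples
#' rhs_core(c(T = 0, ST = 0, S = 0), core_params())
#' @export
rhs_core <- function(state, p) {
  stopifnot(inherits(p, "core_params"))
  if (any(!is.finite(state))) stop_domain("non-finite state")
  T <- state[["T"]]; ST <- state[["ST"]]; S <- state[["S"]]
  A <- free_kaia(S, p$A_T, p$Kd)
  U <- p$C_T - T - ST - S
  c(T = p$k1 * A * U - p$k2 * T,
    ST = p$k2 * T - p$k3 * ST,
    S = p$k3 * ST - p$k4 * S)
}

#' TTFL / PTR model right-hand side
#'
#' Five-variable extension of the core model with kaiBC mRNA `M`.  The
#' transcription term is `V_trsp * 100 / (1 + (S/K_0)^4)` in TTFL mode and
#' the constant `V_trsp` in PTR mode; all KaiC forms are additionally
#' degraded at `V_d`.
#'
#' @param state named numeric vector with components `M`, `U`, `T`, `ST`, `S`.
#' @param p a [ttfl_params()] object.
#' @return named derivative vector.
#' @examples
#' p <- ttfl_params(mode = "PTR")
#' rhs_ttfl(c(M = 0, U = 0, T = 0, ST = 0, S = 0), p)
#' @export
rhs_ttfl <- function(state, p) {
  stopifnot(inherits(p, "ttfl_params"))
  if (any(!is.finite(state))) stop_domain("non-finite state")
  M <- state[["M"]]; U <- state[["U"]]; T <- state[["T"]]
  ST <- state[["ST"]]; S <- state[["S"]]
  A <- free_kaia(S, p$A_T, p$Kd)
  trans <- if (p$mode == "TTFL") {
    p$V_trsp * p$fold_factor / (1 + (S / p$K_0)^p$hill_exponent)
  } else {
    p$V_trsp
  }
  c(M = trans - p$V_m * M,
    U = p$K_s * M - p$k1 * A * U + p$k4 * S - p$V_d * U,
    T = p$k1 * A * U - p$k2 * T - p$V_d * T,
    ST = p$k2 * T - p$k3 * ST - p$V_d * ST,
    S = p$k3 * ST - p$k4 * S - p$V_d * S)
}

#' Eukaryotic repressor-chain right-hand side
#'
#' The shared three-stage negative feedback chain
#' \preformatted{ dM/dt = alpha1 f(R) - beta1 M
#'  dr/dt = alpha2 M - beta2 r
#'  dR/dt = alpha3 r - beta3 R }
#' where the repression function `f` dispatches on the parameter class:
#' free-activator *fraction* for [kim_forger_params()] and free activator
#' amount for [phospholock_params()] / [neurospora_params()].  At a steady
#' state the chain collapses to
#' `alpha1 alpha2 alpha3 f(R*) = beta1 beta2 beta3 R*`, the fixed-point
#' equation used by [steady_state_repressor()].
#'
#' @param state named numeric vector `(M, r, R)` (Kim-Forger: `(M, Pc, P)`).
#' @param p a [kim_forger_params()], [phospholock_params()] or
#'   [neurospora_params()] object.
#' @return named derivative vector.
#' @examples
#' rhs_phospholock(c(M = 0, r = 0, R = 0), phospholock_params_table1(k2 = 10))
#' @export
rhs_phospholock <- function(state, p) {
  if (any(!is.finite(state))) stop_domain("non-finite state")
  sp <- model_spec(p)
  if (sp$id != 3L) stop_domain("parameter set is not a repressor-chain model")
  M <- state[[1]]; r <- state[[2]]; R <- state[[3]]
  f <- repression_value(R, p)
  out <- c(p$alpha1 * f - p$beta1 * M,
           p$alpha2 * M - p$beta2 * r,
           p$alpha3 * r - p$beta3 * R)
  names(out) <- sp$states
  out
}

# repression function value for any repressor-chain parameter object
repression_value <- function(R, p) {
  if (inherits(p, "kim_forger_params")) {
    kim_forger_fraction(R, p$A, p$Kd)
  } else if (inherits(p, "neurospora_params")) {
    neurospora_repression(R, p)
  } else {
    phospholock_repression(R, p)
  }
}
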