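# Parameter-set constructors.  Every model family gets a validating
# constructor returning a classed list; simulate_model() and the detectors
# dispatch on the class.  Units: hours for time, arbitrary concentration
# units (a.u.) for abundances; bimolecular rates are a.u.^-1 h^-1.

new_params <- function(fields, class) {
  structure(fields, class = c(class, "clock_params"))
}

#' @export
print.clock_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flat <- unlist(x[vapply(x, is.numeric, logical(1))])
  cat(paste0("  ", names(flat), " = ", fmt_num(flat)), sep = "\n")
  extra <- x[!vapply(x, is.numeric, logical(1))]
  if (length(extra))
    cat(paste0("  ", names(extra), " = ", vapply(extra, format, "")), sep = "\n")
  invisible(x)
}

#' Core KaiA-sequestration model parameters
#'
#' Parameters of the reduced cyanobacterial clock: KaiC phosphoforms T, ST
#' and S interconvert in a chain, free KaiA (given by [free_kaia()])
#' catalyses the first phosphorylation, and S-phosphorylated KaiC
#' sequesters KaiA.  Defaults are the package's stand-in set, calibrated so
#' that the default system has a circadian (~24 h) limit cycle; equal
#' `k2 = k3 = k4` makes the stoichiometric constant of the balance
#' condition `C_T > (1 + r) A_T` equal to `r = 2`.
#'
#' @param k1 KaiA-stimulated phosphorylation rate (a.u.^-1 h^-1).
#' @param k2,k3,k4 phosphoform interconversion / dephosphorylation rates (h^-1).
#' @param Kd KaiA-KaiC(S) dissociation constant (a.u.); scans span 1e-4..1e-1.
#' @param A_T,C_T total KaiA and KaiC (a.u.).
#' @return a `core_params` object.
#' @examples
#' p <- core_params()
#' p
#' @export
core_params <- function(k1 = 0.2, k2 = 0.13, k3 = 0.13, k4 = 0.13,
                        Kd = 1e-4, A_T = 8, C_T = 40) {
  for (nm in c("k1", "k2", "k3", "k4"))
    check_scalar(get(nm), nm, 0, strict_min = TRUE)
  check_scalar(Kd, "Kd", 0)
  check_scalar(A_T, "A_T", 0, strict_min = TRUE)
  check_scalar(C_T, "C_T", 0, strict_min = TRUE)
  new_params(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                  Kd = Kd, A_T = A_T, C_T = C_T), "core_params")
}

#' TTFL / PTR extension of the core model
#'
#' Adds kaiBC transcription and translation to the core model.  In `TTFL`
#' mode transcription is inhibited by S-phosphorylated KaiC through the
#' fixed structural term `100 / (1 + (S/K_0)^4)`; in `PTR` mode
#' transcription is constitutive at `V_trsp`.  The Hill exponent 4 and the
#' fold factor 100 are structural constants, not free parameters.
#' Defaults are the package's Table-S1 stand-in values.
#'
#' @param V_trsp maximal (PTR: constant) transcription rate (a.u. h^-1).
#' @param V_m mRNA degradation rate (h^-1).
#' @param K_s translation rate (h^-1).
#' @param K_0 inhibition threshold of S on kaiBC transcription (a.u.).
#' @param k1,k2,k3,k4 as in [core_params()].
#' @param V_d KaiC protein degradation/dilution rate (h^-1).
#' @param Kd,A_T as in [core_params()].
#' @param mode `"TTFL"` or `"PTR"`.
#' @return a `ttfl_params` object.
#' @examples
#' ttfl_params(K_s = 0.5, A_T = 20, mode = "PTR")
#' @export
ttfl_params <- function(V_trsp = 10, V_m = 0.5, K_s = 0.5, K_0 = 50,
                        k1 = 0.2, k2 = 0.13, k3 = 0.13, k4 = 0.13,
                        V_d = 0.05, Kd = 1e-4, A_T = 20,
                        mode = c("TTFL", "PTR")) {
  mode <- match.arg(mode)
  for (nm in c("V_trsp", "V_m", "K_s", "K_0", "k1", "k2", "k3", "k4", "V_d"))
    check_scalar(get(nm), nm, 0, strict_min = TRUE)
  check_scalar(Kd, "Kd", 0)
  check_scalar(A_T, "A_T", 0, strict_min = TRUE)
  new_params(list(V_trsp = V_trsp, V_m = V_m, K_s = K_s, K_0 = K_0,
                  k1 = k1, k2 = k2, k3 = k3, k4 = k4, V_d = V_d,
                  Kd = Kd, A_T = A_T, mode = mode,
                  hill_exponent = 4, fold_factor = 100), "ttfl_params")
}

#' Kim-Forger model parameters
#'
#' The three-stage activator-repressor titration model of the mammalian
#' clock: repressor mRNA M, cytosolic protein Pc and nuclear protein P,
#' with transcription proportional to the free-activator fraction
#' [kim_forger_fraction()].
#'
#' @param alpha1,alpha2,alpha3 production rates (h^-1; `alpha1` in a.u. h^-1).
#' @param beta1,beta2,beta3 degradation rates (h^-1).
#' @param A total activator (a.u.).
#' @param Kd activator-repressor dissociation constant (a.u.).
#' @return a `kim_forger_params` object.
#' @export
kim_forger_params <- function(alpha1 = 95.2, beta1 = 25.6,
                              alpha2 = 43.4, beta2 = 28.7,
                              alpha3 = 98.3, beta3 = 20.1,
                              A = 98.9, Kd = 1e-4) {
  for (nm in c("alpha1", "beta1", "alpha2", "beta2", "alpha3", "beta3", "A"))
    check_scalar(get(nm), nm, 0, strict_min = TRUE)
  check_scalar(Kd, "Kd", 0)
  new_params(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                  beta2 = beta2, alpha3 = alpha3, beta3 = beta3,
                  A = A, Kd = Kd), "kim_forger_params")
}

#' Phospholock model parameters
#'
#' Eukaryotic clock model in which the repressor complex R sequesters the
#' activator and is phosphorylated while bound ("phospholock"), dissociating
#' at rate `k3`.  The chain is repressor mRNA M -> protein r -> complex R.
#' The derived quantities `Kd = k1r/k1f` and `k2 = k2f/k2r` are recomputed
#' on construction and never stored independently.
#'
#' @param alpha1,beta1,alpha2,beta2,alpha3,beta3 chain production and
#'   degradation rates (h^-1); defaults are the printed reference set.
#' @param A_T total activator (a.u.).
#' @param k1f,k1r activator-repressor binding/unbinding rates.
#' @param k2f,k2r phospholock phosphorylation/dephosphorylation rates.
#' @param k3 dissociation (degradation) rate of the phosphorylated complex.
#' @return a `phospholock_params` object with derived `Kd`, `k2` fields.
#' @examples
#' phospholock_params(k1f = 0.4, k1r = 0.4, k2f = 0.9, k2r = 0.09, k3 = 0.02)
#' @export
phospholock_params <- function(alpha1 = 95.2, beta1 = 25.6,
                               alpha2 = 43.4, beta2 = 28.7,
                               alpha3 = 98.3, beta3 = 20.1,
                               A_T = 98.9,
                               k1f = 1, k1r = 1, k2f = 1, k2r = 1,
                               k3 = 1.9) {
  for (nm in c("alpha1", "beta1", "alpha2", "beta2", "alpha3", "beta3", "A_T"))
    check_scalar(get(nm), nm, 0, strict_min = TRUE)
  for (nm in c("k1f", "k1r", "k2f", "k2r", "k3"))
    check_scalar(get(nm), nm, 0)
  if (k1f <= 0) stop_domain("'k1f' must be > 0")
  new_params(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                  beta2 = beta2, alpha3 = alpha3, beta3 = beta3,
                  A_T = A_T, k1f = k1f, k1r = k1r, k2f = k2f, k2r = k2r,
                  k3 = k3, Kd = k1r / k1f,
                  k2 = if (k2r > 0) k2f / k2r else Inf),
             "phospholock_params")
}

#' Reference phospholock parameter set at a given phosphorylation ratio
#'
#' Builds the printed reference parameter set (alpha/beta chain rates,
#' `Kd = 1`, `k3 = 1.9`, `A_T = 98.9`) with micro-rates realised for a
#' requested phosphorylation-to-dephosphorylation ratio `k2 = k2f/k2r`.
#' Binding kinetics are taken fast relative to the phosphorylation cycle
#' (`k1f = k1r = k_bind`, rapid pre-equilibrium), the convention under
#' which the ratio `k2` alone -- not the separate magnitudes -- controls
#' the repression function; see the package vignette.
#'
#' @param k2 phosphorylation-to-dephosphorylation ratio (`k2f/k2r`).
#' @param k2r dephosphorylation rate (h^-1); `k2f = k2 * k2r`.
#' @param k_bind binding/unbinding rate scale realising `Kd = 1`.
#' @return a `phospholock_params` object.
#' @examples
#' p <- phospholock_params_table1(k2 = 1e4)
#' effective_constants(p)$Kd_eff   # effective affinity tightens as k2 grows
#' @export
phospholock_params_table1 <- function(k2 = 1, k2r = 1, k_bind = 1000) {
  check_scalar(k2, "k2", 0, strict_min = TRUE)
  phospholock_params(k1f = k_bind, k1r = k_bind, k2f = k2 * k2r, k2r = k2r)
}

#' Phospholock parameters with activator phosphorylation
#'
#' Extends [phospholock_params()] with reversible phosphorylation of the
#' activator itself (rates `k4f`, `k4r`), the mechanism by which the
#' Neurospora clock can oscillate at low repressor-to-activator
#' stoichiometry.  The derived ratio `k4 = k4f/k4r` is recomputed on
#' construction.
#'
#' @inheritParams phospholock_params
#' @param k4f,k4r activator phosphorylation / dephosphorylation rates (h^-1).
#' @return a `neurospora_params` object.
#' @export
neurospora_params <- function(alpha1 = 95.2, beta1 = 25.6,
                              alpha2 = 43.4, beta2 = 28.7,
                              alpha3 = 98.3, beta3 = 20.1,
                              A_T = 98.9,
                              k1f = 1, k1r = 1e-5, k2f = 1, k2r = 0.1,
                              k3 = 0, k4f = 0.5, k4r = 0.5) {
  p <- phospholock_params(alpha1, beta1, alpha2, beta2, alpha3, beta3,
                          A_T, k1f, k1r, k2f, k2r, k3)
  check_scalar(k4f, "k4f", 0)
  check_scalar(k4r, "k4r", 0)
  if (k4f > 0 && k4r <= 0)
    stop_domain("'k4r' must be > 0 when 'k4f' > 0")
  p$k4f <- k4f
  p$k4r <- k4r
  p$k4 <- if (k4r > 0) k4f / k4r else 0
  class(p) <- c("neurospora_params", class(p))
  p
}

# ---------------------------------------------------------------------------
# model dispatch table: class -> native model id, parameter vector, states
# ---------------------------------------------------------------------------

model_spec <- function(p) UseMethod("model_spec")

#' @export
model_spec.core_params <- function(p) {
  list(id = 1L,
       pars = c(p$k1, p$k2, p$k3, p$k4, p$Kd, p$A_T, p$C_T),
       states = c("T", "ST", "S"),
       init = c(T = 0, ST = 0, S = 0),
       monitor = "S")
}

#' @export
model_spec.ttfl_params <- function(p) {
  list(id = 2L,
       pars = c(p$V_trsp, p$V_m, p$K_s, p$K_0, p$k1, p$k2, p$k3, p$k4,
                p$V_d, p$Kd, p$A_T, as.numeric(p$mode == "TTFL")),
       states = c("M", "U", "T", "ST", "S"),
       init = c(M = 0, U = 0, T = 0, ST = 0, S = 0),
       monitor = "S")
}

#' @export
model_spec.kim_forger_params <- function(p) {
  list(id = 3L,
       pars = c(p$alpha1, p$beta1, p$alpha2, p$beta2, p$alpha3, p$beta3,
                p$A, p$Kd, 1, 1, 1),
       states = c("M", "Pc", "P"),
       init = c(M = 0, Pc = 0, P = 0),
       monitor = "M")
}

#' @export
model_spec.phospholock_params <- function(p) {
  ec <- effective_constants(p)
  list(id = 3L,
       pars = c(p$alpha1, p$beta1, p$alpha2, p$beta2, p$alpha3, p$beta3,
                p$A_T, ec$Kd_eff, ec$q, ec$rho, 0),
       states = c("M", "r", "R"),
       init = c(M = 0, r = 0, R = 0),
       monitor = "M")
}
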