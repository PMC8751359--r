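# Closed-form repression / free-activator functions.
#
# All four functions are branches of the same quadratic: the free amount of an
# activator A that is titrated by a sequestrant at effective dissociation
# constant K, optionally discounted by reversible activator phosphorylation
# (factor q = 1 + k4).  The C++ kernel evaluates the numerically stable branch.

#' Free KaiA under sequestration by S431-phosphorylated KaiC
#'
#' Equilibrium amount of free KaiA when a total `A_T` of KaiA is sequestered
#' by an amount `S` of S431-phosphorylated KaiC with dissociation constant
#' `Kd`:
#' \deqn{f(S) = \left(A_T - S - K_d + \sqrt{(A_T - S - K_d)^2 + 4 K_d A_T}\right)/2.}
#' As `Kd` tends to 0 this approaches the tight-binding limit
#' `max(A_T - S, 0)`.
#'
#' @param S sequestrant amount(s), non-negative (vectorised).
#' @param A_T total activator, positive scalar.
#' @param Kd dissociation constant, non-negative scalar.
#' @return free activator, in `[0, A_T]`, same length as `S`.
#' @examples
#' free_kaia(4, A_T = 8, Kd = 1e-2)
#' free_kaia(0:10, A_T = 8, Kd = 1e-4)  # tight binding: ~ max(8 - S, 0)
#' @seealso [kim_forger_fraction()], [phospholock_repression()]
#' @export
free_kaia <- function(S, A_T, Kd) {
  if (any(!is.finite(S)) || any(S < 0)) stop_domain("'S' must be finite and >= 0")
  check_scalar(A_T, "A_T", 0, strict_min = TRUE)
  check_scalar(Kd, "Kd", 0)
  cpp_free_activator(as.numeric(S), A_T, Kd, 1.0)
}

#' Kim-Forger free-activator fraction
#'
#' The repression function of the Kim-Forger model of the mammalian clock:
#' the fraction of activator not sequestered by the repressor,
#' `f(P, A, Kd) = free_kaia(P, A, Kd) / A`, in `[0, 1]`.
#'
#' @param P total repressor amount(s), non-negative (vectorised).
#' @param A total activator, positive scalar.
#' @param Kd activator-repressor dissociation constant, non-negative scalar.
#' @return free-activator fraction in `[0, 1]`.
#' @examples
#' kim_forger_fraction(5, A = 10, Kd = 0.1)
#' @export
kim_forger_fraction <- function(P, A, Kd) {
  if (any(!is.finite(P)) || any(P < 0)) stop_domain("'P' must be finite and >= 0")
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop_domain("'A' must be a positive scalar (A = 0 is outside the model domain)")
  check_scalar(Kd, "Kd", 0)
  cpp_free_activator(as.numeric(P), A, Kd, 1.0) / A
}

#' Effective constants of the phospholock binding scheme
#'
#' Reduces the explicit phospholock reaction scheme
#' \preformatted{ A + R <-> AR   (k1f / k1r)
#'  AR  <-> ARp   (k2f / k2r)
#'  ARp  -> A + R  (k3; repressor-only model)
#'  ARp  -> Ap + R (k3; with activator phosphorylation)
#'  A    -> Ap     (k4f),  Ap -> A (k4r) }
#' to the effective constants of the closed-form repression function.  The
#' mapping is the exact steady state of the subnetwork:
#' \deqn{\tilde K_1 = k_{1f}(k_{2r} + k_3 + k_{2f}), \quad
#'       \tilde K_2 = k_{1r}(k_{2r} + k_3) + k_{2f} k_3,}
#' with effective dissociation constant `Kd_eff = K2_tilde / K1_tilde` and
#' activator-phosphorylation factor `q = 1 + k4f/k4r`.  Without activator
#' phosphorylation the dissociating complex releases active activator and
#' `K3_tilde = K1_tilde`.  With activator phosphorylation the lock cycle
#' releases the activator in its inactive form, so each repressor
#' molecule inactivates activators catalytically and
#' \deqn{\tilde K_3 = \tilde K_1 + k_{1f} k_{2f} k_3 / k_{4r};}
#' the amplification ratio `rho = K3_tilde/K1_tilde` rescales the
#' repressor axis of the repression function.  With `k2f = 0` and
#' `k3 = 0` everything collapses to pure sequestration with
#' `Kd_eff = k1r/k1f`.
#'
#' @param p a [phospholock_params()] or [neurospora_params()] object, or a
#'   named list carrying `k1f, k1r, k2f, k2r, k3` (and optionally
#'   `k4f, k4r`).
#' @return a list with `K1_tilde`, `K2_tilde`, `K3_tilde`, `Kd_eff`,
#'   `rho = K3_tilde/K1_tilde`, `k2 = k2f/k2r`, `k4 = k4f/k4r` (0 when
#'   absent) and `q = 1 + k4`.
#' @examples
#' p <- phospholock_params(k1f = 0.5, k1r = 0.5, k2f = 0.8, k2r = 0.08, k3 = 0.05)
#' effective_constants(p)
#' @export
effective_constants <- function(p) {
  need <- c("k1f", "k1r", "k2f", "k2r", "k3")
  if (!all(need %in% names(p)))
    stop_domain("parameter set lacks the phospholock micro-rates ",
                paste(setdiff(need, names(p)), collapse = ", "))
  for (nm in need) check_scalar(p[[nm]], nm, 0)
  if (p$k1f <= 0) stop_domain("'k1f' must be > 0 (K1_tilde would vanish)")
  k1f <- p$k1f; k1r <- p$k1r; k2f <- p$k2f; k2r <- p$k2r; k3 <- p$k3
  if (k2r + k3 + k2f <= 0)
    stop_domain("degenerate phospholock scheme: k2f + k2r + k3 must be > 0")
  K1 <- k1f * (k2r + k3 + k2f)
  K2 <- k1r * (k2r + k3) + k2f * k3
  k4 <- 0
  K3 <- K1
  has_ap <- inherits(p, "neurospora_params") ||
    (!is.null(p$k4f) && !is.null(p$k4r) && (p$k4f > 0 || p$k4r > 0))
  if (has_ap) {
    if (is.null(p$k4r) || p$k4r <= 0)
      stop_domain("'k4r' must be > 0 when activator phosphorylation is used")
    k4 <- (p$k4f %||% 0) / p$k4r
    K3 <- K1 + k1f * k2f * k3 / p$k4r
  }
  list(K1_tilde = K1, K2_tilde = K2, K3_tilde = K3,
       Kd_eff = K2 / K1, rho = K3 / K1,
       k2 = if (k2r > 0) k2f / k2r else Inf,
       k4 = k4, q = 1 + k4)
}

#' Phospholock repression function
#'
#' Free activator of the repressor-phospholock mechanism, in which the
#' repressor complex R binds the activator and is then phosphorylated,
#' locking the pair together until dissociation at rate `k3`:
#' \deqn{f(R) = \frac{\tilde K_1 A_T - \tilde K_1 R - \tilde K_2 +
#'   \sqrt{(\tilde K_1 A_T + \tilde K_1 R + \tilde K_2)^2 -
#'   4 \tilde K_1^2 A_T R}}{2 \tilde K_1}}
#' with the effective constants of [effective_constants()].  `f(0) = A_T`,
#' `f` is strictly decreasing and tends to 0 as `R` grows.
#'
#' @param R repressor amount(s), non-negative (vectorised).
#' @param p a [phospholock_params()] object.
#' @return free activator, in `[0, A_T]`.
#' @examples
#' p <- phospholock_params_table1(k2 = 100)
#' phospholock_repression(c(0, 50, 98.9, 150), p)
#' @export
phospholock_repression <- function(R, p) {
  if (any(!is.finite(R)) || any(R < 0)) stop_domain("'R' must be finite and >= 0")
  ec <- effective_constants(p)
  if (ec$K1_tilde <= 0) stop_domain("K1_tilde must be > 0")
  cpp_free_activator(as.numeric(R), p$A_T, ec$Kd_eff, 1.0)
}

#' Phospholock repression with activator phosphorylation
#'
#' Extension of [phospholock_repression()] for the Neurospora-type mechanism
#' where the activator cycles between active and phosphorylated-inactive
#' forms (ratio `k4 = k4f/k4r`) and the dissociating phospholock complex
#' releases the activator in its inactive form:
#' \deqn{f(R) = \frac{\tilde K_1 A_T - \tilde K_3 R - \tilde K_2 (1+k_4) +
#'  \sqrt{(\tilde K_1 A_T + \tilde K_3 R + \tilde K_2 (1+k_4))^2 -
#'  4 \tilde K_1 \tilde K_3 A_T R}}{2 \tilde K_1 (1+k_4)}.}
#' At `R = 0` the free activator is `A_T / (1 + k4)`.  Because each
#' repressor molecule catalytically inactivates `rho = K3_tilde/K1_tilde`
#' activators per lock cycle, titration occurs near `R = A_T / rho`: with
#' large `rho` far fewer repressors than activators suffice.  With
#' `K3_tilde = K1_tilde` (for instance `k3 = 0`) and `k4 = 0` the function
#' coincides with [phospholock_repression()].
#'
#' @param R repressor amount(s), non-negative (vectorised).
#' @param p a [neurospora_params()] object.
#' @return free (unphosphorylated) activator, in `[0, A_T/(1+k4)]`.
#' @examples
#' p <- neurospora_params(k1f = 0.5, k1r = 5e-6, k2f = 1, k2r = 0.1,
#'                        k3 = 0.05, k4f = 0.3, k4r = 0.3)
#' neurospora_repression(c(0, 20), p)
#' @export
neurospora_repression <- function(R, p) {
  if (any(!is.finite(R)) || any(R < 0)) stop_domain("'R' must be finite and >= 0")
  ec <- effective_constants(p)
  cpp_free_activator(as.numeric(R) * ec$rho, p$A_T, ec$Kd_eff, ec$q)
}
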