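# Independent oracles used across the suite.  These deliberately avoid the
# closed-form quadratics they are used to check.

# Free activator at binding equilibrium A + S <-> AS with dissociation
# constant Kd, total activator A_T, total sequestrant S_T, found by
# bisection on the scalar mass balance A + A * S_free(A) / Kd = A_T.
bisect_free_activator <- function(S_T, A_T, Kd) {
  g <- function(A) {
    AS <- A_T - A                 # bound activator
    S_free <- S_T - AS
    A * S_free - Kd * AS          # equilibrium residual (scaled)
  }
  lo <- 0; hi <- A_T
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Equilibrium free (unphosphorylated) activator of the explicit phospholock
# mass-action subnetwork, by stiff relaxation of the bound-species ODE:
#   A + R <-> AR (k1f/k1r); AR <-> ARp (k2f/k2r);
#   repressor-only model (activator_phos = FALSE): ARp -> A + R (k3);
#   with activator phosphorylation: ARp -> Ap + R (k3),
#   A -> Ap (k4f), Ap -> A (k4r).
# States integrated: (AR, ARp, Ap); A and R follow from conservation.
relax_free_activator <- function(A_T, R_T, k1f, k1r, k2f, k2r, k3,
                                 k4f = 0, k4r = 1, activator_phos = FALSE,
                                 t_end = 4000) {
  rhs <- function(y) {
    AR <- y[1]; ARp <- y[2]; Ap <- y[3]
    A <- A_T - AR - ARp - Ap
    R <- R_T - AR - ARp
    c(k1f * A * R - k1r * AR - k2f * AR + k2r * ARp,
      k2f * AR - k2r * ARp - k3 * ARp,
      if (activator_phos) k4f * A - k4r * Ap + k3 * ARp else 0)
  }
  tr <- integrate_ode(rhs, init = c(AR = 0, ARp = 0, Ap = 0),
                      t_span = t_end, dt = t_end / 400,
                      rtol = 1e-10, atol = 1e-13, method = "ros23")
  y <- tr$states[nrow(tr$states), ]
  resid <- max(abs(rhs(y)))
  A <- A_T - sum(y)
  attr(A, "residual") <- resid
  A
}

# random phospholock micro-rate draw with rates bounded away from zero so
# the relaxation oracle converges on a fixed horizon
draw_micro_rates <- function() {
  list(k1f = runif(1, 0.05, 1), k1r = runif(1, 0.05, 1),
       k2f = runif(1, 0.05, 1), k2r = runif(1, 0.05, 1),
       k3 = runif(1, 0, 0.1),
       k4f = runif(1, 0.05, 1), k4r = runif(1, 0.05, 1))
}

# minimal hand-built reaction network (bypasses build_network) for SSA checks
toy_network <- function(species, reac, net, rates) {
  structure(list(species = species, reac = reac, net = net, rates = rates,
                 params = NULL,
                 reactions = data.frame(reaction = rep("", nrow(reac)),
                                        rate = rates)),
            class = "reaction_network")
}
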