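# Reconstructed mass-action model of the full KaiABC cycle.
#
# Nine species: free KaiA (A); KaiC phosphoforms U, T, ST, S free; ST and S
# captured by KaiB (BST, BS; KaiB binds only when the S431 site is
# phosphorylated and is treated as non-limiting); KaiBC complexes holding a
# sequestered KaiA (ABST, ABS).  Fourteen irreversible mass-action
# reactions; the ATP/ADP ratio scales the KaiA-stimulated phosphorylation
# step, and the CI-mutant switch (weak KaiB-KaiC binding) scales the KaiB
# capture rate by 1e-3.

DETAILED_SPECIES <- c("A", "U", "T", "ST", "S", "BST", "BS", "ABST", "ABS")

#' Detailed KaiABC model parameters
#'
#' Rate constants of the reconstructed KaiABC reaction network.  The
#' defaults are the package's calibrated baseline: they yield a limit
#' cycle with phosphorylation phase ~8.8 h, dephosphorylation phase
#' ~18.7 h, and a period that varies by under 5% across ATP fractions
#' 0.25..1 (see the vignette for the calibration and its status as a
#' stand-in for the unavailable published rate set).
#'
#' @param k_ut KaiA-stimulated U -> T phosphorylation (a.u.^-1 h^-1;
#'   scaled by `atp_ratio`).
#' @param k_ts T -> ST S431 autophosphorylation (h^-1).
#' @param k_b KaiB capture of S431-phosphorylated KaiC (h^-1; scaled by
#'   1e-3 when `ci_mutant`).
#' @param k_dt0 free-form T-site dephosphorylation ST -> S (h^-1).
#' @param k_su free-form S-site dephosphorylation S -> U (h^-1).
#' @param k_dt T-site dephosphorylation in KaiBC complexes (h^-1).
#' @param k_ds S-site dephosphorylation releasing KaiB (and KaiA) (h^-1).
#' @param k_on KaiA association to KaiBC hubs (a.u.^-1 h^-1).
#' @param Kd_seq dissociation constant of KaiA sequestration (a.u.).
#' @param A_T,C_T total KaiA and KaiC (a.u.).
#' @param atp_ratio ATP/(ATP+ADP), in (0, 1].
#' @param ci_mutant logical; weak KaiB-KaiC binding (CI cat-) variant.
#' @param explicit_kaib logical; track free KaiB as a species instead of
#'   treating it as non-limiting.  Capture becomes bimolecular at rate
#'   `k_b * B / B_T`, so with `B >> `captured pool the implicit model is
#'   recovered; smaller `B_T` makes KaiB limiting.
#' @param B_T total KaiB (a.u.), used only with `explicit_kaib`.
#' @return a `detailed_params` object.
#' @examples
#' detailed_params()
#' @export
detailed_params <- function(k_ut = 0.55, k_ts = 0.085, k_b = 0.085,
                            k_dt0 = 0.02, k_su = 0.02,
                            k_dt = 0.21, k_ds = 0.21,
                            k_on = 1000, Kd_seq = 1e-4,
                            A_T = 8, C_T = 40,
                            atp_ratio = 1, ci_mutant = FALSE,
                            explicit_kaib = FALSE, B_T = 400) {
  for (nm in c("k_ut", "k_ts", "k_b", "k_dt", "k_ds", "k_on"))
    check_scalar(get(nm), nm, 0, strict_min = TRUE)
  for (nm in c("k_dt0", "k_su", "Kd_seq"))
    check_scalar(get(nm), nm, 0)
  check_scalar(A_T, "A_T", 0, strict_min = TRUE)
  check_scalar(C_T, "C_T", 0, strict_min = TRUE)
  if (!is.numeric(atp_ratio) || atp_ratio <= 0 || atp_ratio > 1)
    stop_domain("'atp_ratio' must be in (0, 1]")
  check_scalar(B_T, "B_T", 0, strict_min = TRUE)
  new_params(list(k_ut = k_ut, k_ts = k_ts, k_b = k_b, k_dt0 = k_dt0,
                  k_su = k_su, k_dt = k_dt, k_ds = k_ds, k_on = k_on,
                  Kd_seq = Kd_seq, A_T = A_T, C_T = C_T,
                  atp_ratio = atp_ratio,
                  ci_mutant = isTRUE(ci_mutant),
                  explicit_kaib = isTRUE(explicit_kaib),
                  B_T = B_T), "detailed_params")
}

#' Rescale the ATP/ADP ratio of a detailed parameter set
#'
#' The ATP fraction enters the model as a multiplicative scale on the
#' KaiA-stimulated phosphorylation propensity (a modelling choice: lower
#' ATP slows the nucleotide-exchange-limited phosphorylation arm).
#' `atp_ratio = 1` returns the parameters unchanged.
#'
#' @param p a [detailed_params()] object.
#' @param atp_ratio new ATP fraction in (0, 1].
#' @return the parameter object with the new ratio.
#' @examples
#' atp_scaling(detailed_params(), 0.5)$atp_ratio
#' @export
atp_scaling <- function(p, atp_ratio) {
  stopifnot(inherits(p, "detailed_params"))
  if (!is.numeric(atp_ratio) || length(atp_ratio) != 1 ||
      atp_ratio <= 0 || atp_ratio > 1)
    stop_domain("'atp_ratio' must be in (0, 1]")
  p$atp_ratio <- atp_ratio
  p
}

#' Build the KaiABC reaction network
#'
#' Expands a [detailed_params()] object into an explicit mass-action
#' reaction network: KaiA-catalysed U -> T, slow T -> ST conversion, free
#' ST -> S dephosphorylation, KaiB capture of the S431-phosphorylated
#' forms, reversible KaiA sequestration by the KaiBC complexes, in-complex
#' dephosphorylation, and release of KaiB and KaiA on S431
#' dephosphorylation.  Total KaiC and total KaiA are conserved by every
#' reaction.
#'
#' @param p a [detailed_params()] object.
#' @return a `reaction_network`: species vector, reactant-order matrix,
#'   net stoichiometry matrix, rate vector and a human-readable reaction
#'   table.
#' @examples
#' net <- build_network(detailed_params())
#' net$reactions
#' @export
build_network <- function(p) {
  stopifnot(inherits(p, "detailed_params"))
  xb <- p$explicit_kaib %||% FALSE
  sp <- if (xb) c(DETAILED_SPECIES, "B") else DETAILED_SPECIES
  ci <- if (p$ci_mutant) 1e-3 else 1
  # with explicit KaiB, capture is bimolecular at k_b * B / B_T so that a
  # full KaiB pool reproduces the implicit (non-limiting) rates
  cap_rate <- if (xb) p$k_b * ci / p$B_T else p$k_b * ci
  cap_st <- if (xb) c(ST = 1, B = 1) else c(ST = 1)
  cap_s <- if (xb) c(S = 1, B = 1) else c(S = 1)
  rel_u <- if (xb) c(U = 1, B = 1) else c(U = 1)
  rel_ua <- if (xb) c(U = 1, A = 1, B = 1) else c(U = 1, A = 1)
  rx <- list(
    # name                          reactants      products       rate
    list("U + A -> T + A",          c(A=1, U=1),   c(A=1, T=1),   p$k_ut * p$atp_ratio),
    list("T -> ST",                 c(T=1),        c(ST=1),       p$k_ts),
    list("ST -> BST",               cap_st,        c(BST=1),      cap_rate),
    list("ST -> S",                 c(ST=1),       c(S=1),        p$k_dt0),
    list("S -> BS",                 cap_s,         c(BS=1),       cap_rate),
    list("S -> U",                  c(S=1),        c(U=1),        p$k_su),
    list("BST -> BS",               c(BST=1),      c(BS=1),       p$k_dt),
    list("A + BST -> ABST",         c(A=1, BST=1), c(ABST=1),     p$k_on),
    list("ABST -> A + BST",         c(ABST=1),     c(A=1, BST=1), p$k_on * p$Kd_seq),
    list("A + BS -> ABS",           c(A=1, BS=1),  c(ABS=1),      p$k_on),
    list("ABS -> A + BS",           c(ABS=1),      c(A=1, BS=1),  p$k_on * p$Kd_seq),
    list("ABST -> ABS",             c(ABST=1),     c(ABS=1),      p$k_dt),
    list("BS -> U",                 c(BS=1),       rel_u,         p$k_ds),
    list("ABS -> U + A",            c(ABS=1),      rel_ua,        p$k_ds)
  )
  nr <- length(rx); ns <- length(sp)
  reac <- matrix(0, nr, ns, dimnames = list(NULL, sp))
  net <- matrix(0, nr, ns, dimnames = list(NULL, sp))
  for (i in seq_len(nr)) {
    reac[i, names(rx[[i]][[2]])] <- rx[[i]][[2]]
    net[i, names(rx[[i]][[2]])] <- net[i, names(rx[[i]][[2]])] - rx[[i]][[2]]
    net[i, names(rx[[i]][[3]])] <- net[i, names(rx[[i]][[3]])] + rx[[i]][[3]]
  }
  rates <- vapply(rx, function(r) r[[4]], 0)
  structure(list(species = sp, reac = reac, net = net, rates = rates,
                 params = p,
                 reactions = data.frame(
                   reaction = vapply(rx, function(r) r[[1]], ""),
                   rate = rates)),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      nrow(x$reac), " reactions\n", sep = "")
  print(x$reactions, row.names = FALSE)
  invisible(x)
}

#' Mass-action right-hand side of a reaction network
#'
#' @param state named (or ordered) species vector.
#' @param network a [build_network()] result.
#' @return derivative vector, one entry per species.
#' @examples
#' net <- build_network(detailed_params())
#' rhs_detailed(setNames(rep(0, 9), net$species), net)  # all zero
#' @export
rhs_detailed <- function(state, network) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(state) != length(network$species))
    stop_domain("state dimension (", length(state),
                ") does not match the network (", length(network$species), ")")
  out <- cpp_massaction_rhs(as.numeric(state), network$reac, network$net,
                            network$rates)
  names(out) <- network$species
  out
}

detailed_init <- function(p) {
  init <- setNames(c(p$A_T, p$C_T, rep(0, 7)), DETAILED_SPECIES)
  if (isTRUE(p$explicit_kaib)) init <- c(init, B = p$B_T)
  init
}

#' Simulate the detailed KaiABC model deterministically
#'
#' @param p a [detailed_params()] object.
#' @param init named initial state; defaults to all KaiC unphosphorylated
#'   and all KaiA free.
#' @param t_end,dt horizon and output spacing (h).
#' @param rtol,atol tolerances.
#' @return a `clock_trajectory` over the nine species.
#' @examples
#' tr <- simulate_detailed(detailed_params(), t_end = 120)
#' @export
simulate_detailed <- function(p, init = NULL, t_end = 720, dt = 0.05,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "detailed_params"))
  net <- build_network(p)
  if (is.null(init)) init <- detailed_init(p)
  out <- cpp_integrate_model(4L, numeric(0), as.numeric(init), 0, t_end, dt,
                             rtol, atol, TRUE, net$reac, net$net, net$rates)
  if (!isTRUE(out$ok)) stop("integration failed: ", out$message, call. = FALSE)
  colnames(out$states) <- net$species
  colnames(out$derivs) <- net$species
  new_trajectory(out$times, out$states, out$derivs, out$nclip)
}

#' Phosphorylated KaiC fraction of a detailed-model trajectory
#'
#' The fraction of total KaiC carrying at least one phosphate, i.e. all
#' T/ST/S forms summed over the free, KaiB-bound and KaiAB-bound classes,
#' divided by total KaiC.
#'
#' @param traj trajectory from [simulate_detailed()] or [gillespie()].
#' @return numeric series in `[0, 1]`, one value per time point.
#' @export
phospho_fraction <- function(traj) {
  stopifnot(inherits(traj, "clock_trajectory"))
  st <- traj$states
  need <- c("T", "ST", "S", "BST", "BS", "ABST", "ABS", "U")
  if (!all(need %in% colnames(st)))
    stop_domain("trajectory lacks detailed-model species columns")
  phos <- rowSums(st[, c("T", "ST", "S", "BST", "BS", "ABST", "ABS"), drop = FALSE])
  total <- phos + st[, "U"]
  phos / total
}

#' Exact stochastic simulation of a reaction network
#'
#' Direct-method Gillespie simulation at integer molecule counts.
#' Concentrations map to counts through the volume factor `omega`
#' (counts = concentration x omega); bimolecular propensities are scaled
#' by `1/omega` accordingly.  Reproducible: the same seed gives the same
#' path.
#'
#' @param network a [build_network()] result (rates in concentration
#'   units).
#' @param init named initial counts; defaults to the rounded deterministic
#'   start `omega * (A_T, C_T, 0, ...)`.
#' @param t_end horizon (h).
#' @param seed integer RNG seed.
#' @param omega system-size (volume) factor.
#' @param dt_record recording grid spacing (h).
#' @param max_events safety cap on the number of reaction events.
#' @return a `clock_trajectory` of counts.
#' @examples
#' net <- build_network(detailed_params())
#' tr <- gillespie(net, t_end = 48, seed = 1, omega = 2)
#' @export
gillespie <- function(network, init = NULL, t_end = 240, seed = 1,
                      omega = 1, dt_record = 0.1, max_events = 5e7) {
  stopifnot(inherits(network, "reaction_network"))
  if (nrow(network$reac) == 0) stop_domain("empty reaction network")
  check_scalar(omega, "omega", 0, strict_min = TRUE)
  if (is.null(init)) {
    p <- network$params
    init <- round(detailed_init(p) * omega)
  }
  if (length(init) != length(network$species))
    stop_domain("'init' must have one count per species")
  if (any(init < 0) || any(init != round(init)))
    stop_domain("'init' must be non-negative integer counts")
  order_tot <- rowSums(network$reac)
  rates <- network$rates * omega^(1 - order_tot)   # propensity scaling
  out <- with_seed(seed, cpp_gillespie(network$reac, network$net, rates,
                                       as.numeric(init), t_end, dt_record,
                                       max_events))
  colnames(out$counts) <- network$species
  tr <- new_trajectory(out$times, out$counts)
  attr(tr, "n_events") <- out$n_events
  attr(tr, "omega") <- omega
  tr
}

#' Export a reaction network as flat text
#'
#' Writes a simple SBML-like plain-text description (species block and
#' reaction block with rate constants), convenient for diffing and
#' archiving.
#'
#' @param network a [build_network()] result.
#' @param file path.
#' @return the path, invisibly.
#' @export
write_network_text <- function(network, file) {
  stopifnot(inherits(network, "reaction_network"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# mass-action reaction network", con)
  writeLines(paste("species:", paste(network$species, collapse = " ")), con)
  writeLines("reactions:", con)
  for (i in seq_len(nrow(network$reac)))
    writeLines(sprintf("  %-22s k = %s", network$reactions$reaction[i],
                       fmt_num(network$rates[i], 6)), con)
  invisible(file)
}
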