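# Seeded Monte-Carlo parameter samplers.
#
# Every sampler is a pure function of (scheme, seed): identical inputs give
# bitwise-identical tables.  Derived-parameter rules (k1r = Kd * k1f, paired
# multipliers, ...) are applied exactly once, after sampling.  Where the
# published sampling ranges are unavailable the package ships documented
# stand-in defaults (see the vignette); each is overridable here.

#' Stand-in sampling ranges for the core model
#'
#' Free parameters of the core-model scans: `k1`, `A_T` and `C_T` are drawn
#' uniformly from these ranges while `k2, k3, k4` stay fixed at the values
#' in [core_params()].  Stand-in for the unavailable published table;
#' chosen so the oscillating region at `Kd = 1e-4` is substantial and the
#' default parameter set keeps a circadian period.
#'
#' @return named list of `c(lo, hi)` ranges.
#' @export
core_ranges <- function() {
  list(k1 = c(0, 1), A_T = c(0, 50), C_T = c(0, 200))
}

#' Stand-in sampling ranges for the TTFL/PTR comparison
#'
#' Only the translation rate `K_s` and total KaiA `A_T` vary; all other
#' parameters are fixed at the [ttfl_params()] defaults.  Stand-in for the
#' unavailable published table, calibrated once so that the paired
#' TTFL/PTR comparison reproduces the direction and approximate magnitude
#' of the published oscillating fractions (see the vignette).
#'
#' @return named list of `c(lo, hi)` ranges.
#' @export
ttfl_ranges <- function() {
  list(K_s = c(0, 1), A_T = c(4, 50))
}

check_ranges <- function(ranges, names_needed) {
  if (!all(names_needed %in% names(ranges)))
    stop_domain("ranges must define ", paste(names_needed, collapse = ", "))
  for (nm in names_needed) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
      stop_domain("invalid range for '", nm, "': need finite c(lo, hi), lo < hi")
  }
  invisible(ranges)
}

#' Sample core-model parameter sets at a given binding affinity
#'
#' Draws `n` core-model parameter sets with `k1`, `A_T`, `C_T` uniform in
#' the given ranges and `k2, k3, k4` fixed, at dissociation constant `Kd`.
#'
#' @param Kd KaiA-KaiC(S) dissociation constant (scans span 1e-4..1e-1).
#' @param n number of sets.
#' @param seed integer seed.
#' @param ranges ranges list, see [core_ranges()].
#' @param fixed named list of the fixed rates (`k2`, `k3`, `k4`).
#' @return data frame with one row per set, columns
#'   `k1, k2, k3, k4, Kd, A_T, C_T`.
#' @examples
#' head(sample_core(1e-4, n = 5, seed = 1))
#' @export
sample_core <- function(Kd, n, seed, ranges = core_ranges(),
                        fixed = list(k2 = 0.13, k3 = 0.13, k4 = 0.13)) {
  check_scalar(Kd, "Kd", 0, strict_min = TRUE)
  stopifnot(n >= 1)
  check_ranges(ranges, c("k1", "A_T", "C_T"))
  with_seed(seed, {
    data.frame(
      k1 = runif(n, ranges$k1[1], ranges$k1[2]),
      k2 = fixed$k2, k3 = fixed$k3, k4 = fixed$k4,
      Kd = Kd,
      A_T = runif(n, ranges$A_T[1], ranges$A_T[2]),
      C_T = runif(n, ranges$C_T[1], ranges$C_T[2])
    )
  })
}

#' Sample the paired TTFL/PTR parameter table
#'
#' Draws `n` parameter sets varying only `K_s` and `A_T`; the same table
#' drives both transcription modes, so the TTFL/PTR comparison is paired
#' row by row.
#'
#' @param n number of sets (the published comparison used 22,500).
#' @param seed integer seed.
#' @param ranges ranges list, see [ttfl_ranges()].
#' @param fixed named list overriding any fixed [ttfl_params()] argument.
#' @return data frame with the full parameter columns, one row per set.
#' @examples
#' head(sample_ttfl(n = 5, seed = 1))
#' @export
sample_ttfl <- function(n = 22500, seed = 1, ranges = ttfl_ranges(),
                        fixed = list()) {
  stopifnot(n >= 1)
  check_ranges(ranges, c("K_s", "A_T"))
  base <- formals(ttfl_params)
  fx <- modifyList(list(V_trsp = eval(base$V_trsp), V_m = eval(base$V_m),
                        K_0 = eval(base$K_0), k1 = eval(base$k1),
                        k2 = eval(base$k2), k3 = eval(base$k3),
                        k4 = eval(base$k4), V_d = eval(base$V_d),
                        Kd = eval(base$Kd)), fixed)
  with_seed(seed, {
    data.frame(
      V_trsp = fx$V_trsp, V_m = fx$V_m,
      K_s = runif(n, ranges$K_s[1], ranges$K_s[2]),
      K_0 = fx$K_0, k1 = fx$k1, k2 = fx$k2, k3 = fx$k3, k4 = fx$k4,
      V_d = fx$V_d, Kd = fx$Kd,
      A_T = runif(n, ranges$A_T[1], ranges$A_T[2])
    )
  })
}

#' Sample phospholock parameter sets
#'
#' The published scheme: `A_T`, `alpha1, beta1, ..., alpha3, beta3` uniform
#' on (0, 100); `k1f` and `k2f` uniform on (0, 1); `k1r = k1f` so that
#' `Kd = 1` before any multiplier is applied; `k3` uniform on (0, 0.1).
#' `k2r` is initialised to `k2f` and is meant to be rescaled with
#' [apply_phospho_multiplier()] for the phosphorylation-strength sweep.
#' Random initial conditions (uniform on (0, 10], one triple per row) are
#' drawn alongside so that paired sweeps reuse them.
#'
#' @param n number of sets.
#' @param seed integer seed.
#' @return data frame of parameter rows plus `init_M, init_r, init_R`.
#' @examples
#' tab <- sample_phospholock(n = 3, seed = 1)
#' all(tab$k1r == tab$k1f)
#' @export
sample_phospholock <- function(n = 1e4, seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    tab <- data.frame(
      A_T = runif(n, 0, 100),
      alpha1 = runif(n, 0, 100), beta1 = runif(n, 0, 100),
      alpha2 = runif(n, 0, 100), beta2 = runif(n, 0, 100),
      alpha3 = runif(n, 0, 100), beta3 = runif(n, 0, 100),
      k1f = runif(n, 0, 1), k2f = runif(n, 0, 1),
      k3 = runif(n, 0, 0.1)
    )
    tab$k1r <- tab$k1f            # Kd = 1
    tab$k2r <- tab$k2f
    tab$init_M <- runif(n, 0, 10)
    tab$init_r <- runif(n, 0, 10)
    tab$init_R <- runif(n, 0, 10)
    tab
  })
}

#' Rescale the dephosphorylation rate of a phospholock table
#'
#' Applies the sweep rule `k2r = multiplier * k2f` (multiplier 100 is the
#' strongest dephosphorylation, 1e-4 the strongest phosphorylation); all
#' other columns are untouched, so tables derived with different
#' multipliers stay row-paired.
#'
#' @param tab table from [sample_phospholock()].
#' @param multiplier positive scalar.
#' @return the table with `k2r` replaced.
#' @export
apply_phospho_multiplier <- function(tab, multiplier) {
  check_scalar(multiplier, "multiplier", 0, strict_min = TRUE)
  tab$k2r <- multiplier * tab$k2f
  tab
}

#' Rejection-sample oscillating parameter sets of the activator-phosphorylation model
#'
#' Draws parameter sets of the phospholock model with activator
#' phosphorylation under the published constraints -- `Kd = 1e-5`
#' (`k1r = 1e-5 k1f`), phosphorylation ten times stronger than
#' dephosphorylation (`k2f = 10 k2r`), balanced activator phosphorylation
#' (`k4r = k4f`), `k3` fixed -- and keeps those that oscillate under the
#' event-location criterion, until `target` oscillating sets are found.
#'
#' @param target number of oscillating sets required.
#' @param k3_value fixed dissociation/degradation rate of the
#'   phosphorylated complex.
#' @param seed integer seed.
#' @param Kd dissociation constant constraint (`k1r = Kd * k1f`).
#' @param k2_ratio phosphorylation-strength constraint (`k2f = k2_ratio * k2r`).
#' @param max_draws draw budget; exceeding it is an error reporting the
#'   acceptance rate.
#' @param horizon,dt event-detection settings, see
#'   [detect_oscillation_events()].
#' @return data frame of the accepted parameter rows (with their initial
#'   conditions and detected periods); attributes `draws` and
#'   `acceptance_rate`.
#' @examples
#' \donttest{
#' tab <- sample_until_oscillating(target = 5, k3_value = 0, seed = 1)
#' attr(tab, "acceptance_rate")
#' }
#' @export
sample_until_oscillating <- function(target = 100, k3_value = 0, seed = 1,
                                     Kd = 1e-5, k2_ratio = 10,
                                     max_draws = 600 * target,
                                     horizon = 300, dt = 0.1) {
  stopifnot(target >= 1)
  check_scalar(k3_value, "k3_value", 0)
  rows <- vector("list", target)
  found <- 0L
  draws <- 0L
  with_seed(seed, {
    while (found < target && draws < max_draws) {
      draws <- draws + 1L
      u <- runif(7, 0, 100)                 # A_T, alpha/beta chain
      k1f <- runif(1); k2r <- runif(1); k4f <- runif(1)
      init <- runif(3, 0, 10)
      p <- neurospora_params(alpha1 = u[2], beta1 = u[3], alpha2 = u[4],
                             beta2 = u[5], alpha3 = u[6], beta3 = u[7],
                             A_T = u[1],
                             k1f = k1f, k1r = Kd * k1f,
                             k2f = k2_ratio * k2r, k2r = k2r,
                             k3 = k3_value, k4f = k4f, k4r = k4f)
      v <- detect_oscillation_events(p, init = init, horizon = horizon, dt = dt)
      if (v$oscillating) {
        found <- found + 1L
        rows[[found]] <- data.frame(
          A_T = u[1], alpha1 = u[2], beta1 = u[3], alpha2 = u[4],
          beta2 = u[5], alpha3 = u[6], beta3 = u[7],
          k1f = k1f, k1r = Kd * k1f, k2f = k2_ratio * k2r, k2r = k2r,
          k3 = k3_value, k4f = k4f, k4r = k4f,
          init_M = init[1], init_r = init[2], init_R = init[3],
          period = v$period)
      }
    }
  })
  if (found < target)
    stop(sprintf(paste0("draw budget exhausted: %d oscillating sets in %d ",
                        "draws (acceptance rate %.3f%%); raise max_draws"),
                 found, draws, 100 * found / draws), call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "draws") <- draws
  attr(out, "acceptance_rate") <- found / draws
  out
}

#' Write / read a sampling scheme as YAML
#'
#' A scheme is a plain list (model name, fixed values, uniform ranges,
#' derived rules, count, seed); these helpers give it a flat-file round
#' trip.
#'
#' @param scheme named list.
#' @param file path.
#' @return `read_scheme_yaml` returns the list.
#' @export
write_scheme_yaml <- function(scheme, file) {
  yaml::write_yaml(scheme, file)
  invisible(file)
}

#' @rdname write_scheme_yaml
#' @export
read_scheme_yaml <- function(file) yaml::read_yaml(file)
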