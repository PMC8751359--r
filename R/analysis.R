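# Headline analyses: oscillation-region scans, stoichiometric conditions,
# sensitivity curves and steady-state stoichiometric ratios.

binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)

# classify one core/TTFL parameter row spectrally
classify_fft_row <- function(p, t_end, dt, ...) {
  tr <- simulate_model(p, t_end = t_end, dt = dt)
  detect_oscillation_fft(tr, species = model_spec(p)$monitor, ...)
}

#' Oscillating fraction of the core model across binding affinities
#'
#' For each dissociation constant on a (by default 14-point, 1e-4..1e-1
#' log-spaced) grid, draws `n` core-model parameter sets and classifies
#' each spectrally, reporting the oscillating fraction with its binomial
#' standard error and a Spearman trend test across the grid.
#'
#' @param kd_grid dissociation-constant grid.
#' @param n parameter sets per grid point (the published scan used 1e5;
#'   scale down for desk runs).
#' @param seed master seed; each grid point gets a substream.
#' @param ranges sampling ranges, see [core_ranges()].
#' @param t_end,dt simulation horizon and output spacing.
#' @return a list with `summary` (per-Kd fractions and standard errors),
#'   `rows` (every parameter set with its verdict and period),
#'   `trend` (Spearman rho and p-value), class `kd_sweep`.
#' @examples
#' \donttest{
#' sw <- kd_sweep_core(kd_grid = c(1e-4, 1e-2), n = 50, seed = 1)
#' sw$summary
#' }
#' @export
kd_sweep_core <- function(kd_grid = logspace(1e-4, 1e-1, 14), n = 1e5,
                          seed = 1, ranges = core_ranges(),
                          t_end = 400, dt = 0.1) {
  stopifnot(all(kd_grid > 0), n >= 1)
  rows <- vector("list", length(kd_grid))
  for (i in seq_along(kd_grid)) {
    tab <- sample_core(kd_grid[i], n = n, seed = substream_seed(seed, i),
                       ranges = ranges)
    osc <- logical(n); per <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      p <- core_params(k1 = tab$k1[j], k2 = tab$k2[j], k3 = tab$k3[j],
                       k4 = tab$k4[j], Kd = tab$Kd[j],
                       A_T = tab$A_T[j], C_T = tab$C_T[j])
      v <- classify_fft_row(p, t_end, dt)
      osc[j] <- v$oscillating
      per[j] <- v$period
    }
    tab$oscillating <- osc
    tab$period <- per
    rows[[i]] <- tab
  }
  rows <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(kd_grid, function(kd) {
    sub <- rows[rows$Kd == kd, ]
    f <- mean(sub$oscillating)
    data.frame(Kd = kd, n = nrow(sub), n_osc = sum(sub$oscillating),
               fraction = f, se = binom_se(f, nrow(sub)))
  }))
  trend <- if (length(kd_grid) >= 4) {
    ct <- suppressWarnings(cor.test(summary$Kd, summary$fraction,
                                    method = "spearman"))
    list(rho = unname(ct$estimate), p_value = ct$p.value)
  } else list(rho = NA_real_, p_value = NA_real_)
  structure(list(summary = summary, rows = rows, trend = trend,
                 seed = seed), class = "kd_sweep")
}

#' Check the stoichiometric balance condition on scan results
#'
#' Oscillations of the core model require total KaiC to exceed total KaiA
#' by a margin set by the phosphorylation/dephosphorylation rates:
#' `C_T > (1 + r) A_T` (strict inequality; with the package defaults
#' `r = 2`, i.e. `C_T > 3 A_T`).  This reports how many oscillating
#' parameter sets satisfy the condition, with the margins of any
#' violators, and the converse count showing the condition is necessary
#' but not sufficient.
#'
#' @param scan a `kd_sweep` result or a data frame of rows carrying
#'   `A_T`, `C_T` and `oscillating`.
#' @param r_const the rate-ratio constant `r` (default 2).
#' @return a list: `fraction_compliant` among oscillating rows, data frame
#'   of `violators`, and `n_quiet_compliant`, the number of
#'   condition-satisfying rows that nonetheless do not oscillate.
#' @export
stoich_condition_check <- function(scan, r_const = 2) {
  rows <- if (inherits(scan, "kd_sweep")) scan$rows else scan
  stopifnot(all(c("A_T", "C_T", "oscillating") %in% names(rows)))
  osc <- rows[rows$oscillating, ]
  compliant <- osc$C_T > (1 + r_const) * osc$A_T
  violators <- osc[!compliant, , drop = FALSE]
  if (nrow(violators))
    violators$margin <- violators$C_T - (1 + r_const) * violators$A_T
  quiet <- rows[!rows$oscillating, ]
  list(r_const = r_const,
       n_oscillating = nrow(osc),
       fraction_compliant = if (nrow(osc)) mean(compliant) else NA_real_,
       violators = violators,
       n_quiet_compliant = sum(quiet$C_T > (1 + r_const) * quiet$A_T))
}

#' Paired TTFL vs PTR oscillating fractions
#'
#' Simulates the transcription-translation-feedback (TTFL) and
#' constitutive-transcription (PTR) variants of the extended core model on
#' the same parameter table (only `K_s` and `A_T` vary) and reports the
#' paired oscillating fractions.
#'
#' @param n number of paired parameter sets (published comparison: 22,500).
#' @param seed integer seed.
#' @param ranges sampling ranges, see [ttfl_ranges()].
#' @param t_end,dt simulation settings.
#' @return a list with `fraction_ttfl`, `fraction_ptr` (and standard
#'   errors), and `rows`, the paired per-set verdicts, class
#'   `ttfl_ptr_comparison`.
#' @examples
#' \donttest{
#' cmp <- ttfl_vs_ptr(n = 50, seed = 1)
#' c(cmp$fraction_ttfl, cmp$fraction_ptr)
#' }
#' @export
ttfl_vs_ptr <- function(n = 22500, seed = 1, ranges = ttfl_ranges(),
                        t_end = 400, dt = 0.1) {
  tab <- sample_ttfl(n = n, seed = seed, ranges = ranges)
  res <- list()
  for (mode in c("TTFL", "PTR")) {
    osc <- logical(n); per <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      p <- ttfl_params(V_trsp = tab$V_trsp[j], V_m = tab$V_m[j],
                       K_s = tab$K_s[j], K_0 = tab$K_0[j], k1 = tab$k1[j],
                       k2 = tab$k2[j], k3 = tab$k3[j], k4 = tab$k4[j],
                       V_d = tab$V_d[j], Kd = tab$Kd[j], A_T = tab$A_T[j],
                       mode = mode)
      v <- classify_fft_row(p, t_end, dt)
      osc[j] <- v$oscillating; per[j] <- v$period
    }
    res[[mode]] <- list(osc = osc, per = per)
  }
  tab$osc_ttfl <- res$TTFL$osc
  tab$period_ttfl <- res$TTFL$per
  tab$osc_ptr <- res$PTR$osc
  tab$period_ptr <- res$PTR$per
  structure(list(
    n = n,
    fraction_ttfl = mean(tab$osc_ttfl),
    se_ttfl = binom_se(mean(tab$osc_ttfl), n),
    fraction_ptr = mean(tab$osc_ptr),
    se_ptr = binom_se(mean(tab$osc_ptr), n),
    rows = tab, seed = seed), class = "ttfl_ptr_comparison")
}

#' Oscillation fraction across binding affinity and phosphorylation strength
#'
#' The phospholock robustness surface: for each dissociation constant in
#' `kd_grid` draws a phospholock parameter table (`k1r = Kd * k1f`), then
#' re-simulates the same table for every dephosphorylation multiplier
#' (`k2r = multiplier * k2f`; multiplier 100 = strongest dephosphorylation,
#' 1e-4 = strongest phosphorylation), classifying each run with the
#' event-location criterion.  Rows are paired across multipliers: the same
#' parameter draws and initial conditions are reused.
#'
#' @param kd_grid binding-affinity grid.
#' @param multipliers `k2r/k2f` multiplier grid, strongest dephosphorylation
#'   first.
#' @param n parameter sets per Kd (published: 1e4).
#' @param seed master seed (substream per Kd).
#' @param horizon,dt event-detection settings.
#' @return a list with `percent` (matrix, Kd x multiplier, oscillating
#'   percentage) and `counts`, class `phospho_sweep`.
#' @examples
#' \donttest{
#' sw <- phospho_strength_sweep(kd_grid = 1, multipliers = c(100, 1e-4),
#'                              n = 50, seed = 1)
#' sw$percent
#' }
#' @export
phospho_strength_sweep <- function(kd_grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
                                   multipliers = c(100, 10, 1, 0.1, 0.01,
                                                   1e-3, 1e-4),
                                   n = 1e4, seed = 1,
                                   horizon = 300, dt = 0.1) {
  stopifnot(all(kd_grid > 0), all(multipliers > 0), n >= 1)
  counts <- matrix(0L, length(kd_grid), length(multipliers),
                   dimnames = list(fmt_num(kd_grid), fmt_num(multipliers)))
  for (i in seq_along(kd_grid)) {
    base <- sample_phospholock(n = n, seed = substream_seed(seed, i))
    base$k1r <- kd_grid[i] * base$k1f
    for (m in seq_along(multipliers)) {
      tab <- apply_phospho_multiplier(base, multipliers[m])
      nosc <- 0L
      for (j in seq_len(n)) {
        p <- phospholock_params(alpha1 = tab$alpha1[j], beta1 = tab$beta1[j],
                                alpha2 = tab$alpha2[j], beta2 = tab$beta2[j],
                                alpha3 = tab$alpha3[j], beta3 = tab$beta3[j],
                                A_T = tab$A_T[j], k1f = tab$k1f[j],
                                k1r = tab$k1r[j], k2f = tab$k2f[j],
                                k2r = tab$k2r[j], k3 = tab$k3[j])
        v <- detect_oscillation_events(
          p, init = c(tab$init_M[j], tab$init_r[j], tab$init_R[j]),
          horizon = horizon, dt = dt)
        if (v$oscillating) nosc <- nosc + 1L
      }
      counts[i, m] <- nosc
    }
  }
  structure(list(kd_grid = kd_grid, multipliers = multipliers, n = n,
                 counts = counts, percent = 100 * counts / n, seed = seed),
            class = "phospho_sweep")
}

#' Log-log sensitivity of a repression function
#'
#' Computes `d log f / d log x` by centred finite differences on a
#' (typically log-spaced) grid -- the "order of reaction" of the
#' repression function; larger peak magnitude means a sharper titration
#' cusp and favours oscillations.
#'
#' @param f function of one argument, positive on the grid interior
#'   (points where `f <= 0` are truncated with a warning).
#' @param grid abscissa values, strictly increasing.
#' @return a data frame `x`, `f`, `sensitivity` with attributes
#'   `peak` (maximum `|sensitivity|`) and `peak_x` (its location), class
#'   `sensitivity_curve`.
#' @examples
#' sc <- sensitivity_curve(function(x) 1 / x, grid = exp(seq(0, 3, 0.1)))
#' range(sc$sensitivity)   # identically -1 for a power law
#' @export
sensitivity_curve <- function(f, grid) {
  stopifnot(is.function(f), length(grid) >= 3, all(diff(grid) > 0),
            all(grid > 0))
  fv <- vapply(grid, f, 0)
  pos <- fv > 0
  if (!all(pos)) {
    warning("f <= 0 on part of the grid; domain truncated", call. = FALSE)
    keep <- which(pos)
    grid <- grid[keep]; fv <- fv[keep]
    if (length(grid) < 3) stop_domain("fewer than 3 positive points remain")
  }
  lx <- log(grid); lf <- log(fv)
  n <- length(grid)
  s <- rep(NA_real_, n)
  s[2:(n - 1)] <- (lf[3:n] - lf[1:(n - 2)]) / (lx[3:n] - lx[1:(n - 2)])
  s[1] <- (lf[2] - lf[1]) / (lx[2] - lx[1])
  s[n] <- (lf[n] - lf[n - 1]) / (lx[n] - lx[n - 1])
  out <- data.frame(x = grid, f = fv, sensitivity = s)
  ipk <- which.max(abs(s))
  attr(out, "peak") <- abs(s[ipk])
  attr(out, "peak_x") <- grid[ipk]
  class(out) <- c("sensitivity_curve", class(out))
  out
}

#' Steady-state repressor level and stoichiometric ratio
#'
#' Solves the fixed-point equation of the repressor chain,
#' `f(R) = (beta1 beta2 beta3 / (alpha1 alpha2 alpha3)) R`, whose left side
#' is the repression function (free activator) and whose right side is the
#' linear drain through the chain.  The left side is bounded and the right
#' side increases without bound, so a bracketing root always exists on
#' `[0, A_T * alpha1 alpha2 alpha3 / (beta1 beta2 beta3) + 1]`.  The
#' stoichiometric ratio is `S = R* / A_T`.
#'
#' @param p a [phospholock_params()] or [neurospora_params()] object.
#' @param tol root tolerance.
#' @return list with `R_star`, `S_ratio` and the equation `residual`.
#' @examples
#' p <- neurospora_params(k3 = 0.5)
#' steady_state_repressor(p)
#' @export
steady_state_repressor <- function(p, tol = 1e-12) {
  stopifnot(inherits(p, "phospholock_params") ||
            inherits(p, "kim_forger_params"))
  A_T <- if (!is.null(p$A_T)) p$A_T else p$A
  b <- (p$beta1 * p$beta2 * p$beta3) / (p$alpha1 * p$alpha2 * p$alpha3)
  g <- function(R) repression_value(R, p) - b * R
  hi <- A_T / b + 1
  if (g(0) <= 0) return(list(R_star = 0, S_ratio = 0, residual = g(0)))
  if (g(hi) >= 0)
    stop("bracketing failure: no sign change on [0, ", fmt_num(hi), "]",
         call. = FALSE)
  root <- uniroot(g, c(0, hi), tol = tol)
  R_star <- root$root
  list(R_star = R_star, S_ratio = R_star / A_T, residual = g(R_star))
}

#' Stoichiometric-ratio distributions across k3
#'
#' For each `k3` on the grid, rejection-samples `target` oscillating
#' parameter sets of the activator-phosphorylation phospholock model
#' ([sample_until_oscillating()]) and computes each set's steady-state
#' stoichiometric ratio.  Reports the per-`k3` ratio distribution, its
#' range and its minimum -- the quantities behind the claim that activator
#' phosphorylation widens the admissible repressor-to-activator
#' stoichiometry as `k3` grows.
#'
#' @param k3_grid `k3` values, including 0.
#' @param target oscillating sets per grid value.
#' @param seed master seed (substream per `k3`).
#' @param ... passed to [sample_until_oscillating()].
#' @return a list with `summary` (per-k3 min/max/range), `ratios` (list of
#'   ratio vectors) and `tables` (accepted parameter rows), class
#'   `stoich_ratio_scan`.
#' @examples
#' \donttest{
#' sc <- stoich_ratio_distribution(k3_grid = c(0, 1.9), target = 5, seed = 1)
#' sc$summary
#' }
#' @export
stoich_ratio_distribution <- function(k3_grid = c(0, 0.1, 1.9),
                                      target = 100, seed = 1, ...) {
  stopifnot(length(k3_grid) >= 1, all(k3_grid >= 0))
  ratios <- list(); tables <- list()
  for (i in seq_along(k3_grid)) {
    tab <- sample_until_oscillating(target = target, k3_value = k3_grid[i],
                                    seed = substream_seed(seed, i), ...)
    r <- numeric(nrow(tab))
    for (j in seq_len(nrow(tab))) {
      p <- neurospora_params(alpha1 = tab$alpha1[j], beta1 = tab$beta1[j],
                             alpha2 = tab$alpha2[j], beta2 = tab$beta2[j],
                             alpha3 = tab$alpha3[j], beta3 = tab$beta3[j],
                             A_T = tab$A_T[j], k1f = tab$k1f[j],
                             k1r = tab$k1r[j], k2f = tab$k2f[j],
                             k2r = tab$k2r[j], k3 = tab$k3[j],
                             k4f = tab$k4f[j], k4r = tab$k4r[j])
      r[j] <- steady_state_repressor(p)$S_ratio
    }
    tab$S_ratio <- r
    key <- fmt_num(k3_grid[i])
    ratios[[key]] <- r
    tables[[key]] <- tab
  }
  summary <- data.frame(
    k3 = k3_grid,
    n = vapply(ratios, length, 0L),
    min = vapply(ratios, min, 0),
    max = vapply(ratios, max, 0),
    range = vapply(ratios, function(x) diff(range(x)), 0),
    draws = vapply(tables, function(t) attr(t, "draws"), 0)
  )
  structure(list(summary = summary, ratios = ratios, tables = tables,
                 seed = seed), class = "stoich_ratio_scan")
}
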