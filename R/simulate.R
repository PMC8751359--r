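# Integration and oscillation classification.

new_trajectory <- function(times, states, derivs = NULL, nclip = 0) {
  structure(list(times = times, states = states, derivs = derivs,
                 nclip = nclip),
            class = "clock_trajectory")
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat("<clock_trajectory> ", nrow(x$states), " points, t = ",
      fmt_num(min(x$times)), "..", fmt_num(max(x$times)), " h, species: ",
      paste(colnames(x$states), collapse = ", "), "\n", sep = "")
  if (x$nclip > 0)
    cat("  (", x$nclip, " sub-1e-12 negative values clipped to 0)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.clock_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Integrate an ODE system to a uniform time grid
#'
#' Adaptive integration with dense output on a uniform grid.  `rhs` is
#' either a clock parameter object (native, fast path) or an R function
#' `function(y)` returning the autonomous derivative vector.  Two methods
#' are available: `"ros23"`, a stiff-capable Rosenbrock pair (the package's
#' workhorse for the clock models, whose repression cusps make them stiff at
#' tight effective affinities), and `"dopri5"`, a fifth-order explicit
#' Dormand-Prince pair for non-stiff work.  The defaults meet relative
#' tolerance 1e-6 and absolute tolerance 1e-9.
#'
#' @param rhs clock parameter object or `function(y) -> dy`.
#' @param init named initial state; defaults to the model's standard start.
#' @param t_span end time (scalar) or `c(t0, t1)` in hours.
#' @param dt output grid spacing (h).
#' @param rtol,atol relative/absolute tolerances.
#' @param method `"auto"` (ros23 for models, dopri5 for R functions),
#'   `"ros23"` or `"dopri5"`.
#' @return a `clock_trajectory` with `times`, `states` (matrix, one column
#'   per species), `derivs` (right-hand side at the grid nodes) and `nclip`
#'   (count of clipped sub-1e-12 negatives).
#' @examples
#' tr <- integrate_ode(function(y) -y, init = c(x = 1), t_span = 1, dt = 0.1)
#' tr$states[nrow(tr$states), "x"]   # ~ exp(-1)
#' @export
integrate_ode <- function(rhs, init = NULL, t_span = 400, dt = 0.05,
                          rtol = 1e-6, atol = 1e-9,
                          method = c("auto", "ros23", "dopri5")) {
  method <- match.arg(method)
  if (length(t_span) == 1L) t_span <- c(0, t_span)
  if (!is.numeric(t_span) || length(t_span) != 2L || t_span[2] <= t_span[1])
    stop_domain("'t_span' must be a positive horizon or an increasing pair")
  check_scalar(dt, "dt", 0, strict_min = TRUE)

  if (inherits(rhs, "clock_params")) {
    sp <- model_spec(rhs)
    if (is.null(init)) init <- sp$init
    if (length(init) != length(sp$states))
      stop_domain("'init' must have ", length(sp$states), " components")
    if (any(!is.finite(init))) stop_domain("'init' must be finite")
    stiff <- method %in% c("auto", "ros23")
    out <- cpp_integrate_model(sp$id, sp$pars, as.numeric(init),
                               t_span[1], t_span[2], dt, rtol, atol, stiff)
    states_names <- sp$states
  } else if (is.function(rhs)) {
    if (is.null(init)) stop_domain("'init' is required for a function rhs")
    if (any(!is.finite(init))) stop_domain("'init' must be finite")
    test <- rhs(as.numeric(init))
    if (length(test) != length(init))
      stop_domain("rhs must return a derivative of the same length as 'init'")
    stiff <- method == "ros23"
    out <- cpp_integrate_rfun(function(y) as.numeric(rhs(y)),
                              as.numeric(init), t_span[1], t_span[2],
                              dt, rtol, atol, stiff)
    states_names <- names(init)
    if (is.null(states_names))
      states_names <- paste0("y", seq_along(init))
  } else {
    stop_domain("'rhs' must be a clock parameter object or a function")
  }

  if (!isTRUE(out$ok))
    stop("integration failed: ", out$message,
         " (t_span = [", t_span[1], ", ", t_span[2], "], rtol = ", rtol,
         ", atol = ", atol, ")", call. = FALSE)
  colnames(out$states) <- states_names
  colnames(out$derivs) <- states_names
  new_trajectory(out$times, out$states, out$derivs, out$nclip)
}

#' Simulate a clock model from its parameter object
#'
#' Convenience wrapper around [integrate_ode()] using the model's default
#' initial condition (all species at zero for the reduced models).
#'
#' @inheritParams integrate_ode
#' @param p clock parameter object.
#' @param t_end simulation horizon (h).
#' @return a `clock_trajectory`.
#' @examples
#' tr <- simulate_model(core_params(), t_end = 200)
#' range(tr$states[, "S"])
#' @export
simulate_model <- function(p, init = NULL, t_end = 400, dt = 0.05,
                           rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(p, "clock_params"))
  integrate_ode(p, init = init, t_span = t_end, dt = dt,
                rtol = rtol, atol = atol, method = "ros23")
}

new_verdict <- function(oscillating, period, method, evidence) {
  structure(list(oscillating = oscillating,
                 period = if (oscillating) period else NA_real_,
                 method = method, evidence = evidence),
            class = "oscillation_verdict")
}

#' @export
print.oscillation_verdict <- function(x, ...) {
  cat("<oscillation_verdict> ", if (x$oscillating) "oscillating" else
      "not oscillating", sep = "")
  if (x$oscillating) cat(", period = ", fmt_num(x$period), " h", sep = "")
  cat(" [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Spectral oscillation test
#'
#' Classifies a uniformly sampled series as oscillating or not from its
#' discrete Fourier spectrum, the procedure used for the core and TTFL/PTR
#' scans.  The first `transient` fraction of the series is discarded, the
#' mean is removed, and the dominant non-zero-frequency peak is located
#' (with parabolic interpolation of log power for sub-bin period
#' resolution).  The series is called oscillating when the peak amplitude
#' is at least `amp_frac` of the series mean level and at least
#' `median_mult` times the median spectral amplitude; these thresholds (the
#' original procedure is silent on them) reject numerically flat series and
#' broadband noise while keeping small-amplitude limit cycles.
#'
#' @param x numeric series sampled at spacing `dt`, or a
#'   `clock_trajectory` (then `species` selects the column).
#' @param dt sampling interval (h); taken from the trajectory if given.
#' @param species column to analyse when `x` is a trajectory.
#' @param transient fraction of the series discarded as transient.
#' @param amp_frac peak-amplitude threshold relative to the mean level.
#' @param median_mult peak threshold relative to the median spectral
#'   amplitude.
#' @param min_cycles minimum number of cycles the window must contain for a
#'   peak to be trusted (guards against trend leakage into the lowest
#'   frequency bins).
#' @return an `oscillation_verdict`; evidence carries the peak frequency,
#'   amplitude, and thresholds.
#' @examples
#' t <- seq(0, 2400, by = 0.1)
#' detect_oscillation_fft(sin(2 * pi * t / 24) + 5, dt = 0.1)
#' @export
detect_oscillation_fft <- function(x, dt = NULL, species = NULL,
                                   transient = 0.3, amp_frac = 0.01,
                                   median_mult = 5, min_cycles = 3) {
  if (inherits(x, "clock_trajectory")) {
    if (is.null(dt)) dt <- x$times[2] - x$times[1]
    if (is.null(species)) species <- colnames(x$states)[ncol(x$states)]
    x <- x$states[, species]
  }
  if (is.null(dt)) stop_domain("'dt' is required for a plain series")
  if (length(x) < 64) stop("series too short for spectral analysis", call. = FALSE)
  i0 <- floor(length(x) * transient) + 1L
  xs <- x[i0:length(x)]
  n <- length(xs)
  level <- mean(xs)
  xs <- xs - level
  sp <- Mod(fft(xs))[1:(n %/% 2 + 1)]
  freqs <- (0:(n %/% 2)) / (n * dt)
  k0 <- min_cycles + 1L                      # first trusted bin (index 1 = DC)
  if (k0 + 1 > length(sp))
    return(new_verdict(FALSE, NA, "fft", list(reason = "window too short")))
  k <- which.max(sp[k0:length(sp)]) + k0 - 1L
  amp <- 2 * sp[k] / n
  med <- median(sp[-1])
  ok <- amp >= amp_frac * abs(level) && sp[k] >= median_mult * med && sp[k] > 0
  # parabolic interpolation of log power around the peak
  fpk <- freqs[k]
  if (k > 2 && k < length(sp)) {
    la <- log(sp[k - 1] + 1e-300); lb <- log(sp[k] + 1e-300)
    lc <- log(sp[k + 1] + 1e-300)
    den <- la - 2 * lb + lc
    if (is.finite(den) && den < 0)
      fpk <- freqs[k] + 0.5 * (la - lc) / den * (freqs[2] - freqs[1])
  }
  per <- if (fpk > 0) 1 / fpk else NA_real_
  new_verdict(ok, per, "fft",
              list(peak_freq = fpk, peak_amplitude = amp,
                   median_amplitude = 2 * med / n, mean_level = level,
                   bin_width = freqs[2] - freqs[1]))
}

#' Event-location oscillation test
#'
#' The two-pass event procedure used for the phospholock scans: integrate
#' the model over `horizon` time units from the given (or random) initial
#' condition, take the mean of the monitored species, then locate every
#' time at which the series crosses that mean while increasing.  The
#' system is called oscillating when at least three crossings exist and
#' the last three are evenly spaced,
#' `|(te1 - te2) - (te2 - te3)| < gap_tol`, in which case the period is
#' `te1 - te2`.  Crossing times are refined from the integration grid by
#' cubic Hermite interpolation using the stored derivatives, so the
#' comparison is not limited by the output grid.
#'
#' @param p clock parameter object (or `function(y)` rhs with `init` and
#'   `monitor` given explicitly).
#' @param init initial state; when `NULL`, drawn uniformly from (0, 10]
#'   per state using the current RNG state (seed with [set.seed()]).
#' @param horizon integration length (time units; hours here).
#' @param dt output grid spacing used for the crossing search.
#' @param monitor monitored species name or index; defaults to the model's
#'   designated monitor species (mRNA for the repressor-chain models, S
#'   for the KaiC models).
#' @param gap_tol spacing tolerance of the printed criterion.
#' @param rtol,atol integration tolerances.
#' @return an `oscillation_verdict`; evidence carries the crossing times
#'   and the mean level.
#' @examples
#' set.seed(1)
#' p <- phospholock_params(alpha1 = 50, beta1 = 1, alpha2 = 30, beta2 = 1,
#'                         alpha3 = 30, beta3 = 1, A_T = 60,
#'                         k1f = 1, k1r = 1e-4, k2f = 0, k2r = 1, k3 = 0)
#' detect_oscillation_events(p)
#' @export
detect_oscillation_events <- function(p, init = NULL, horizon = 300,
                                      dt = 0.1, monitor = NULL,
                                      gap_tol = 1e-3,
                                      rtol = 1e-6, atol = 1e-9) {
  if (inherits(p, "clock_params")) {
    sp <- model_spec(p)
    if (is.null(monitor)) monitor <- sp$monitor
    if (is.null(init)) init <- runif(length(sp$states), 0, 10)
  } else if (is.function(p)) {
    if (is.null(init)) stop_domain("'init' is required for a function rhs")
    if (is.null(monitor)) monitor <- 1L
  } else stop_domain("'p' must be a clock parameter object or a function")

  tr <- integrate_ode(p, init = init, t_span = horizon, dt = dt,
                      rtol = rtol, atol = atol,
                      method = if (inherits(p, "clock_params")) "ros23" else "auto")
  m <- if (is.character(monitor)) tr$states[, monitor] else tr$states[, monitor]
  dm <- if (is.character(monitor)) tr$derivs[, monitor] else tr$derivs[, monitor]
  mu <- mean(m)
  ev <- cpp_crossing_times(tr$times, m, dm, mu)
  if (length(ev) < 3)
    return(new_verdict(FALSE, NA, "events",
                       list(events = ev, mean_level = mu,
                            reason = "fewer than 3 upward mean crossings")))
  te <- rev(ev)[1:3]                      # te1 (last), te2, te3
  gap_diff <- abs((te[1] - te[2]) - (te[2] - te[3]))
  osc <- gap_diff < gap_tol
  new_verdict(osc, te[1] - te[2], "events",
              list(events = ev, last_three = te, gap_diff = gap_diff,
                   mean_level = mu))
}

#' Phosphorylation/dephosphorylation phase durations
#'
#' Splits each cycle of an oscillatory series into the rising phase
#' `tau1` (trough to next peak) and the falling phase `tau2` (peak to next
#' trough).  Extrema are located on the grid after transient removal and
#' refined by parabolic interpolation; `tau1 + tau2` equals the period up
#' to sampling resolution.
#'
#' @param x numeric series or `clock_trajectory`.
#' @param times sample times (required for a plain series).
#' @param species trajectory column (defaults to last).
#' @param transient fraction discarded as transient.
#' @return named vector `c(tau1 = , tau2 = )` (hours), with the number of
#'   cycles used as attribute `cycles`.
#' @examples
#' t <- seq(0, 480, by = 0.05)
#' x <- sin(2 * pi * t / 24)
#' phase_durations(x, times = t)   # ~ (12, 12)
#' @export
phase_durations <- function(x, times = NULL, species = NULL,
                            transient = 0.3) {
  if (inherits(x, "clock_trajectory")) {
    times <- x$times
    if (is.null(species)) species <- colnames(x$states)[ncol(x$states)]
    x <- x$states[, species]
  }
  if (is.null(times)) stop_domain("'times' is required for a plain series")
  i0 <- floor(length(x) * transient) + 1L
  t <- times[i0:length(x)]; v <- x[i0:length(x)]
  n <- length(v)
  refine <- function(i) {       # parabolic vertex around grid extremum
    if (i <= 1 || i >= n) return(t[i])
    den <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (den == 0) return(t[i])
    t[i] + 0.5 * (v[i - 1] - v[i + 1]) / den * (t[2] - t[1])
  }
  peaks <- which(diff(sign(diff(v))) < 0) + 1L
  troughs <- which(diff(sign(diff(v))) > 0) + 1L
  # ignore numerical micro-extrema
  amp <- max(v) - min(v)
  keep <- function(idx) idx[abs(v[idx] - mean(v)) > 0.01 * amp]
  peaks <- keep(peaks); troughs <- keep(troughs)
  if (length(peaks) < 2 || length(troughs) < 2)
    stop("series is not oscillatory: need at least two full cycles",
         call. = FALSE)
  tp <- vapply(peaks, refine, 0); tt <- vapply(troughs, refine, 0)
  tau1 <- c(); tau2 <- c()
  for (a in tt) {
    nxt <- tp[tp > a]
    if (length(nxt)) tau1 <- c(tau1, nxt[1] - a)
  }
  for (a in tp) {
    nxt <- tt[tt > a]
    if (length(nxt)) tau2 <- c(tau2, nxt[1] - a)
  }
  out <- c(tau1 = mean(tau1), tau2 = mean(tau2))
  attr(out, "cycles") <- min(length(tau1), length(tau2))
  out
}

#' Serialise an oscillation verdict to JSON
#'
#' @param v an `oscillation_verdict`.
#' @param file optional path; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
verdict_to_json <- function(v, file = NULL) {
  stopifnot(inherits(v, "oscillation_verdict"))
  js <- jsonlite::toJSON(unclass(v), auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Write / read a trajectory as CSV
#'
#' Plain-text round trip: a `time` column plus one named column per
#' species.
#'
#' @param traj a `clock_trajectory`.
#' @param file path.
#' @return `read_trajectory_csv` returns a `clock_trajectory` (without
#'   derivatives).
#' @export
write_trajectory_csv <- function(traj, file) {
  stopifnot(inherits(traj, "clock_trajectory"))
  write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  if (!"time" %in% names(df)) stop_domain("no 'time' column in ", file)
  st <- as.matrix(df[setdiff(names(df), "time")])
  new_trajectory(df$time, st)
}
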