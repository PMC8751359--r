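# Integrators, oscillation detectors and phase summaries.

test_that("integration meets tolerance on closed-form problems", {
  # tolerances control the local error; allow the usual small accumulation
  tr <- integrate_ode(function(y) -y, init = c(x = 1), t_span = 1,
                      dt = 0.1, method = "dopri5")
  expect_equal(unname(tr$states[11, "x"]), exp(-1), tolerance = 1e-7)
  trs <- integrate_ode(function(y) -y, init = c(x = 1), t_span = 1,
                       dt = 0.1, method = "ros23")
  expect_equal(unname(trs$states[11, "x"]), exp(-1), tolerance = 5e-5)
  # harmonic oscillator: energy drift over 10 periods
  tr <- integrate_ode(function(y) c(y[2], -y[1]), init = c(q = 1, p = 0),
                      t_span = 20 * pi, dt = 0.05, method = "dopri5")
  E <- rowSums(tr$states^2)
  expect_lt(max(abs(E - 1)), 1e-4)
})

test_that("solver failure raises a diagnostic error", {
  blow <- function(y) y^2          # finite-time blow-up from x(0)=1 at t=1
  expect_error(integrate_ode(blow, init = c(x = 1), t_span = 2, dt = 0.1),
               "integration failed")
})

test_that("spectral detector: pure tone, constant, and two-tone dominance", {
  t <- seq(0, 2400, by = 0.1)
  v <- detect_oscillation_fft(5 + sin(2 * pi * t / 24), dt = 0.1)
  expect_true(v$oscillating)
  expect_equal(v$period, 24, tolerance = v$evidence$bin_width * 24^2)
  vc <- detect_oscillation_fft(rep(3.7, 5000), dt = 0.1)
  expect_false(vc$oscillating)
  v2 <- detect_oscillation_fft(
    5 + sin(2 * pi * t / 24) + 0.2 * sin(2 * pi * t / 12), dt = 0.1)
  expect_true(v2$oscillating)
  expect_equal(v2$period, 24, tolerance = 0.5)
  expect_error(detect_oscillation_fft(1:10, dt = 1), "too short")
})

test_that("event detector implements the two-pass mean-crossing criterion", {
  om <- 2 * pi / 24
  sine_sys <- function(y) c(om * cos(y[2]), om)     # y1 = 5 + sin(om t)
  v <- detect_oscillation_events(sine_sys, init = c(M = 5, phi = 0),
                                 horizon = 300, dt = 0.1, monitor = 1)
  expect_true(v$oscillating)
  expect_equal(v$period, 24, tolerance = 1e-6)
  expect_lt(v$evidence$gap_diff, 1e-6)
  # pure decay: no upward crossing of the mean
  vd <- detect_oscillation_events(function(y) -y / 20, init = c(M = 1),
                                  horizon = 300, dt = 0.1, monitor = 1)
  expect_false(vd$oscillating)
  # damped spiral: crossings exist but spacings drift above the tolerance
  g <- 1 / 60
  damp <- function(y) c(-g * y[1] + om * y[2], -om * y[1] - g * y[2], 0)
  vd2 <- detect_oscillation_events(damp, init = c(x = 0, y = 1, c = 5),
                                   horizon = 300, dt = 0.1, monitor = 1)
  expect_false(vd2$oscillating)
})

test_that("detectors are offset-invariant", {
  om <- 2 * pi / 24
  base <- detect_oscillation_events(function(y) c(om * cos(y[2]), om),
                                    init = c(M = 5, phi = 0), monitor = 1)
  up <- detect_oscillation_events(function(y) c(om * cos(y[2]), om),
                                  init = c(M = 105, phi = 0), monitor = 1)
  expect_equal(base$oscillating, up$oscillating)
  expect_equal(base$period, up$period, tolerance = 1e-9)
  t <- seq(0, 2400, by = 0.1)
  s <- sin(2 * pi * t / 24)
  f1 <- detect_oscillation_fft(5 + s, dt = 0.1)
  f2 <- detect_oscillation_fft(25 + s, dt = 0.1)
  expect_equal(f1$oscillating, f2$oscillating)
  expect_equal(f1$period, f2$period, tolerance = 1e-9)
})

test_that("phase durations split cycles as constructed", {
  # asymmetric triangle: 9.5 h rise, 18.5 h fall
  period <- 28
  t <- seq(0, 20 * period, by = 0.05)
  ph <- t %% period
  x <- ifelse(ph < 9.5, ph / 9.5, 1 - (ph - 9.5) / 18.5)
  tau <- phase_durations(x, times = t)
  expect_equal(tau[["tau1"]], 9.5, tolerance = 0.1)
  expect_equal(tau[["tau2"]], 18.5, tolerance = 0.1)
  # symmetric sine
  ts <- seq(0, 480, by = 0.05)
  tau2 <- phase_durations(sin(2 * pi * ts / 24), times = ts)
  expect_equal(unname(tau2), c(12, 12), tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(sum(tau2), 24, tolerance = 0.02)
  expect_error(phase_durations(exp(-ts / 50), times = ts), "not oscillatory")
})

test_that("FFT and event detectors agree across regimes and on period", {
  # seeded benchmark over oscillatory and non-oscillatory phospholock sets
  set.seed(99)
  n <- 60
  agree <- 0; both <- 0; per_ok <- TRUE
  for (i in 1:n) {
    Kd <- 10^runif(1, -6, 0)
    p <- phospholock_params(
      alpha1 = runif(1, 0, 100), beta1 = runif(1, 0, 100),
      alpha2 = runif(1, 0, 100), beta2 = runif(1, 0, 100),
      alpha3 = runif(1, 0, 100), beta3 = runif(1, 0, 100),
      A_T = runif(1, 0, 100), k1f = 1, k1r = Kd,
      k2f = 0, k2r = 1, k3 = 0)
    init <- runif(3, 0, 10)
    # fine grid: draws with fast degradation rates cycle in well under an
    # hour, and both detectors need several samples per cycle
    ve <- detect_oscillation_events(p, init = init, horizon = 300, dt = 0.02)
    tr <- simulate_model(p, init = init, t_end = 300, dt = 0.02)
    vf <- detect_oscillation_fft(tr, species = "M")
    if (ve$oscillating == vf$oscillating) agree <- agree + 1
    if (ve$oscillating && vf$oscillating) {
      both <- both + 1
      bw <- vf$evidence$bin_width
      if (abs(1 / ve$period - 1 / vf$period) > bw) per_ok <- FALSE
    }
  }
  expect_gte(agree / n, 0.95)
  expect_gt(both, 0)
  expect_true(per_ok)
})

test_that("trajectories round-trip through CSV", {
  tr <- simulate_model(core_params(), t_end = 10, dt = 0.5)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$times, tr$times)
  expect_equal(back$states, tr$states)
  js <- verdict_to_json(detect_oscillation_fft(
    5 + sin(2 * pi * seq(0, 2400, 0.1) / 24), dt = 0.1))
  expect_true(jsonlite::validate(js))
})
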