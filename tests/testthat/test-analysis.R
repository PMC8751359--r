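# Analyses: sensitivity curves, steady states, degenerate scans, reports.

test_that("sensitivity of a power law is identically its exponent", {
  sc <- sensitivity_curve(function(x) 3 / x, grid = exp(seq(0, 4, 0.05)))
  expect_equal(sc$sensitivity, rep(-1, nrow(sc)), tolerance = 1e-10)
  sc2 <- sensitivity_curve(function(x) x^2, grid = exp(seq(0, 2, 0.1)))
  expect_equal(range(sc2$sensitivity), c(2, 2), tolerance = 1e-10)
  expect_warning(sensitivity_curve(function(x) 1 - x,
                                   grid = seq(0.1, 2, 0.1)), "truncated")
})

test_that("peak sensitivity grows as binding tightens (Kd down)", {
  peaks <- vapply(c(1e-2, 1e-3, 1e-4), function(kd) {
    sc <- sensitivity_curve(function(S) free_kaia(S, 8, kd),
                            grid = seq(4, 12, length.out = 801))
    attr(sc, "peak")
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("peak sensitivity grows with phosphorylation ratio k2", {
  grid <- seq(75, 150, length.out = 601)
  peaks <- vapply(c(1, 10, 100, 1e3, 1e4), function(k2) {
    p <- phospholock_params_table1(k2 = k2)
    sc <- sensitivity_curve(function(R) phospholock_repression(R, p), grid)
    attr(sc, "peak")
  }, 0)
  expect_true(all(diff(peaks) > 0))
  # the effective affinity itself tightens monotonically with k2
  kds <- vapply(c(1, 10, 100, 1e3, 1e4), function(k2)
    effective_constants(phospholock_params_table1(k2 = k2))$Kd_eff, 0)
  expect_true(all(diff(kds) < 0))
})

test_that("slower decay of the locked complex sharpens repression", {
  grid <- seq(75, 150, length.out = 601)
  peaks <- vapply(c(1.9, 0.5, 0.1), function(k3) {
    p <- phospholock_params(k1f = 1000, k1r = 1000, k2f = 10, k2r = 1,
                            k3 = k3)
    sc <- sensitivity_curve(function(R) phospholock_repression(R, p), grid)
    attr(sc, "peak")
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("steady-state repressor solves the fixed-point equation", {
  p <- neurospora_params(k3 = 0.5)
  ss <- steady_state_repressor(p)
  expect_lt(abs(ss$residual), 1e-10)
  expect_equal(ss$S_ratio, ss$R_star / p$A_T)
  # production-starved limit: beta >> alpha forces R* ~ 0
  p0 <- neurospora_params(alpha1 = 1e-3, alpha2 = 1e-3, alpha3 = 1e-3,
                          beta1 = 90, beta2 = 90, beta3 = 90, k3 = 0.5)
  expect_lt(steady_state_repressor(p0)$R_star, 1e-4)
  # dynamical oracle: a non-oscillating chain relaxes to R*
  pq <- phospholock_params(alpha1 = 20, beta1 = 1, alpha2 = 10, beta2 = 1,
                           alpha3 = 10, beta3 = 1, A_T = 50,
                           k1f = 1, k1r = 1, k2f = 0.1, k2r = 0.1, k3 = 0.05)
  ssq <- steady_state_repressor(pq)
  tr <- simulate_model(pq, t_end = 400, dt = 0.5)
  expect_equal(unname(tr$states[nrow(tr$states), "R"]), ssq$R_star,
               tolerance = 1e-5)
})

test_that("a scheme violating the balance condition almost never oscillates", {
  # A_T >= C_T everywhere: C_T > 3 A_T is impossible by construction
  sw <- kd_sweep_core(kd_grid = c(1e-4, 1e-2), n = 40, seed = 2,
                      ranges = list(k1 = c(0, 1), A_T = c(50, 100),
                                    C_T = c(1, 45)))
  expect_true(all(sw$summary$fraction <= 0.05))
})

test_that("stoichiometric condition check uses a strict boundary", {
  rows <- data.frame(A_T = c(10, 10, 10), C_T = c(30, 30.1, 100),
                     oscillating = c(TRUE, TRUE, FALSE))
  chk <- stoich_condition_check(rows)
  expect_equal(chk$n_oscillating, 2)
  expect_equal(chk$fraction_compliant, 0.5)      # C_T = 3 A_T exactly fails
  expect_equal(nrow(chk$violators), 1)
  expect_equal(chk$n_quiet_compliant, 1)         # necessary, not sufficient
})

test_that("report compares computed values against references bytewise-stably", {
  bundle <- list(pipeline = "ttfl-vs-ptr",
                 summary = data.frame(n = 10, pct_ttfl = 98.0,
                                      pct_ptr = 70.0))
  rep1 <- make_report(list(bundle))
  expect_true(rep1$pass[rep1$quantity == "pct_ttfl"])
  expect_false(rep1$pass[rep1$quantity == "pct_ptr"])
  f1 <- tempfile(fileext = ".md"); f2 <- tempfile(fileext = ".md")
  make_report(list(bundle), file = f1)
  make_report(list(bundle), file = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(make_report(list()), "no bundles")
})
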