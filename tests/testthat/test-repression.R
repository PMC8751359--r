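# Repression / free-activator functions against algebraic limits and
# independent equilibrium oracles.

test_that("free_kaia matches tight-binding limits and the bisection oracle", {
  # zero-Kd algebra
  expect_equal(free_kaia(0, A_T = 8, Kd = 0), 8)
  expect_equal(free_kaia(4, A_T = 8, Kd = 0), 4)
  expect_equal(free_kaia(12, A_T = 8, Kd = 0), 0)
  # Kd -> 0 pointwise limit
  S <- seq(0, 16, length.out = 81)
  expect_equal(free_kaia(S, 8, 1e-12), pmax(8 - S, 0), tolerance = 1e-5)
  # equilibrium oracle at finite Kd
  for (case in list(c(4, 8, 1e-2), c(7.5, 8, 1e-3), c(20, 8, 1e-1),
                    c(0.5, 2, 5e-2))) {
    expect_equal(free_kaia(case[1], case[2], case[3]),
                 bisect_free_activator(case[1], case[2], case[3]),
                 tolerance = 1e-8)
  }
  expect_error(free_kaia(-1, 8, 0.1), "must be finite")
  expect_error(free_kaia(1, 0, 0.1), "A_T")
})

test_that("repression functions are bounded, continuous and non-increasing", {
  S <- seq(0, 300, length.out = 600)
  pset <- list(
    function(x) free_kaia(x, 8, 1e-4),
    function(x) kim_forger_fraction(x, 10, 1e-3),
    function(x) phospholock_repression(x, phospholock_params_table1(k2 = 100)),
    function(x) neurospora_repression(
      x, neurospora_params(k1f = 0.5, k1r = 5e-6, k2f = 1, k2r = 0.1,
                           k3 = 0.05, k4f = 0.4, k4r = 0.4)))
  caps <- c(8, 1, 98.9, 98.9)
  for (i in seq_along(pset)) {
    f <- vapply(S, pset[[i]], 0)
    expect_true(all(f >= 0) && all(f <= caps[i] + 1e-12))
    expect_true(all(diff(f) <= 1e-12))              # monotone non-increasing
    expect_lt(max(abs(diff(f))), caps[i] * 0.6)     # no jumps on this grid
  }
})

test_that("Kim-Forger fraction is the shared quadratic normalised by A", {
  set.seed(7)
  for (i in 1:50) {
    P <- runif(1, 0, 30); A <- runif(1, 0.5, 20); Kd <- 10^runif(1, -6, 0)
    expect_equal(kim_forger_fraction(P, A, Kd), free_kaia(P, A, Kd) / A,
                 tolerance = 1e-12)
  }
  expect_equal(kim_forger_fraction(0, 10, 0), 1)
  expect_equal(kim_forger_fraction(10, 10, 0), 0)
  expect_error(kim_forger_fraction(1, 0, 0.1), "positive")
})

test_that("effective constants collapse to pure sequestration without the lock", {
  p <- phospholock_params(k1f = 0.4, k1r = 0.2, k2f = 0, k2r = 1, k3 = 0)
  ec <- effective_constants(p)
  expect_equal(ec$Kd_eff, 0.5)
  R <- seq(0, 250, length.out = 101)
  expect_equal(phospholock_repression(R, p), free_kaia(R, p$A_T, 0.5),
               tolerance = 1e-12)
})

test_that("closed-form phospholock repression equals the mass-action equilibrium", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    mr <- draw_micro_rates()
    A_T <- runif(1, 5, 100)
    R_T <- runif(1, 0, 2 * A_T)
    p <- phospholock_params(A_T = A_T, k1f = mr$k1f, k1r = mr$k1r,
                            k2f = mr$k2f, k2r = mr$k2r, k3 = mr$k3)
    closed <- phospholock_repression(R_T, p)
    oracle <- relax_free_activator(A_T, R_T, mr$k1f, mr$k1r, mr$k2f,
                                   mr$k2r, mr$k3)
    worst <- max(worst, abs(closed - oracle) / max(oracle, 1e-8))
  }
  expect_lt(worst, 1e-6)
})

test_that("activator-phosphorylation closed form equals its equilibrium oracle", {
  set.seed(43)
  worst <- 0
  for (i in 1:100) {
    mr <- draw_micro_rates()
    A_T <- runif(1, 5, 100)
    R_T <- runif(1, 0, 2 * A_T)
    p <- neurospora_params(A_T = A_T, k1f = mr$k1f, k1r = mr$k1r,
                           k2f = mr$k2f, k2r = mr$k2r, k3 = mr$k3,
                           k4f = mr$k4f, k4r = mr$k4r)
    closed <- neurospora_repression(R_T, p)
    oracle <- relax_free_activator(A_T, R_T, mr$k1f, mr$k1r, mr$k2f,
                                   mr$k2r, mr$k3, mr$k4f, mr$k4r,
                                   activator_phos = TRUE)
    worst <- max(worst, abs(closed - oracle) / max(oracle, 1e-8))
  }
  expect_lt(worst, 1e-6)
})

test_that("activator phosphorylation reduces correctly at R = 0 and k4 = 0", {
  # K3_tilde = K1_tilde requires the catalytic branch to vanish: k3 = 0
  p0 <- neurospora_params(k1f = 0.5, k1r = 0.1, k2f = 0.7, k2r = 0.2,
                          k3 = 0, k4f = 0, k4r = 1)
  expect_equal(effective_constants(p0)$rho, 1)
  R <- seq(0, 200, length.out = 101)
  pe <- phospholock_params(k1f = 0.5, k1r = 0.1, k2f = 0.7, k2r = 0.2,
                           k3 = 0)
  expect_equal(neurospora_repression(R, p0), phospholock_repression(R, pe),
               tolerance = 1e-14)
  expect_equal(phospholock_repression(0, pe), pe$A_T)
  p1 <- neurospora_params(k4f = 0.3, k4r = 0.3)   # k4 = 1
  expect_equal(neurospora_repression(0, p1), p1$A_T / 2)
  # large-R tail decays to zero
  expect_lt(neurospora_repression(1e7, p1), 1e-2)
})

test_that("derived parameters are recomputed, never stored inconsistently", {
  p <- phospholock_params(k1f = 0.8, k1r = 0.2, k2f = 0.9, k2r = 0.3, k3 = 0.01)
  expect_equal(p$Kd, 0.25)
  expect_equal(p$k2, 3)
  ec <- effective_constants(p)
  expect_equal(ec$K1_tilde, 0.8 * (0.3 + 0.01 + 0.9))
  expect_equal(ec$K2_tilde, 0.2 * (0.3 + 0.01) + 0.9 * 0.01)
  expect_equal(ec$K3_tilde, ec$K1_tilde)   # no activator phosphorylation
  pn <- neurospora_params(k1f = 0.8, k1r = 0.2, k2f = 0.9, k2r = 0.3,
                          k3 = 0.01, k4f = 0.5, k4r = 0.25)
  ecn <- effective_constants(pn)
  expect_equal(ecn$K3_tilde, ecn$K1_tilde + 0.8 * 0.9 * 0.01 / 0.25)
  expect_equal(ecn$q, 3)                   # 1 + k4f/k4r
  expect_error(effective_constants(list(k1f = 1)), "micro-rates")
})
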