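# Samplers: determinism, bounds, constraints, distributional shape.

test_that("samplers are bitwise reproducible and respect their bounds", {
  a <- sample_core(1e-3, n = 500, seed = 11)
  b <- sample_core(1e-3, n = 500, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, sample_core(1e-3, n = 500, seed = 12)))
  rg <- core_ranges()
  expect_true(all(a$k1 >= rg$k1[1] & a$k1 <= rg$k1[2]))
  expect_true(all(a$A_T >= rg$A_T[1] & a$A_T <= rg$A_T[2]))
  expect_true(all(a$C_T >= rg$C_T[1] & a$C_T <= rg$C_T[2]))
  expect_true(all(a$k2 == a$k2[1]))   # fixed rates constant
  expect_error(sample_core(1e-3, 10, 1, ranges = list(k1 = c(1, 0),
               A_T = c(0, 1), C_T = c(0, 1))), "invalid range")
})

test_that("sampled marginals are uniform (Kolmogorov-Smirnov, alpha = 0.01)", {
  tab <- sample_core(1e-4, n = 5000, seed = 2024)
  for (col in c("k1", "A_T", "C_T")) {
    r <- core_ranges()[[col]]
    ks <- suppressWarnings(stats::ks.test((tab[[col]] - r[1]) / diff(r), "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("TTFL sampler varies only K_s and A_T and pairs by construction", {
  tab <- sample_ttfl(n = 400, seed = 5)
  expect_equal(nrow(tab), 400)
  varying <- vapply(tab, function(x) length(unique(x)) > 1, TRUE)
  expect_setequal(names(varying)[varying], c("K_s", "A_T"))
  # identical rows drive both modes: the table itself is the pairing
  expect_identical(tab, sample_ttfl(n = 400, seed = 5))
})

test_that("phospholock sampler enforces the published constraints", {
  tab <- sample_phospholock(n = 3000, seed = 31)
  expect_identical(tab$k1r, tab$k1f)            # Kd = 1
  expect_lte(max(tab$k3), 0.1)
  expect_lte(max(tab$k1f), 1)
  expect_lte(max(tab$A_T), 100)
  # multiplier grid: derived tables share every column except k2r
  m100 <- apply_phospho_multiplier(tab, 100)
  m001 <- apply_phospho_multiplier(tab, 1e-4)
  expect_equal(m100$k2r, 100 * tab$k2f)
  expect_equal(m001$k2r, 1e-4 * tab$k2f)
  same <- setdiff(names(tab), "k2r")
  expect_identical(m100[same], m001[same])
})

test_that("substream seeds are deterministic, distinct, and in range", {
  s <- vapply(0:50, function(i) substream_seed(123, i), 1L)
  expect_identical(s, vapply(0:50, function(i) substream_seed(123, i), 1L))
  expect_equal(length(unique(s)), 51)
  expect_true(all(s >= 1 & s < 2^31 - 1))
  expect_false(substream_seed(1, 0) == substream_seed(2, 0))
})

test_that("rejection sampler returns verified oscillating sets", {
  tab <- sample_until_oscillating(target = 3, k3_value = 0, seed = 7)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$k2f, 10 * tab$k2r)            # phosphorylation-dominant
  expect_equal(tab$k1r, 1e-5 * tab$k1f)          # Kd constraint
  expect_equal(tab$k4r, tab$k4f)                 # balanced activator cycle
  expect_gt(attr(tab, "draws"), 0)
  # every accepted row re-verifies under the event criterion
  for (j in seq_len(nrow(tab))) {
    p <- neurospora_params(alpha1 = tab$alpha1[j], beta1 = tab$beta1[j],
                           alpha2 = tab$alpha2[j], beta2 = tab$beta2[j],
                           alpha3 = tab$alpha3[j], beta3 = tab$beta3[j],
                           A_T = tab$A_T[j], k1f = tab$k1f[j],
                           k1r = tab$k1r[j], k2f = tab$k2f[j],
                           k2r = tab$k2r[j], k3 = tab$k3[j],
                           k4f = tab$k4f[j], k4r = tab$k4r[j])
    v <- detect_oscillation_events(
      p, init = c(tab$init_M[j], tab$init_r[j], tab$init_R[j]))
    expect_true(v$oscillating)
    expect_equal(v$period, tab$period[j], tolerance = 1e-8)
  }
  # infeasible target within a tiny budget reports the acceptance rate
  expect_error(sample_until_oscillating(target = 50, k3_value = 0, seed = 7,
                                        max_draws = 10),
               "draw budget")
})

test_that("schemes round-trip through YAML", {
  scheme <- list(model = "core", fixed = list(k2 = 0.13),
                 uniform = list(k1 = c(0, 1)), n = 100, seed = 4)
  f <- tempfile(fileext = ".yaml")
  write_scheme_yaml(scheme, f)
  expect_equal(read_scheme_yaml(f), scheme)
})
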