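# Binding equilibria: depletion quadratic, competition, two-site model.

test_that("complex_concentration solves the depletion quadratic", {
  expect_equal(complex_concentration(1.5, 0, 0.05), 0)
  # stoichiometric (tight-binding) limit: C -> min(A0, L0)
  expect_equal(complex_concentration(1.5, 1.0, 1e-12), 1.0, tolerance = 1e-9)
  # closed form against the bisection oracle at the worked point
  expect_equal(complex_concentration(1.5, 1.5, 0.05),
               bisect_complex(1.5, 1.5, 0.05), tolerance = 1e-12)
  expect_equal(complex_concentration(1.5, 1.5, 0.05), 1.25, tolerance = 1e-12)
})

test_that("complex_concentration matches bisection and obeys bounds on random systems", {
  withr::with_seed(42, {
    n <- 300
    A0 <- 10^runif(n, -2, 2)
    L0 <- 10^runif(n, -2, 2)
    Kd <- 10^runif(n, -3, 2)
    C <- complex_concentration(A0, L0, Kd)
    expect_true(all(C >= 0 & C <= pmin(A0, L0) + 1e-12))
    oracle <- mapply(bisect_complex, A0, L0, Kd)
    expect_lt(max(abs(C - oracle) / pmax(oracle, 1e-12)), 1e-10)
    # monotone increasing in L0, decreasing in Kd
    expect_true(all(complex_concentration(A0, L0 * 1.1, Kd) >= C - 1e-12))
    expect_true(all(complex_concentration(A0, L0, Kd * 1.1) <= C + 1e-12))
  })
})

test_that("invalid binding inputs are rejected", {
  expect_error(complex_concentration(-1, 1, 0.05), class = "actinfit_invalid_input")
  expect_error(complex_concentration(1, 1, 0), class = "actinfit_invalid_input")
  expect_error(complex_concentration(1, NA, 0.05), class = "actinfit_invalid_input")
  expect_error(predicted_signal(0, 1, 0.05, 100, 20), class = "actinfit_invalid_input")
})

test_that("predicted_signal maps occupancy to fluorescence", {
  expect_equal(predicted_signal(1.5, 0, 0.05, 100, 20), 100)
  expect_equal(predicted_signal(1.5, 1e6, 0.05, 100, 20), 120, tolerance = 1e-5)
  expect_equal(predicted_signal(1.5, 1.5, 0.05, 100, 20),
               100 + 20 * (1.25 / 1.5), tolerance = 1e-10)
  f <- predicted_signal(1.5, seq(0, 10, by = 0.5), 0.05, 100, 20)
  expect_true(all(f >= 100 & f <= 120))
  expect_true(all(diff(f) >= 0))
})

test_that("competition_solve reduces to 1:1 when one ligand is absent", {
  s <- competition_solve(1.5, E0 = 15, K_E = 7.5, T0 = 0, K_T = 3)
  expect_equal(s$AE, complex_concentration(1.5, 15, 7.5), tolerance = 1e-12)
  expect_equal(s$AT, 0)
  s2 <- competition_solve(1.5, E0 = 0, K_E = 7.5, T0 = 25, K_T = 3)
  expect_equal(s2$AT, complex_concentration(1.5, 25, 3), tolerance = 1e-12)
})

test_that("competition_solve conserves mass and matches bisection", {
  s <- competition_solve(1.5, E0 = 15, K_E = 7.5, T0 = 25, K_T = 3)
  orc <- bisect_competition(1.5, 15, 7.5, 25, 3)
  expect_equal(s$free_actin, unname(orc["free_actin"]), tolerance = 1e-9)
  expect_equal(s$AE, unname(orc["AE"]), tolerance = 1e-9)
  expect_equal(s$AT, unname(orc["AT"]), tolerance = 1e-9)
  expect_lt(s$residual, 1e-9)
  # both mass-action laws hold
  expect_equal(s$free_actin * s$free_E / s$AE, 7.5, tolerance = 1e-8)
  expect_equal(s$free_actin * s$free_T / s$AT, 3, tolerance = 1e-8)
})

test_that("raising competitor load never increases the reporter complex", {
  withr::with_seed(7, {
    for (i in 1:50) {
      A0 <- 10^runif(1, -1, 1); K_E <- 10^runif(1, -1, 1)
      K_T <- 10^runif(1, -1, 1); T0 <- 10^runif(1, -1, 1.5)
      E <- sort(10^runif(4, -2, 2))
      at <- vapply(E, function(e) competition_solve(A0, e, K_E, T0, K_T)$AT,
                   numeric(1))
      expect_true(all(diff(at) <= 1e-12))
    }
  })
})

test_that("apparent_kd follows the linear competition formula", {
  expect_equal(apparent_kd(3, 0, 7.5), 3)
  expect_equal(apparent_kd(3, 15, 7.5), 9)
  expect_gte(apparent_kd(2, 5, 1), 2)
  expect_equal(invert_apparent_kd(K_T0 = 3, K_app = 9, E0 = 15), 7.5)
  expect_error(invert_apparent_kd(3, 2, 15), class = "actinfit_invalid_input")
})

test_that("apparent_kd approximates the exact solve when actin is trace", {
  # validity domain: A0 << K_E, K_T
  A0 <- 0.01; E0 <- 15; K_E <- 7.5; K_T <- 3
  kapp <- apparent_kd(K_T, E0, K_E)
  # exact half-occupancy point of the reporter from the ternary solve
  half <- uniroot(function(T0) {
    competition_solve(A0, E0, K_E, T0, K_T)$AT / A0 - 0.5
  }, c(1e-4, 1e4), tol = 1e-12)$root
  expect_equal(half, kapp, tolerance = 0.1)
})

test_that("two_site_signal is additive over independent sites", {
  expect_equal(two_site_signal(1.5, 0, 0.05, 0, 3, 100, 17, 12), 100)
  expect_equal(two_site_signal(1.5, 1e7, 0.05, 1e7, 3, 100, 17, 12), 129,
               tolerance = 1e-5)
  # mid-range equals the composition of two independent 1:1 solves
  th1 <- complex_concentration(1.5, 2, 0.05) / 1.5
  th2 <- complex_concentration(1.5, 5, 3) / 1.5
  expect_equal(two_site_signal(1.5, 2, 0.05, 5, 3, 100, 17, 12),
               100 + 17 * th1 + 12 * th2, tolerance = 1e-12)
})
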