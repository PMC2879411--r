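# Generators: determinism, noiseless exactness, and the master round-trip
# suite pairing every generator with its fitter at zero noise.

test_that("generators are bit-identical under a fixed seed", {
  a <- sim_titration(0.05, noise = 0.02, n_rep = 3, seed = 5)
  b <- sim_titration(0.05, noise = 0.02, n_rep = 3, seed = 5)
  expect_identical(a$signal, b$signal)
  c <- sim_titration(0.05, noise = 0.02, n_rep = 3, seed = 6)
  expect_false(identical(a$signal, c$signal))

  r1 <- sim_rate_titration("capping", 15, seq(0, 0.15, length.out = 12),
                           noise = 0.02, seed = 5)
  r2 <- sim_rate_titration("capping", 15, seq(0, 0.15, length.out = 12),
                           noise = 0.02, seed = 5)
  expect_identical(r1$norm_rate_pct, r2$norm_rate_pct)

  e1 <- sim_exchange(c(0, 2), Kd = 0.3, k_free = 0.05, k_bound = 0.01,
                     noise = 0.02, seed = 5)
  e2 <- sim_exchange(c(0, 2), Kd = 0.3, k_free = 0.05, k_bound = 0.01,
                     noise = 0.02, seed = 5)
  expect_identical(e1$traces$signal, e2$traces$signal)
  expect_equal(attr(a, "seed"), 5L)
})

test_that("zero noise reproduces the exact model curves", {
  g <- seq(0, 2, length.out = 15)
  d <- sim_titration(0.05, grid = g, noise = 0, seed = 1)
  expect_equal(d$signal, predicted_signal(1.5, g, 0.05, 100, 20),
               tolerance = 1e-14)
  expect_equal(d$signal[1], 100) # control at baseline

  gr <- seq(0, 8, length.out = 12)
  r <- sim_rate_titration("sequestration", 2.5, gr, A0 = 2, noise = 0, seed = 1)
  expect_equal(r$norm_rate_pct, sequestration_curve(gr, 2.5, 2, 0.6),
               tolerance = 1e-14)
  expect_equal(r$norm_rate_pct[1], 100)
  expect_true(all(r$norm_rate_pct >= 0))
})

test_that("replicates differ but share the grid", {
  d <- sim_titration(0.05, noise = 0.02, n_rep = 2, seed = 9)
  s1 <- d$signal[d$replicate == 1]
  s2 <- d$signal[d$replicate == 2]
  expect_false(identical(s1, s2))
  expect_identical(d$ligand_conc_uM[d$replicate == 1],
                   d$ligand_conc_uM[d$replicate == 2])
})

test_that("every generator round-trips through its fitter at zero noise", {
  d <- sim_titration(1.7, grid = seq(0, 15, length.out = 15), noise = 0,
                     seed = 2)
  expect_equal(coef(fit_binding(d, 1.5))[["Kd_uM"]], 1.7, tolerance = 1e-6)

  dc <- sim_rate_titration("capping", 108, seq(0, 1, length.out = 12),
                           noise = 0, seed = 2)
  expect_equal(coef(fit_kcap(dc))[["Kcap_nM"]], 108, tolerance = 1e-6)

  ds <- sim_rate_titration("sequestration", 2.5, seq(0, 8, length.out = 12),
                           A0 = 2, noise = 0, seed = 2)
  expect_equal(coef(fit_kseq(ds, A0 = 2))[["Kseq_uM"]], 2.5, tolerance = 1e-6)

  ex <- sim_exchange(c(0, 1, 5), A0 = 2, Kd = 0.3, k_free = 0.05,
                     k_bound = 0.01, noise = 0, seed = 2)
  for (L in unique(ex$traces$ligand_conc_uM)) {
    tr <- dplyr::filter(ex$traces, ligand_conc_uM == L)
    k_true <- ex$kobs$k_obs_true[ex$kobs$ligand_conc_uM == L]
    expect_equal(coef(fit_exchange_trace(tr))[["k_obs"]], k_true,
                 tolerance = 1e-6)
  }

  cal <- sim_calibration(c(2.58, 4.22, 7.4, 11.4), slope = -0.8,
                         intercept = 18, noise = 0, seed = 2)
  fitcal <- linear_calibration(tibble::tibble(
    observed_position = cal$observed_position, known_value = cal$known_value))
  # latent line position = 18 - 0.8 * value inverts to value = (18 - pos)/0.8
  expect_equal(fitcal$slope, -1 / 0.8, tolerance = 1e-10)
  expect_equal(fitcal$intercept, 18 / 0.8, tolerance = 1e-10)
})

test_that("generator input validation", {
  expect_error(sim_titration(0.05, grid = c(1, 0.5)),
               class = "actinfit_invalid_input")
  expect_error(sim_rate_titration("capping", 15, c(0, 0, 1)),
               class = "actinfit_invalid_input")
  expect_error(sim_titration(0.05, noise = -0.1),
               class = "actinfit_invalid_input")
})
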