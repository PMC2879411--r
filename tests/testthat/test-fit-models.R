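# Named fits: noiseless round-trips, bias at realistic noise,
# identifiability failures, mechanism discrimination.

test_that("noiseless round-trips recover generating constants to 1e-6", {
  d <- sim_rate_titration("capping", 15, seq(0, 0.15, length.out = 12),
                          noise = 0, seed = 1)
  expect_equal(coef(fit_kcap(d))[["Kcap_nM"]], 15, tolerance = 1e-6)

  d <- sim_rate_titration("sequestration", 2.5, seq(0, 8, length.out = 12),
                          A0 = 2, noise = 0, seed = 1)
  expect_equal(coef(fit_kseq(d, A0 = 2))[["Kseq_uM"]], 2.5, tolerance = 1e-6)

  d <- sim_titration(0.05, noise = 0, seed = 1)
  expect_equal(coef(fit_binding(d, 1.5))[["Kd_uM"]], 0.05, tolerance = 1e-6)

  tr <- tibble::tibble(time_s = seq(0, 150, by = 5))
  tr$signal <- exchange_trace(tr$time_s, 0.04, 1.2)
  f <- fit_exchange_trace(tr)
  expect_equal(coef(f)[["k_obs"]], 0.04, tolerance = 1e-8)
  expect_equal(coef(f)[["amplitude"]], 1.2, tolerance = 1e-8)
})

test_that("median bias is small at 2% noise on 12-point grids", {
  kc <- vapply(1:60, function(i) {
    d <- sim_rate_titration("capping", 15, seq(0, 0.15, length.out = 12),
                            noise = 0.02, seed = 400 + i)
    coef(fit_kcap(d))[["Kcap_nM"]]
  }, numeric(1))
  expect_lt(abs(median(kc) - 15) / 15, 0.05)

  ks <- vapply(1:60, function(i) {
    d <- sim_rate_titration("sequestration", 2.5, seq(0, 8, length.out = 12),
                            A0 = 2, noise = 0.02, seed = 500 + i)
    coef(fit_kseq(d, A0 = 2))[["Kseq_uM"]]
  }, numeric(1))
  expect_lt(abs(median(ks) - 2.5) / 2.5, 0.05)

  kd <- vapply(1:60, function(i) {
    d <- sim_titration(3, grid = seq(0, 30, length.out = 12), noise = 0.02,
                       seed = 600 + i)
    coef(fit_binding(d, 1.5))[["Kd_uM"]]
  }, numeric(1))
  expect_lt(abs(median(kd) - 3) / 3, 0.05)
})

test_that("flat titrations raise an identifiability error", {
  d <- tibble::tibble(ligand_conc_uM = seq(0, 1, length.out = 8),
                      norm_rate_pct = rep(100, 8))
  expect_error(fit_kcap(d), class = "actinfit_fit_error")
  expect_error(fit_kseq(d, A0 = 2), class = "actinfit_fit_error")
})

test_that("missing control or too few points are rejected", {
  d <- tibble::tibble(ligand_conc_uM = c(0.1, 0.2, 0.4, 0.8, 1.6),
                      norm_rate_pct = c(90, 70, 50, 30, 10))
  expect_error(fit_kcap(d), class = "actinfit_fit_error") # no control point
  d2 <- tibble::tibble(ligand_conc_uM = c(0, 1), norm_rate_pct = c(100, 40))
  expect_error(fit_kseq(d2, A0 = 2), class = "actinfit_fit_error")
})

test_that("a sequestration grid far below Kseq yields a wide interval", {
  rel_width <- function(K, grid) {
    d <- sim_rate_titration("sequestration", K, grid, A0 = 2, noise = 0.02,
                            seed = 77)
    f <- bootstrap_ci(fit_kseq(d, A0 = 2), n_resamples = 60, seed = 1)
    diff(c(f$conf_int$conf.low[1], f$conf_int$conf.high[1])) / f$estimate[[1]]
  }
  # Kseq = 50 uM probed only to 4 uM (barely any inhibition) versus a
  # well-probed Kseq = 2.5 uM: the under-determined constant is flagged by
  # a far wider relative interval
  under <- rel_width(50, seq(0, 4, length.out = 12))
  well <- rel_width(2.5, seq(0, 8, length.out = 12))
  expect_gt(under, 5 * well)
})

test_that("discrimination recovers the generating mechanism", {
  grid <- seq(0, 10, length.out = 12)
  ms <- discriminate_mechanism(
    sim_mechanism_pair("sequestration", 3, grid, A0_pair = c(2, 4), seed = 101))
  expect_equal(ms$classification, "sequestration")
  expect_gt(ms$ic50_shift_ratio, 1.3) # rightward shift with more actin

  mc <- discriminate_mechanism(
    sim_mechanism_pair("capping", 50, grid, A0_pair = c(2, 4), seed = 102))
  expect_equal(mc$classification, "capping")
  expect_equal(mc$ic50_shift_ratio, 1, tolerance = 0.2) # A0-invariant

  expect_s3_class(tidy(ms), "tbl_df")
})

test_that("discrimination refuses a single-A0 input and can return ambiguous", {
  grid <- seq(0, 10, length.out = 12)
  one <- sim_rate_titration("capping", 50, grid, seed = 103)
  expect_error(discriminate_mechanism(one), class = "actinfit_invalid_input")
  pair <- sim_mechanism_pair("capping", 50, grid, seed = 104)
  amb <- discriminate_mechanism(pair, ambiguity_threshold = Inf)
  expect_equal(amb$classification, "ambiguous")
})
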