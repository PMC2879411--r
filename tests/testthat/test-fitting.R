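# The shared nonlinear least-squares engine and bootstrap machinery.

lin_model <- function(p, d) p[["a"]] * d$x + p[["b"]]

test_that("nls_fit matches closed-form weighted least squares on a linear model", {
  withr::with_seed(3, {
    d <- tibble::tibble(x = seq(0, 10, length.out = 12))
    d$y <- 2.5 * d$x - 1 + rnorm(12, 0, 0.3)
    w <- runif(12, 0.5, 2)
    fit <- nls_fit(d, "y", lin_model, start = c(a = 1, b = 0), weights = w)
    orc <- wls_closed_form(cbind(d$x, 1), d$y, w)
    expect_equal(unname(fit$estimate), unname(orc$beta), tolerance = 1e-10)
    expect_equal(unname(fit$std_error), unname(orc$se), tolerance = 1e-6)
    expect_equal(fit$rss, sum(w * (d$y - lin_model(fit$estimate, d))^2),
                 tolerance = 1e-10)
  })
})

test_that("duplicating the data shrinks standard errors as closed form predicts", {
  withr::with_seed(5, {
    d <- tibble::tibble(x = seq(1, 8, length.out = 10))
    d$y <- 0.7 * d$x + 2 + rnorm(10, 0, 0.2)
    d2 <- dplyr::bind_rows(d, d)
    f1 <- nls_fit(d, "y", lin_model, start = c(a = 1, b = 0))
    f2 <- nls_fit(d2, "y", lin_model, start = c(a = 1, b = 0))
    o1 <- wls_closed_form(cbind(d$x, 1), d$y)
    o2 <- wls_closed_form(cbind(d2$x, 1), d2$y)
    expect_equal(unname(f1$std_error), unname(o1$se), tolerance = 1e-6)
    expect_equal(unname(f2$std_error), unname(o2$se), tolerance = 1e-6)
    expect_true(all(f2$std_error < f1$std_error))
  })
})

test_that("exact data recover exact parameters and zero residual", {
  d <- tibble::tibble(x = 1:10, y = 3 * (1:10) + 4)
  fit <- nls_fit(d, "y", lin_model, start = c(a = 1, b = 0))
  expect_equal(unname(fit$estimate), c(3, 4), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
})

test_that("bound-active solutions are flagged", {
  d <- tibble::tibble(x = 1:10, y = 3 * (1:10))
  fit <- nls_fit(d, "y", function(p, d) p[["a"]] * d$x,
                 start = c(a = 1), lower = 0.1, upper = 2)
  expect_true(fit$bound_active[["a"]])
  expect_equal(fit$estimate[["a"]], 2)
})

test_that("too few points raise a fit error", {
  d <- tibble::tibble(x = 1:3, y = 1:3)
  expect_error(nls_fit(d, "y", lin_model, start = c(a = 1, b = 0)),
               class = "actinfit_fit_error")
})

test_that("fits and bootstrap are bit-reproducible for a fixed seed", {
  d <- sim_rate_titration("capping", 15, seq(0, 0.15, length.out = 12),
                          noise = 0.02, seed = 9)
  f1 <- bootstrap_ci(fit_kcap(d), n_resamples = 50, seed = 21)
  f2 <- bootstrap_ci(fit_kcap(d), n_resamples = 50, seed = 21)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$boot, f2$boot)
  expect_identical(f1$conf_int, f2$conf_int)
  f3 <- bootstrap_ci(fit_kcap(d), n_resamples = 50, seed = 22)
  expect_false(identical(f1$conf_int, f3$conf_int))
})

test_that("bootstrap intervals bracket the estimate and widen with noise", {
  grid <- seq(0, 0.15, length.out = 12)
  width <- vapply(c(0.01, 0.08), function(nz) {
    d <- sim_rate_titration("capping", 15, grid, noise = nz, seed = 31)
    f <- bootstrap_ci(fit_kcap(d), n_resamples = 80, seed = 1)
    expect_true(f$conf_int$conf.low[1] <= f$estimate[[1]])
    expect_true(f$conf_int$conf.high[1] >= f$estimate[[1]])
    diff(c(f$conf_int$conf.low[1], f$conf_int$conf.high[1]))
  }, numeric(1))
  expect_lt(width[1], width[2])
})

test_that("normalize_to_control maps linearly onto percent", {
  expect_equal(normalize_to_control(0.38, 0.38), 100)
  expect_equal(normalize_to_control(0, 0.38), 0)
  raw <- c(0.1, 0.2, 0.3)
  expect_equal(normalize_to_control(2 * raw, 0.4),
               normalize_to_control(raw, 0.2))
})

test_that("tidy and glance summarise a fit", {
  d <- sim_titration(0.05, noise = 0, seed = 1)
  f <- fit_binding(d, 1.5)
  td <- tidy(f)
  expect_setequal(td$term, c("Kd_uM", "F0", "dF"))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$nobs, nrow(d))
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
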