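# Shared weighted nonlinear least-squares engine.
#
# All titration and kinetic fits in the package funnel through nls_fit():
# multi-start Levenberg-Marquardt (minpack.lm::nls.lm) on a user-supplied
# curve function, with box bounds, 1/sd^2 weighting when uncertainties are
# present, a Nelder-Mead fallback, and seeded case-resampling bootstrap CIs.

# numeric jacobian of the weighted residual vector, central differences
num_jacobian <- function(fn, par, eps = 1e-5) {
  r0 <- fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    up <- dn <- par
    up[j] <- par[j] + h
    dn[j] <- par[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

#' Weighted nonlinear least-squares fit with multi-start initialisation
#'
#' Fits `model_fn(par, data)` to `data[[response]]` by minimising the
#' weighted residual sum of squares. Starts are laid out on a log-spaced
#' grid spanning `start_decades` decades around the supplied start for every
#' strictly positive parameter (concentration-like constants are best
#' searched in log space); the best converged start wins. If every
#' Levenberg-Marquardt start fails, a gradient-free Nelder-Mead pass is
#' attempted before giving up.
#'
#' Weighting is `1/sd^2` when a `weights` vector is supplied (callers pass
#' `1/sd^2` from a measured-uncertainty column), otherwise unweighted.
#'
#' @param data a data frame; passed unchanged to `model_fn`.
#' @param response name of the column in `data` holding the observations.
#' @param model_fn function `(par, data) -> numeric` returning predictions,
#'   `par` a named numeric vector.
#' @param start named numeric vector of starting values.
#' @param lower,upper named or recycled numeric bounds (default unbounded).
#' @param weights optional numeric vector of weights (e.g. `1/sd^2`).
#' @param n_starts number of multi-start points (default 7).
#' @param start_decades width of the log-spaced start grid in decades
#'   (default 5).
#' @return an object of class `actinfit_fit`: a list with elements
#'   `estimate`, `std_error`, `rss`, `fitted`, `residuals`, `converged`,
#'   `bound_active`, `n`, `model`, `data`, and (after [bootstrap_ci()])
#'   `conf_int`, `boot`, `seed`.
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
#' f <- nls_fit(d, "y", function(p, d) p[["a"]] * d$x + p[["b"]],
#'              start = c(a = 1, b = 0))
#' coef(f)
#' @seealso [bootstrap_ci()], [generics::tidy()], [generics::glance()]
#' @export
nls_fit <- function(data, response, model_fn, start,
                    lower = rep(-Inf, length(start)),
                    upper = rep(Inf, length(start)),
                    weights = NULL, n_starts = 7, start_decades = 5,
                    model = "custom") {
  stopifnot(is.data.frame(data), response %in% names(data))
  y <- data[[response]]
  n <- length(y)
  p <- length(start)
  if (n < p + 2) {
    abort(sprintf("need at least %d data points to fit %d parameters", p + 2, p),
          class = "actinfit_fit_error")
  }
  w <- weights %||% rep(1, n)
  if (!all(is.finite(w)) || any(w < 0)) {
    abort("weights must be finite and non-negative", class = "actinfit_fit_error")
  }
  sw <- sqrt(w)
  resid_fn <- function(par) {
    pr <- model_fn(stats::setNames(par, names(start)), data)
    sw * (y - pr)
  }

  lower <- rep_len(lower, p)
  upper <- rep_len(upper, p)

  # deterministic multi-start: joint log shifts for positive parameters
  shifts <- if (n_starts > 1) seq(-start_decades / 2, start_decades / 2,
                                  length.out = n_starts) else 0
  starts <- lapply(shifts, function(s) {
    st <- start
    pos <- start > 0 & is.finite(start)
    st[pos] <- pmin(pmax(start[pos] * 10^s, lower[pos] + 1e-12),
                    ifelse(is.finite(upper[pos]), upper[pos], start[pos] * 10^s))
    st
  })
  starts <- unique(starts)

  best <- NULL
  diagnostics <- character(0)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  if (is.null(best)) {
    # gradient-free fallback: Brent for one parameter, Nelder-Mead otherwise
    obj <- function(par) sum(resid_fn(par)^2)
    nm <- tryCatch(
      if (p == 1L) {
        lo <- if (is.finite(lower)) lower else start / 1e6
        hi <- if (is.finite(upper)) upper else start * 1e6
        stats::optim(start, obj, method = "Brent", lower = lo, upper = hi)
      } else {
        stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000))
      },
      error = function(e) e)
    if (inherits(nm, "error")) {
      abort(paste0("all fit starts failed: ",
                   paste(unique(diagnostics), collapse = "; ")),
            class = "actinfit_fit_error")
    }
    est <- pmin(pmax(nm$par, lower), upper)
    rss <- nm$value
    converged <- nm$convergence == 0
  } else {
    est <- stats::setNames(best$par, names(start))
    rss <- best$deviance
    converged <- best$info %in% 1:4
    # Gauss-Newton polish: tightens the optimum to near machine precision
    # (exact in one step for models linear in the parameters)
    for (it in 1:3) {
      r <- resid_fn(est)
      J <- tryCatch(num_jacobian(resid_fn, est), error = function(e) NULL)
      if (is.null(J)) break
      step <- tryCatch(drop(solve(crossprod(J), crossprod(J, r))),
                       error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- pmin(pmax(est - step, lower), upper)
      rss_cand <- sum(resid_fn(cand)^2)
      if (rss_cand <= rss * (1 + 1e-12)) {
        est <- stats::setNames(cand, names(start))
        rss <- min(rss_cand, rss)
      } else break
    }
  }

  fitted <- model_fn(est, data)
  res <- y - fitted
  bound_active <- (is.finite(lower) & abs(est - lower) < 1e-10 * pmax(abs(est), 1)) |
                  (is.finite(upper) & abs(est - upper) < 1e-10 * pmax(abs(est), 1))

  # asymptotic SEs from the weighted jacobian
  se <- rep(NA_real_, p)
  if (n > p) {
    J <- tryCatch(num_jacobian(resid_fn, est), error = function(e) NULL)
    if (!is.null(J)) {
      JtJ <- crossprod(J)
      sig2 <- rss / (n - p)
      V <- tryCatch(solve(JtJ) * sig2, error = function(e) NULL)
      if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
    }
  }

  structure(list(
    estimate = stats::setNames(as.numeric(est), names(start)),
    std_error = stats::setNames(se, names(start)),
    rss = rss,
    fitted = fitted,
    residuals = res,
    converged = converged,
    bound_active = stats::setNames(bound_active, names(start)),
    n = n,
    model = model,
    response = response,
    model_fn = model_fn,
    lower = lower, upper = upper,
    weights = weights,
    data = as_tibble(data),
    conf_int = NULL, boot = NULL, seed = NA_integer_
  ), class = "actinfit_fit")
}

#' Seeded case-resampling bootstrap confidence intervals
#'
#' Refits the model to `n_resamples` case (row) resamples of the original
#' data and stores the 2.5/97.5 percentile interval on the fit object.
#' Fully reproducible: the same seed, data and model give bit-identical
#' intervals.
#'
#' @param fit an [nls_fit()] result.
#' @param n_resamples number of bootstrap resamples (default 500).
#' @param seed integer seed controlling resampling.
#' @param level confidence level (default 0.95).
#' @return the fit object with `conf_int` (tibble: term, conf.low,
#'   conf.high), `boot` (matrix of resample estimates) and `seed` filled in.
#' @export
bootstrap_ci <- function(fit, n_resamples = 500, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "actinfit_fit"))
  dat <- fit$data
  n <- nrow(dat)
  p <- length(fit$estimate)
  idx_mat <- withr::with_seed(seed,
    matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n))
  est <- fit$estimate
  boot <- matrix(NA_real_, n_resamples, p,
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(n_resamples)) {
    db <- dat[idx_mat[, b], , drop = FALSE]
    wb <- if (is.null(fit$weights)) NULL else fit$weights[idx_mat[, b]]
    fb <- tryCatch(
      nls_fit(db, fit$response, fit$model_fn, start = est,
              lower = fit$lower, upper = fit$upper, weights = wb,
              n_starts = 1, model = fit$model),
      error = function(e) NULL)
    if (!is.null(fb)) boot[b, ] <- fb$estimate
  }
  alpha <- (1 - level) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  fit$conf_int <- tibble(term = names(est),
                         conf.low = pmin(ci[1, ], est),
                         conf.high = pmax(ci[2, ], est))
  fit$boot <- boot
  fit$seed <- as.integer(seed)
  fit
}

#' Normalise raw rates to percent of control
#'
#' Linear scaling that maps the uninhibited control rate to 100%.
#'
#' @param raw numeric vector of raw rates.
#' @param control the control (zero-inhibitor) rate.
#' @return rates as percent of control.
#' @examples
#' normalize_to_control(c(0.38, 0.19, 0), 0.38)
#' @export
normalize_to_control <- function(raw, control) {
  check_num(raw = raw)
  check_pos(control = control)
  100 * raw / control
}

#' @export
coef.actinfit_fit <- function(object, ...) object$estimate

#' @export
print.actinfit_fit <- function(x, ...) {
  cat(sprintf("<actinfit_fit: %s>  n = %d, RSS = %.6g, converged = %s\n",
              x$model, x$n, x$rss, x$converged))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted actinfit model
#'
#' @param x an [nls_fit()] object.
#' @param ... unused.
#' @return a tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, and bootstrap `conf.low`/`conf.high` when available.
#' @export
tidy.actinfit_fit <- function(x, ...) {
  out <- tibble(term = names(x$estimate),
                estimate = unname(x$estimate),
                std.error = unname(x$std_error))
  if (!is.null(x$conf_int)) {
    out <- dplyr::left_join(out, x$conf_int, by = "term")
  }
  out
}

#' One-row fit summary
#'
#' @param x an [nls_fit()] object.
#' @param ... unused.
#' @return a one-row tibble: `rss`, `sigma`, `df.residual`, `converged`,
#'   `nobs`, `n_boot`, `seed`, `model`.
#' @export
glance.actinfit_fit <- function(x, ...) {
  p <- length(x$estimate)
  tibble(rss = x$rss,
         sigma = sqrt(x$rss / max(x$n - p, 1)),
         df.residual = x$n - p,
         converged = x$converged,
         nobs = x$n,
         n_boot = if (is.null(x$boot)) 0L else nrow(x$boot),
         seed = x$seed,
         model = x$model)
}

#' Plot a fitted titration with its data
#'
#' @param object an [nls_fit()] object whose data contain a single numeric
#'   predictor column (the first non-response numeric column is used).
#' @param ... unused.
#' @return a ggplot object: points for the data, a line for the fitted
#'   curve on a dense grid.
#' @export
autoplot.actinfit_fit <- function(object, ...) {
  dat <- object$data
  xcols <- setdiff(names(dat)[vapply(dat, is.numeric, logical(1))],
                   object$response)
  xcol <- xcols[1]
  grid <- dat[rep(1L, 200L), , drop = FALSE]
  grid[[xcol]] <- seq(min(dat[[xcol]]), max(dat[[xcol]]), length.out = 200)
  grid$.fitted <- object$model_fn(object$estimate, grid)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[xcol]],
                                    y = .data[[object$response]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$.fitted),
                       colour = "#2166ac") +
    ggplot2::labs(x = xcol, y = object$response,
                  title = sprintf("%s fit", object$model)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
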