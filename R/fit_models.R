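# Named fits for the assay classes: equilibrium titrations (Kd),
# capping titrations (Kcap), sequestration titrations (Kseq),
# exchange traces (k_obs), and capping-vs-sequestration discrimination.
#
# Each wrapper assembles a curve model for nls_fit(), picks starts from the
# data-implied scale, applies 1/sd^2 weights when an uncertainty column is
# present, and optionally attaches seeded bootstrap intervals.

rate_weights <- function(data, sd_col) {
  if (sd_col %in% names(data) && all(is.finite(data[[sd_col]])) &&
      all(data[[sd_col]] > 0)) 1 / data[[sd_col]]^2 else NULL
}

check_titration_range <- function(y, min_range, what) {
  if (diff(range(y)) < min_range) {
    abort(sprintf("%s is flat (dynamic range %.3g); constant not identifiable",
                  what, diff(range(y))),
          class = "actinfit_fit_error")
  }
}

#' Fit a 1:1 binding titration (depletion isotherm)
#'
#' Fits `F = F0 + dF * C(A0, L0, Kd)/A0` (see [predicted_signal()]) to a
#' fluorescence titration by weighted nonlinear least squares, estimating
#' the dissociation constant together with the baseline and saturation
#' increment.
#'
#' @param data tibble with columns `ligand_conc_uM`, `signal`, and
#'   optionally `signal_sd` (used as 1/sd^2 weights).
#' @param A0 total labelled actin, µM.
#' @param n_boot bootstrap resamples for confidence intervals (0 = none).
#' @param seed seed for the bootstrap.
#' @return an `actinfit_fit` with parameters `Kd_uM`, `F0`, `dF`.
#' @examples
#' d <- tibble::tibble(ligand_conc_uM = seq(0, 2, length.out = 15))
#' d$signal <- predicted_signal(1.5, d$ligand_conc_uM, 0.05, 100, 20)
#' coef(fit_binding(d, A0 = 1.5))
#' @export
fit_binding <- function(data, A0, n_boot = 0, seed = 1L) {
  stopifnot(all(c("ligand_conc_uM", "signal") %in% names(data)))
  check_pos(A0 = A0)
  y <- data$signal
  check_titration_range(y, 1e-9 * max(abs(y), 1), "binding titration")
  ctrl <- y[which.min(data$ligand_conc_uM)]
  span <- y[which.max(data$ligand_conc_uM)] - ctrl
  # Kd start: ligand at half signal change, net of stoichiometric depletion
  half <- ctrl + span / 2
  kd0 <- tryCatch({
    o <- order(data$ligand_conc_uM)
    stats::approx(y[o], data$ligand_conc_uM[o], xout = half, ties = mean)$y
  }, error = function(e) NA_real_)
  kd0 <- max(kd0 - A0 / 2, max(data$ligand_conc_uM) / 100, 1e-4, na.rm = TRUE)
  fit <- nls_fit(
    data, "signal",
    function(p, d) predicted_signal(A0, d$ligand_conc_uM, p[["Kd_uM"]],
                                    p[["F0"]], p[["dF"]]),
    start = c(Kd_uM = kd0, F0 = ctrl, dF = span),
    lower = c(1e-8, -Inf, -Inf), upper = c(1e5, Inf, Inf),
    weights = rate_weights(data, "signal_sd"),
    model = "binding_1to1")
  if (n_boot > 0) fit <- bootstrap_ci(fit, n_boot, seed)
  fit
}

#' Fit a barbed-end capping titration
#'
#' Estimates the end-binding dissociation constant `Kcap` from normalized
#' elongation rates versus capper concentration, using the end-depletion
#' quadratic (see [capping_curve()]). Input rates are clipped to the 0-120% range
#' before fitting.
#'
#' @param data tibble with columns `ligand_conc_uM` (capper, µM),
#'   `norm_rate_pct`, and optionally `rate_sd`.
#' @param ends0 free filament-end concentration, nM.
#' @param depletion use the depletion quadratic (default) or the hyperbola.
#' @inheritParams fit_binding
#' @return an `actinfit_fit` with parameter `Kcap_nM`.
#' @examples
#' d <- tibble::tibble(ligand_conc_uM = seq(0, 0.15, length.out = 12))
#' d$norm_rate_pct <- capping_curve(d$ligand_conc_uM * 1e3, Kcap = 15)
#' coef(fit_kcap(d))
#' @export
fit_kcap <- function(data, ends0 = 2, depletion = TRUE, n_boot = 0, seed = 1L) {
  stopifnot(all(c("ligand_conc_uM", "norm_rate_pct") %in% names(data)))
  if (nrow(data) < 5 || !any(data$ligand_conc_uM == 0)) {
    abort("capping fit needs >= 5 grid points including a ligand-free control",
          class = "actinfit_fit_error")
  }
  data$norm_rate_pct <- pmin(pmax(data$norm_rate_pct, 0), 120)
  check_titration_range(data$norm_rate_pct, 2, "capping titration")
  conc_nM <- data$ligand_conc_uM * 1e3
  k0 <- tryCatch(ic50(conc_nM, data$norm_rate_pct),
                 error = function(e) stats::median(conc_nM[conc_nM > 0]))
  k0 <- max(k0 - ends0 / 2, min(conc_nM[conc_nM > 0]) / 10, 1e-3)
  fit <- nls_fit(
    data, "norm_rate_pct",
    function(p, d) capping_curve(d$ligand_conc_uM * 1e3, p[["Kcap_nM"]],
                                 ends0 = ends0, depletion = depletion),
    start = c(Kcap_nM = k0), lower = 1e-6, upper = 1e7,
    weights = rate_weights(data, "rate_sd"),
    model = "capping")
  if (n_boot > 0) fit <- bootstrap_ci(fit, n_boot, seed)
  fit
}

#' Fit a sequestration titration
#'
#' Estimates the monomer-sequestration constant `Kseq` from normalized
#' elongation rates versus sequesterer concentration (see
#' [sequestration_curve()]). Input rates are clipped to the 0-120% range.
#'
#' @param data tibble with columns `ligand_conc_uM`, `norm_rate_pct`, and
#'   optionally `rate_sd`.
#' @param A0 total G-actin, µM.
#' @param Cc critical concentration at the assayed end, µM (default 0.6,
#'   pointed end).
#' @inheritParams fit_binding
#' @return an `actinfit_fit` with parameter `Kseq_uM`.
#' @examples
#' d <- tibble::tibble(ligand_conc_uM = seq(0, 8, length.out = 12))
#' d$norm_rate_pct <- sequestration_curve(d$ligand_conc_uM, 2.5, A0 = 2)
#' coef(fit_kseq(d, A0 = 2))
#' @export
fit_kseq <- function(data, A0, Cc = 0.6, n_boot = 0, seed = 1L) {
  stopifnot(all(c("ligand_conc_uM", "norm_rate_pct") %in% names(data)))
  if (nrow(data) < 5 || !any(data$ligand_conc_uM == 0)) {
    abort("sequestration fit needs >= 5 grid points including a control",
          class = "actinfit_fit_error")
  }
  data$norm_rate_pct <- pmin(pmax(data$norm_rate_pct, 0), 120)
  check_titration_range(data$norm_rate_pct, 2, "sequestration titration")
  k0 <- tryCatch(ic50(data$ligand_conc_uM, data$norm_rate_pct),
                 error = function(e) stats::median(
                   data$ligand_conc_uM[data$ligand_conc_uM > 0]))
  k0 <- max(k0 - (A0 - Cc) / 2, 1e-3)
  fit <- nls_fit(
    data, "norm_rate_pct",
    function(p, d) sequestration_curve(d$ligand_conc_uM, p[["Kseq_uM"]],
                                       A0 = A0, Cc = Cc),
    start = c(Kseq_uM = k0), lower = 1e-8, upper = 1e5,
    weights = rate_weights(data, "rate_sd"),
    model = "sequestration")
  if (n_boot > 0) fit <- bootstrap_ci(fit, n_boot, seed)
  fit
}

#' Fit a single-exponential exchange trace
#'
#' Recovers the pseudo-first-order rate constant and amplitude of a
#' fluorescent-nucleotide incorporation trace,
#' \eqn{F(t) = F_\infty (1 - e^{-k_{obs} t})}.
#'
#' @param data tibble with columns `time_s`, `signal`.
#' @inheritParams fit_binding
#' @return an `actinfit_fit` with parameters `k_obs` (s^-1) and
#'   `amplitude`.
#' @examples
#' d <- tibble::tibble(time_s = seq(0, 120, by = 5))
#' d$signal <- exchange_trace(d$time_s, k_obs = 0.04, amplitude = 1.2)
#' coef(fit_exchange_trace(d))
#' @export
fit_exchange_trace <- function(data, n_boot = 0, seed = 1L) {
  stopifnot(all(c("time_s", "signal") %in% names(data)))
  amp0 <- max(data$signal)
  check_titration_range(data$signal, 1e-9 * max(abs(amp0), 1), "exchange trace")
  # initial-slope start for k_obs
  i <- order(data$time_s)
  t1 <- data$time_s[i][2]; y1 <- data$signal[i][2]
  k0 <- max(-log(max(1 - y1 / amp0, 1e-3)) / max(t1, 1e-9), 1e-4)
  fit <- nls_fit(
    data, "signal",
    function(p, d) exchange_trace(d$time_s, p[["k_obs"]], p[["amplitude"]]),
    start = c(k_obs = k0, amplitude = amp0),
    lower = c(1e-9, -Inf), upper = c(1e4, Inf),
    model = "exchange_trace")
  if (n_boot > 0) fit <- bootstrap_ci(fit, n_boot, seed)
  fit
}

#' Discriminate capping from sequestration using titrations at two actin
#' concentrations
#'
#' Capping acts on filament ends, so its dose-response is invariant to the
#' total G-actin concentration; sequestration removes monomer, so the
#' concentration needed for half-inhibition grows roughly linearly with
#' total actin (curves shift to higher ligand, i.e. rightward). Fitting
#' both mechanisms jointly across a pair of titrations that differ only in
#' `A0` and comparing residual sums of squares classifies the mechanism;
#' the IC50 shift ratio between the two actin concentrations is reported
#' as corroborating evidence.
#'
#' @param data tibble with columns `ligand_conc_uM`, `norm_rate_pct`,
#'   `A0_uM` containing exactly two distinct `A0_uM` values, and optionally
#'   `rate_sd`.
#' @param ends0 free-end concentration for the capping model, nM.
#' @param Cc critical concentration for the sequestration model, µM.
#' @param ambiguity_threshold relative RSS difference below which the call
#'   is `"ambiguous"` rather than a forced choice (default 0.05).
#' @return an object of class `actinfit_mechanism`: a list with
#'   `classification` (`"capping"`, `"sequestration"` or `"ambiguous"`),
#'   `rss` (named), `ic50` (per-`A0` tibble), `ic50_shift_ratio`, and the
#'   two joint fits.
#' @examples
#' g <- seq(0, 10, length.out = 12)
#' pair <- dplyr::bind_rows(
#'   tibble::tibble(ligand_conc_uM = g, A0_uM = 2,
#'                  norm_rate_pct = sequestration_curve(g, 3, 2)),
#'   tibble::tibble(ligand_conc_uM = g, A0_uM = 4,
#'                  norm_rate_pct = sequestration_curve(g, 3, 4)))
#' discriminate_mechanism(pair)$classification
#' @export
discriminate_mechanism <- function(data, ends0 = 2, Cc = 0.6,
                                   ambiguity_threshold = 0.05) {
  stopifnot(all(c("ligand_conc_uM", "norm_rate_pct", "A0_uM") %in% names(data)))
  a0s <- sort(unique(data$A0_uM))
  if (length(a0s) != 2) {
    abort("discrimination needs titrations at exactly two distinct `A0_uM`",
          class = "actinfit_invalid_input")
  }
  data$norm_rate_pct <- pmin(pmax(data$norm_rate_pct, 0), 120)
  w <- rate_weights(data, "rate_sd")

  conc_nM <- data$ligand_conc_uM * 1e3
  k0_cap <- tryCatch(ic50(conc_nM, data$norm_rate_pct) ,
                     error = function(e) stats::median(conc_nM[conc_nM > 0]))
  fit_cap <- nls_fit(
    data, "norm_rate_pct",
    function(p, d) capping_curve(d$ligand_conc_uM * 1e3, p[["Kcap_nM"]],
                                 ends0 = ends0),
    start = c(Kcap_nM = max(k0_cap, 1e-3)), lower = 1e-6, upper = 1e7,
    weights = w, model = "capping_joint")
  k0_seq <- tryCatch(ic50(data$ligand_conc_uM, data$norm_rate_pct),
                     error = function(e) stats::median(
                       data$ligand_conc_uM[data$ligand_conc_uM > 0]))
  fit_seq <- nls_fit(
    data, "norm_rate_pct",
    function(p, d) sequestration_curve(d$ligand_conc_uM, p[["Kseq_uM"]],
                                       A0 = d$A0_uM, Cc = Cc),
    start = c(Kseq_uM = max(k0_seq, 1e-3)), lower = 1e-8, upper = 1e5,
    weights = w, model = "sequestration_joint")

  rss <- c(capping = fit_cap$rss, sequestration = fit_seq$rss)
  rel_diff <- abs(diff(rss)) / max(min(rss), .Machine$double.eps)
  classification <- if (rel_diff < ambiguity_threshold) "ambiguous"
                    else names(rss)[which.min(rss)]

  ic50_tbl <- purrr::map_dfr(a0s, function(a) {
    sub <- dplyr::filter(data, .data$A0_uM == a)
    tibble(A0_uM = a,
           ic50_uM = tryCatch(ic50(sub$ligand_conc_uM, sub$norm_rate_pct),
                              error = function(e) NA_real_))
  })
  shift <- ic50_tbl$ic50_uM[2] / ic50_tbl$ic50_uM[1]

  structure(list(classification = classification,
                 rss = rss, rss_rel_diff = rel_diff,
                 ic50 = ic50_tbl, ic50_shift_ratio = shift,
                 fit_capping = fit_cap, fit_sequestration = fit_seq),
            class = "actinfit_mechanism")
}

#' @export
print.actinfit_mechanism <- function(x, ...) {
  cat(sprintf("<mechanism discrimination>  call: %s\n", x$classification))
  cat(sprintf("  RSS capping = %.4g, sequestration = %.4g (rel. diff %.2f%%)\n",
              x$rss[["capping"]], x$rss[["sequestration"]],
              100 * x$rss_rel_diff))
  cat(sprintf("  IC50 shift ratio (high/low A0) = %.3g\n", x$ic50_shift_ratio))
  invisible(x)
}

#' @rdname tidy.actinfit_fit
#' @export
tidy.actinfit_mechanism <- function(x, ...) {
  tibble(mechanism = names(x$rss),
         rss = unname(x$rss),
         estimate = c(x$fit_capping$estimate, x$fit_sequestration$estimate),
         term = c(names(x$fit_capping$estimate),
                  names(x$fit_sequestration$estimate)),
         selected = names(x$rss) == x$classification)
}
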