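# Native molecular weight and shape from size-exclusion chromatography and
# density-gradient sedimentation: marker calibration, the Siegel-Monty
# relation MW = alpha * a * s, and prolate axial ratio via the Perrin
# translational friction function.

#' Linear marker calibration
#'
#' Ordinary least-squares line relating a hydrodynamic property of marker
#' proteins (Stokes radius, Svedberg coefficient, or molecular weight) to
#' their observed position (elution volume or gradient fraction). With two
#' markers the line interpolates exactly (R^2 = 1).
#'
#' @param series tibble with columns `observed_position` and `known_value`
#'   (>= 2 markers, strictly monotone positions).
#' @return an object of class `actinfit_calibration`: list with `slope`,
#'   `intercept`, `r_squared`, `range` (of positions), and the input
#'   `series`.
#' @examples
#' s <- tibble::tibble(observed_position = c(10, 12, 14, 16),
#'                     known_value = c(11.4, 7.4, 4.22, 2.58))
#' linear_calibration(s)$r_squared
#' @export
linear_calibration <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("observed_position", "known_value") %in% names(series)))
  x <- series$observed_position
  y <- series$known_value
  if (length(x) < 2) {
    abort("calibration needs at least two markers", class = "actinfit_invalid_input")
  }
  if (any(diff(order(x)) == 0) || anyDuplicated(x)) {
    abort("marker positions must be strictly monotone (no duplicates)",
          class = "actinfit_invalid_input")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 range = range(x),
                 series = as_tibble(series)),
            class = "actinfit_calibration")
}

#' @export
print.actinfit_calibration <- function(x, ...) {
  cat(sprintf("<calibration: %d markers>  value = %.4g + %.4g * position, R^2 = %.4f\n",
              nrow(x$series), x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Interpolate a sample position on a marker calibration
#'
#' Linear prediction of the physical value (Stokes radius or Svedberg
#' coefficient) at an observed sample position, with a flag distinguishing
#' interpolation inside the marker range from extrapolation.
#'
#' @param calibration a [linear_calibration()] object.
#' @param position observed sample position(s).
#' @return tibble with `position`, `value`, `extrapolated`.
#' @export
interpolate_calibration <- function(calibration, position) {
  stopifnot(inherits(calibration, "actinfit_calibration"))
  check_num(position = position)
  tibble(position = position,
         value = calibration$intercept + calibration$slope * position,
         extrapolated = position < calibration$range[1] |
                        position > calibration$range[2])
}

#' Empirical Siegel-Monty factor from standards
#'
#' The proportionality factor in `MW = alpha * a * s` absorbs solvent
#' viscosity, density and the partial specific volume. Rather than
#' computing it from buffer properties it is calibrated empirically as the
#' through-origin slope of standard-protein molecular weights against
#' their `a * s` products.
#'
#' @param standards tibble with columns `mw_kD`, `stokes_A` (Angstrom) and
#'   `s_svedberg`.
#' @return alpha such that `mw_kD = alpha * stokes_A * s_svedberg`.
#' @examples
#' std <- tibble::tibble(mw_kD = c(25, 158, 232),
#'                       stokes_A = c(20.9, 48.1, 52.2),
#'                       s_svedberg = c(2.58, 7.4, 11.4))
#' alpha_from_standards(std)
#' @export
alpha_from_standards <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("mw_kD", "stokes_A", "s_svedberg") %in% names(standards)))
  as_prod <- standards$stokes_A * standards$s_svedberg
  check_pos(as_prod = as_prod, mw = standards$mw_kD)
  fit <- lm(mw_kD ~ 0 + as_prod, data = tibble(mw_kD = standards$mw_kD,
                                               as_prod = as_prod))
  unname(coef(fit)[1])
}

#' Siegel-Monty native molecular weight
#'
#' `MW = alpha * a * s`, combining the Stokes radius from gel filtration
#' with the sedimentation coefficient from a density gradient; the
#' combination cancels the shape dependence that makes either measurement
#' alone unreliable for elongated proteins.
#'
#' @param a Stokes radius, Angstrom.
#' @param s sedimentation coefficient, Svedberg.
#' @param alpha calibration factor from [alpha_from_standards()].
#' @return molecular weight, kD.
#' @export
mw_siegel_monty <- function(a, s, alpha) {
  check_pos(a = a, s = s, alpha = alpha)
  alpha * a * s
}

# Perrin translational friction factor for a prolate ellipsoid with axial
# ratio p = a/b > 1 (q = 1/p): F(p) = sqrt(1-q^2) / (q^(2/3) * log((1 + sqrt(1-q^2))/q))
perrin_prolate <- function(p) {
  check_num(p = p)
  out <- numeric(length(p))
  one <- abs(p - 1) < 1e-12
  out[one] <- 1
  q <- 1 / p[!one]
  e <- sqrt(1 - q^2)
  out[!one] <- e / (q^(2 / 3) * log((1 + e) / q))
  out
}

#' Axial ratio of a prolate ellipsoid from its frictional ratio
#'
#' Numerically inverts the Perrin translational shape function for a
#' prolate ellipsoid of revolution: given the frictional ratio `f/f0`
#' (observed friction over that of the anhydrous sphere of equal volume),
#' returns the axial ratio `p = a/b >= 1`. The function is monotone
#' increasing, with `p = 1` exactly at `f/f0 = 1`; inversion is by
#' bisection (`uniroot`) on `p` in `[1, 1e4]`.
#'
#' @param f_ratio frictional ratio `f/f0` (>= 1). Vectorised.
#' @return prolate axial ratio `p`.
#' @examples
#' axial_ratio_prolate(1.5)
#' @export
axial_ratio_prolate <- function(f_ratio) {
  check_num(f_ratio = f_ratio)
  if (any(f_ratio < 1)) {
    abort("frictional ratio `f/f0` must be >= 1", class = "actinfit_invalid_input")
  }
  vapply(f_ratio, function(fr) {
    if (fr - 1 < 1e-12) return(1)
    uniroot(function(p) perrin_prolate(p) - fr, c(1 + 1e-10, 1e4),
            tol = 1e-12)$root
  }, numeric(1))
}

#' Full hydrodynamic characterisation
#'
#' Combines calibrated Stokes radius and sedimentation coefficient into a
#' Siegel-Monty molecular weight, then derives the frictional ratio from
#' the anhydrous minimal sphere (partial specific volume `nu`) and the
#' prolate axial ratio.
#'
#' The minimal-sphere Stokes radius is
#' \eqn{a_0 = (3 MW \nu / (4 \pi N_A))^{1/3}} and `f/f0 = a / a0`
#' (hydration is not modelled beyond `nu`).
#'
#' @param a Stokes radius, Angstrom.
#' @param s sedimentation coefficient, Svedberg.
#' @param alpha Siegel-Monty factor.
#' @param nu partial specific volume, mL/g (default 0.73).
#' @return one-row tibble: `stokes_A`, `s_svedberg`, `alpha`, `mw_kD`,
#'   `f_ratio`, `axial_ratio`.
#' @export
hydro_report <- function(a, s, alpha, nu = 0.73) {
  mw <- mw_siegel_monty(a, s, alpha)
  check_pos(nu = nu)
  # a0 in cm from MW in g/mol: (3 * MW * nu / (4 pi N_A))^(1/3); 1 cm = 1e8 A
  NA_avog <- 6.02214076e23
  a0_cm <- (3 * (mw * 1000) * nu / (4 * pi * NA_avog))^(1 / 3)
  a0_A <- a0_cm * 1e8
  f_ratio <- max(a / a0_A, 1)
  tibble(stokes_A = a, s_svedberg = s, alpha = alpha, mw_kD = mw,
         f_ratio = f_ratio, axial_ratio = axial_ratio_prolate(f_ratio))
}
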