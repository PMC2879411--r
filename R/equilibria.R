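# Binding equilibria: 1:1 ligand-depletion isotherm, exact competition,
# two independent sites, and the fluorescence observation model.
#
# Internal units are micromolar throughout. The depletion quadratic is the
# standard treatment when total receptor is comparable to Kd, so free and
# total ligand cannot be identified; all occupancies here come from solving
# mass action plus conservation exactly, never from the free≈total shortcut.

#' Equilibrium complex concentration for a 1:1 binding system
#'
#' Solves the mass-action equilibrium \eqn{(A_0 - C)(L_0 - C) = K_d C} for
#' the complex concentration `C`, taking ligand depletion into account. This
#' is the isotherm behind fluorescence titrations of labelled G-actin with a
#' monomer-binding ligand: the physically meaningful root of the quadratic,
#' with \eqn{0 \le C \le \min(A_0, L_0)}.
#'
#' The root is computed in the numerically stable form
#' \eqn{C = 2 A_0 L_0 / (b + \sqrt{b^2 - 4 A_0 L_0})} with
#' \eqn{b = A_0 + L_0 + K_d}, which avoids cancellation when
#' \eqn{K_d \ll A_0, L_0}.
#'
#' @param A0 total receptor (e.g. G-actin) concentration, µM. Vectorised.
#' @param L0 total ligand concentration, µM. Vectorised.
#' @param Kd equilibrium dissociation constant, µM (> 0).
#' @return complex concentration in µM, same length as the recycled inputs.
#' @examples
#' complex_concentration(A0 = 1.5, L0 = 1.5, Kd = 0.05)
#' @seealso [predicted_signal()], [competition_solve()]
#' @export
complex_concentration <- function(A0, L0, Kd) {
  check_nonneg(A0 = A0, L0 = L0)
  check_pos(Kd = Kd)
  b <- A0 + L0 + Kd
  disc <- b * b - 4 * A0 * L0
  disc[disc < 0] <- 0 # guard tiny negative round-off
  C <- 2 * A0 * L0 / (b + sqrt(disc))
  pmin(C, pmin(A0, L0))
}

#' Predicted fluorescence signal of a 1:1 titration
#'
#' Observation model linking fractional occupancy of the labelled species to
#' the measured signal: \eqn{F = F_0 + \Delta F \cdot C/A_0}, where `C` is
#' the depletion-quadratic complex concentration. For a probe whose
#' fluorescence rises on complex formation (`dF > 0`) the signal is bounded
#' in `[F0, F0 + dF]`.
#'
#' @inheritParams complex_concentration
#' @param F0 baseline fluorescence (arbitrary units) at zero occupancy.
#' @param dF signal change at full occupancy (same units as `F0`).
#' @return predicted signal, vectorised over `L0`.
#' @examples
#' predicted_signal(A0 = 1.5, L0 = c(0, 0.5, 1.5, 10), Kd = 0.05,
#'                  F0 = 100, dF = 20)
#' @export
predicted_signal <- function(A0, L0, Kd, F0, dF) {
  check_pos(A0 = A0)
  check_num(F0 = F0, dF = dF)
  C <- complex_concentration(A0, L0, Kd)
  F0 + dF * (C / A0)
}

#' Exact ternary competition equilibrium
#'
#' Two ligands E and T compete for the same site on monomeric actin. The
#' coupled equilibria are reduced to a single monotone equation in free
#' actin `a`:
#' \deqn{a + E_0 a/(K_E + a) + T_0 a/(K_T + a) = A_0}
#' solved by bracketed root search on `[0, A0]` and polished by Newton
#' steps so all three conservation laws hold to relative 1e-9 or better.
#'
#' @param A0 total actin, µM.
#' @param E0,K_E total concentration and dissociation constant of the first
#'   ligand (e.g. a capping-domain fragment), µM.
#' @param T0,K_T total concentration and dissociation constant of the second
#'   ligand (e.g. thymosin beta-4), µM.
#' @return a one-row tibble with columns `free_actin`, `AE`, `AT`,
#'   `free_E`, `free_T` (µM) and `residual` (largest relative conservation
#'   residual).
#' @examples
#' competition_solve(A0 = 1.5, E0 = 15, K_E = 7.5, T0 = 25, K_T = 3)
#' @export
competition_solve <- function(A0, E0, K_E, T0, K_T) {
  check_nonneg(A0 = A0, E0 = E0, T0 = T0)
  check_pos(K_E = K_E, K_T = K_T)
  if (A0 == 0) {
    return(tibble(free_actin = 0, AE = 0, AT = 0,
                  free_E = E0, free_T = T0, residual = 0))
  }
  g <- function(a) a + E0 * a / (K_E + a) + T0 * a / (K_T + a) - A0
  root <- uniroot(g, interval = c(0, A0), tol = .Machine$double.eps^0.75)$root
  # Newton polish: g is smooth and increasing on [0, A0]
  gp <- function(a) 1 + E0 * K_E / (K_E + a)^2 + T0 * K_T / (K_T + a)^2
  a <- root
  for (i in 1:5) {
    step <- g(a) / gp(a)
    a <- min(max(a - step, 0), A0)
    if (abs(step) < 1e-16 * max(a, 1e-300)) break
  }
  AE <- E0 * a / (K_E + a)
  AT <- T0 * a / (K_T + a)
  res <- abs(a + AE + AT - A0) / A0
  if (!is.finite(res) || res > 1e-8) {
    abort(sprintf("competition solver failed to conserve mass (residual %.3g)", res),
          class = "actinfit_numeric_error")
  }
  tibble(free_actin = a, AE = AE, AT = AT,
         free_E = E0 - AE, free_T = T0 - AT, residual = res)
}

#' Apparent dissociation constant of a competed ligand
#'
#' Linear competition approximation: in the presence of a fixed
#' concentration `E0` of a competitor with constant `K_E`, the apparent
#' dissociation constant of the reporter ligand is
#' \deqn{K_{app} = K_T^0 (1 + E_0 / K_E).}
#' The approximation assumes the competitor is not significantly depleted
#' (valid when total actin is well below both constants); the exact
#' alternative is [competition_solve()].
#'
#' @param K_T0 dissociation constant of the reporter ligand alone, µM.
#' @param E0 total competitor concentration, µM.
#' @param K_E competitor dissociation constant, µM.
#' @return apparent dissociation constant, µM (always >= `K_T0`).
#' @examples
#' apparent_kd(K_T0 = 3, E0 = 15, K_E = 7.5) # 9
#' @export
apparent_kd <- function(K_T0, E0, K_E) {
  check_pos(K_T0 = K_T0, K_E = K_E)
  check_nonneg(E0 = E0)
  K_T0 * (1 + E0 / K_E)
}

#' Invert the apparent-Kd relation for the competitor's constant
#'
#' Given a measured `K_app` at competitor load `E0`, returns the competitor
#' dissociation constant implied by the linear competition formula:
#' \eqn{K_E = E_0 / (K_{app}/K_T^0 - 1)}.
#'
#' Note that published worked examples occasionally quote a competitor Kd
#' that is inconsistent with this algebra (e.g. reading "about the reporter's
#' own Kd" off a pair that actually implies a 2-3 fold weaker constant);
#' this function always reports the formula's value.
#'
#' @inheritParams apparent_kd
#' @param K_app measured apparent dissociation constant, µM (> `K_T0`).
#' @return competitor dissociation constant `K_E`, µM.
#' @examples
#' invert_apparent_kd(K_T0 = 3, K_app = 9, E0 = 15) # 7.5
#' @export
invert_apparent_kd <- function(K_T0, K_app, E0) {
  check_pos(K_T0 = K_T0, K_app = K_app, E0 = E0)
  if (K_app <= K_T0) {
    abort("`K_app` must exceed `K_T0` for a finite competitor constant",
          class = "actinfit_invalid_input")
  }
  E0 / (K_app / K_T0 - 1)
}

#' Signal of a two-independent-site system
#'
#' Two ligands bind non-overlapping sites on the same actin monomer with no
#' cooperativity; their fluorescence increments are additive. Each site's
#' occupancy comes from its own 1:1 depletion solve against the shared total
#' actin, and \eqn{F = F_0 + \Delta F_1 \theta_1 + \Delta F_2 \theta_2}, so
#' the saturation signal is exactly `F0 + dF1 + dF2`.
#'
#' @param A0 total actin, µM.
#' @param L1,K1 total concentration and dissociation constant of the
#'   site-1 ligand, µM.
#' @param L2,K2 same for the site-2 ligand.
#' @param F0 baseline signal.
#' @param dF1,dF2 per-site signal increments at full occupancy.
#' @return predicted signal, vectorised over `L1`/`L2`.
#' @examples
#' two_site_signal(A0 = 1.5, L1 = 2, K1 = 0.05, L2 = 30, K2 = 3,
#'                 F0 = 100, dF1 = 17, dF2 = 12)
#' @export
two_site_signal <- function(A0, L1, K1, L2, K2, F0, dF1, dF2) {
  check_pos(A0 = A0)
  check_num(F0 = F0, dF1 = dF1, dF2 = dF2)
  th1 <- complex_concentration(A0, L1, K1) / A0
  th2 <- complex_concentration(A0, L2, K2) / A0
  F0 + dF1 * th1 + dF2 * th2
}
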