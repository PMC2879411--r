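# Seeded filament-end elongation: rate law, capping and sequestration
# titration curves, IC50 read-out, and nucleotide-exchange kinetics.
#
# Conventions: seed/end and capper concentrations in nM (capping constants
# are nanomolar), G-actin and sequestration constants in µM, k+ in
# µM^-1 s^-1, rates in nM subunits s^-1, normalized rates in % of control.

#' Initial elongation rate of seeded filament growth
#'
#' The linear seeded-growth rate law \eqn{V = [seeds] \cdot k_+ (C - C_c)}:
#' free ends extend at a rate proportional to the free-monomer excess over
#' the critical concentration. At or below `Cc` the net rate is zero.
#'
#' @param free_actin free G-actin concentration `C`, µM.
#' @param seeds0 free filament-end concentration, nM.
#' @param kplus association rate constant, µM^-1 s^-1 (default 10, the
#'   standard value for barbed-end assembly of Mg-ATP-actin).
#' @param Cc critical concentration at the measured end, µM.
#' @return elongation rate in nM subunits s^-1, vectorised.
#' @examples
#' elongation_rate(free_actin = 2, seeds0 = 2, kplus = 10, Cc = 0.1) # 38
#' @export
elongation_rate <- function(free_actin, seeds0, kplus = 10, Cc = 0.1) {
  check_nonneg(free_actin = free_actin, seeds0 = seeds0, Cc = Cc)
  check_pos(kplus = kplus)
  seeds0 * kplus * pmax(free_actin - Cc, 0)
}

#' Seed concentration from a measured initial rate
#'
#' Exact inverse of [elongation_rate()]; used to calibrate the free-end
#' concentration of a seed preparation from growth at known G-actin.
#'
#' @param V measured initial rate, nM subunits s^-1.
#' @param C free G-actin, µM (must exceed `Cc`).
#' @param Cc critical concentration, µM.
#' @param kplus association rate constant, µM^-1 s^-1.
#' @return seed (free end) concentration, nM.
#' @examples
#' seeds_from_rate(V = 38, C = 2, Cc = 0.1, kplus = 10) # 2
#' @export
seeds_from_rate <- function(V, C, Cc = 0.1, kplus = 10) {
  check_nonneg(V = V, Cc = Cc)
  check_pos(kplus = kplus)
  check_num(C = C)
  if (any(C <= Cc)) {
    abort("free actin `C` must exceed the critical concentration `Cc`",
          class = "actinfit_invalid_input")
  }
  V / (kplus * (C - Cc))
}

#' Normalized elongation rate under barbed-end capping
#'
#' A capper binds free filament ends with dissociation constant `Kcap`;
#' only uncapped ends elongate, so the normalized rate is 100 times the
#' free-end fraction. Because working end concentrations (a few nM) are
#' comparable to nanomolar `Kcap`, the default accounts for capper
#' depletion through the 1:1 quadratic between ends and capper; the
#' free-ligand hyperbola `100/(1 + X/Kcap)` is available for legend-style
#' fits.
#'
#' @param capper total capper concentration grid, nM.
#' @param Kcap end-binding dissociation constant, nM.
#' @param ends0 free-end concentration, nM (default 2).
#' @param depletion use the end-depletion quadratic (default `TRUE`).
#' @return normalized rates in % of control, monotone non-increasing.
#' @examples
#' capping_curve(c(0, 5, 15, 50, 200), Kcap = 15, ends0 = 2)
#' @export
capping_curve <- function(capper, Kcap, ends0 = 2, depletion = TRUE) {
  check_nonneg(capper = capper, ends0 = ends0)
  check_pos(Kcap = Kcap)
  if (!depletion || ends0 == 0) {
    return(100 / (1 + capper / Kcap))
  }
  capped <- complex_concentration(ends0, capper, Kcap)
  100 * (ends0 - capped) / ends0
}

#' Normalized elongation rate under monomer sequestration
#'
#' A sequesterer removes polymerization-competent G-actin into a 1:1
#' non-polymerizable complex with constant `Kseq`. Free actin follows the
#' depletion quadratic, and the normalized rate is the free-monomer excess
#' over the critical concentration relative to control:
#' \eqn{100 (A_{free} - C_c)/(A_0 - C_c)}, clipped below at 0.
#'
#' @param sequesterer total sequesterer concentration grid, µM.
#' @param Kseq monomer-binding dissociation constant, µM.
#' @param A0 total G-actin, µM.
#' @param Cc critical concentration at the measured end, µM
#'   (defaults: 0.6 pointed, 0.1 barbed; see [elongation_rate()]).
#' @return normalized rates in % of control.
#' @examples
#' sequestration_curve(c(0, 1, 2, 4), Kseq = 2.5, A0 = 2, Cc = 0.6)
#' @export
sequestration_curve <- function(sequesterer, Kseq, A0, Cc = 0.6) {
  check_nonneg(sequesterer = sequesterer, Cc = Cc)
  check_pos(Kseq = Kseq, A0 = A0)
  if (any(A0 <= Cc)) {
    abort("total actin `A0` must exceed the critical concentration `Cc`",
          class = "actinfit_invalid_input")
  }
  bound <- complex_concentration(A0, sequesterer, Kseq)
  a_free <- A0 - bound
  pmax(100 * (a_free - Cc) / (A0 - Cc), 0)
}

#' Half-inhibition concentration of a titration curve
#'
#' Linear interpolation of the inhibitor concentration at which the
#' normalized rate crosses 50% of control.
#'
#' @param conc inhibitor concentration grid (any consistent unit).
#' @param rate normalized rates, % of control.
#' @return the interpolated IC50, in the unit of `conc`.
#' @examples
#' g <- seq(0, 200, by = 5)
#' ic50(g, capping_curve(g, Kcap = 15, ends0 = 0.01))
#' @export
ic50 <- function(conc, rate) {
  check_num(conc = conc, rate = rate)
  stopifnot(length(conc) == length(rate))
  o <- order(conc)
  conc <- conc[o]; rate <- rate[o]
  below <- which(rate <= 50)
  if (length(below) == 0 || below[1] == 1L) {
    abort("curve does not cross 50% within the grid; IC50 not defined",
          class = "actinfit_not_defined")
  }
  i <- below[1]
  x1 <- conc[i - 1]; x2 <- conc[i]
  y1 <- rate[i - 1]; y2 <- rate[i]
  x1 + (50 - y1) * (x2 - x1) / (y2 - y1)
}

#' Pseudo-first-order nucleotide exchange rate in presence of a ligand
#'
#' Monomer-binding ligands slow nucleotide exchange on G-actin. The
#' observed exchange rate is the occupancy-weighted mixture of the free and
#' bound rates: with bound fraction \eqn{f_b} from the 1:1 depletion
#' quadratic, \eqn{k_{obs} = f_b k_{bound} + (1-f_b) k_{free}}.
#'
#' @param ligand0 total ligand concentration, µM (vectorised).
#' @param A0 total G-actin, µM.
#' @param Kd ligand-actin dissociation constant, µM.
#' @param k_free exchange rate constant on free G-actin, s^-1.
#' @param k_bound exchange rate constant on the complex, s^-1 (a 5-fold
#'   inhibition corresponds to `k_bound = k_free / 5`).
#' @return observed pseudo-first-order rate constants, s^-1.
#' @examples
#' exchange_kobs(c(0, 1, 5, 50), A0 = 2, Kd = 0.3,
#'               k_free = 0.05, k_bound = 0.01)
#' @export
exchange_kobs <- function(ligand0, A0, Kd, k_free, k_bound) {
  check_pos(A0 = A0, k_free = k_free)
  check_nonneg(ligand0 = ligand0, k_bound = k_bound)
  fb <- complex_concentration(A0, ligand0, Kd) / A0
  fb * k_bound + (1 - fb) * k_free
}

#' Single-exponential nucleotide-exchange fluorescence trace
#'
#' Fluorescent-ATP incorporation follows a pseudo-first-order rise
#' \eqn{F(t) = F_\infty (1 - e^{-k_{obs} t})}.
#'
#' @param t time grid, seconds.
#' @param k_obs observed rate constant, s^-1.
#' @param amplitude plateau fluorescence `F_inf` (default 1).
#' @return signal values on `t`.
#' @examples
#' exchange_trace(seq(0, 100, by = 5), k_obs = 0.05)
#' @export
exchange_trace <- function(t, k_obs, amplitude = 1) {
  check_nonneg(t = t)
  check_pos(k_obs = k_obs)
  check_num(amplitude = amplitude)
  amplitude * (1 - exp(-k_obs * t))
}
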