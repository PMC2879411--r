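# Seeded generators for every assay class the package fits. Each generator
# draws homoscedastic Gaussian noise with standard deviation expressed as a
# fraction of the curve's dynamic range and is bit-reproducible for a given
# integer seed; replicates are drawn sequentially from one seeded stream.

#' Simulate fluorescence binding titrations
#'
#' Generates replicate 1:1 depletion-isotherm titrations of labelled
#' G-actin with a monomer-binding ligand (see [predicted_signal()]) with
#' Gaussian noise. Defaults emulate an NBD-actin titration: 1.5 µM actin,
#' a 20% fluorescence increase at saturation, 2% noise.
#'
#' @param Kd_uM ground-truth dissociation constant, µM.
#' @param A0 total labelled actin, µM.
#' @param grid ligand concentration grid, µM (strictly increasing).
#' @param F0 baseline signal; `dF` saturation increment.
#' @param dF signal change at full occupancy.
#' @param noise Gaussian noise sd as a fraction of `|dF|` (default 0.02).
#' @param n_rep number of replicate titrations.
#' @param seed integer seed; recorded as attribute `seed` of the result.
#' @return tibble with columns `replicate`, `ligand_conc_uM`, `signal`,
#'   `signal_sd`.
#' @examples
#' sim_titration(Kd_uM = 0.05, n_rep = 2, seed = 1)
#' @export
sim_titration <- function(Kd_uM, A0 = 1.5, grid = seq(0, 2, length.out = 15),
                          F0 = 100, dF = 20, noise = 0.02, n_rep = 1,
                          seed = 1L) {
  check_nonneg(noise = noise)
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing", class = "actinfit_invalid_input")
  }
  mu <- predicted_signal(A0, grid, Kd_uM, F0, dF)
  sd <- noise * abs(dF)
  out <- withr::with_seed(seed, purrr::map_dfr(seq_len(n_rep), function(r) {
    tibble(replicate = r, ligand_conc_uM = grid,
           signal = mu + rnorm(length(grid), 0, sd),
           signal_sd = sd)
  }))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "truth") <- list(Kd_uM = Kd_uM, A0 = A0, F0 = F0, dF = dF)
  out
}

#' Simulate normalized elongation-rate titrations
#'
#' Generates replicate seeded-growth titrations under a capping or a
#' sequestration mechanism (see [capping_curve()],
#' [sequestration_curve()]), with the ligand-free control at 100%,
#' Gaussian noise (sd as a fraction of the 100% dynamic range), and rates
#' clipped below at 0.
#'
#' @param mechanism `"capping"` or `"sequestration"`.
#' @param K ground-truth constant: `Kcap` in nM for capping, `Kseq` in µM
#'   for sequestration.
#' @param grid ligand grid, µM (strictly increasing, starting at 0).
#' @param A0 total G-actin, µM (sequestration; recorded for both).
#' @param Cc critical concentration, µM (sequestration; default pointed
#'   end).
#' @param ends0 free-end concentration, nM (capping).
#' @param noise Gaussian sd as a fraction of the 100% range (default
#'   0.02).
#' @inheritParams sim_titration
#' @return tibble with columns `replicate`, `ligand_conc_uM`,
#'   `norm_rate_pct`, `rate_sd`, `A0_uM`, `end`.
#' @examples
#' sim_rate_titration("capping", K = 15,
#'                    grid = seq(0, 0.15, length.out = 12), seed = 4)
#' @export
sim_rate_titration <- function(mechanism = c("capping", "sequestration"),
                               K, grid, A0 = 2, Cc = 0.6, ends0 = 2,
                               noise = 0.02, n_rep = 1, seed = 1L) {
  mechanism <- match.arg(mechanism)
  check_nonneg(noise = noise)
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing", class = "actinfit_invalid_input")
  }
  mu <- switch(mechanism,
    capping = capping_curve(grid * 1e3, Kcap = K, ends0 = ends0),
    sequestration = sequestration_curve(grid, Kseq = K, A0 = A0, Cc = Cc))
  sd <- noise * 100
  end <- if (mechanism == "capping") "barbed" else "pointed"
  out <- withr::with_seed(seed, purrr::map_dfr(seq_len(n_rep), function(r) {
    tibble(replicate = r, ligand_conc_uM = grid,
           norm_rate_pct = pmax(mu + rnorm(length(grid), 0, sd), 0),
           rate_sd = sd, A0_uM = A0, end = end)
  }))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "truth") <- list(mechanism = mechanism, K = K, A0 = A0,
                             Cc = Cc, ends0 = ends0)
  out
}

#' Simulate a matched pair of titrations at two actin concentrations
#'
#' Convenience wrapper for the mechanism-discrimination experiment: one
#' mechanism, one ground-truth constant, two total-actin concentrations,
#' a shared ligand grid.
#'
#' @inheritParams sim_rate_titration
#' @param A0_pair the two total G-actin concentrations, µM.
#' @return tibble as [sim_rate_titration()] with both `A0_uM` values.
#' @export
sim_mechanism_pair <- function(mechanism = c("capping", "sequestration"),
                               K, grid, A0_pair = c(2, 4), Cc = 0.6,
                               ends0 = 2, noise = 0.02, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(A0_pair) == 2)
  bind_rows(
    sim_rate_titration(mechanism, K, grid, A0 = A0_pair[1], Cc = Cc,
                       ends0 = ends0, noise = noise, seed = seed),
    sim_rate_titration(mechanism, K, grid, A0 = A0_pair[2], Cc = Cc,
                       ends0 = ends0, noise = noise, seed = seed + 1L))
}

#' Simulate nucleotide-exchange traces
#'
#' For each ligand concentration, computes the true observed rate from the
#' occupancy model (see [exchange_kobs()]) and generates a noisy
#' single-exponential incorporation trace.
#'
#' @param ligand_grid total ligand concentrations, µM.
#' @param A0 total G-actin, µM.
#' @param Kd ligand-actin dissociation constant, µM.
#' @param k_free,k_bound exchange rate constants on free and complexed
#'   actin, s^-1.
#' @param t time grid, seconds.
#' @param amplitude trace plateau.
#' @param noise Gaussian sd as a fraction of `amplitude`.
#' @inheritParams sim_titration
#' @return list with `traces` (tibble: `ligand_conc_uM`, `time_s`,
#'   `signal`) and `kobs` (tibble: `ligand_conc_uM`, `k_obs_true`).
#' @examples
#' sim_exchange(c(0, 2, 10), Kd = 0.3, k_free = 0.05, k_bound = 0.01,
#'              seed = 2)$kobs
#' @export
sim_exchange <- function(ligand_grid, A0 = 2, Kd, k_free, k_bound,
                         t = seq(0, 200, by = 2), amplitude = 1,
                         noise = 0.02, seed = 1L) {
  check_nonneg(noise = noise)
  kobs <- exchange_kobs(ligand_grid, A0, Kd, k_free, k_bound)
  traces <- withr::with_seed(seed, purrr::map2_dfr(
    ligand_grid, kobs, function(L, k) {
      tibble(ligand_conc_uM = L, time_s = t,
             signal = exchange_trace(t, k, amplitude) +
                      rnorm(length(t), 0, noise * abs(amplitude)))
    }))
  out <- list(traces = traces,
              kobs = tibble(ligand_conc_uM = ligand_grid, k_obs_true = kobs))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate a marker calibration series
#'
#' Marker positions generated from a latent line
#' `position = intercept + slope * known_value` plus Gaussian noise, as in
#' gradient-sedimentation or gel-filtration calibrations.
#'
#' @param known_values marker values (e.g. Svedberg coefficients).
#' @param slope,intercept latent line parameters.
#' @param noise Gaussian sd on positions (absolute units).
#' @inheritParams sim_titration
#' @return tibble with `marker`, `known_value`, `observed_position`;
#'   attribute `truth` holds the latent line.
#' @examples
#' sim_calibration(c(2.58, 4.22, 7.4, 11.4), slope = -0.8, intercept = 18)
#' @export
sim_calibration <- function(known_values, slope, intercept, noise = 0,
                            seed = 1L) {
  check_num(known_values = known_values, slope = slope, intercept = intercept)
  check_nonneg(noise = noise)
  pos <- withr::with_seed(seed,
    intercept + slope * known_values + rnorm(length(known_values), 0, noise))
  out <- tibble(marker = paste0("M", seq_along(known_values)),
                known_value = known_values,
                observed_position = pos)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "truth") <- list(slope = slope, intercept = intercept)
  out
}
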