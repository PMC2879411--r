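# Tabular I/O and reporting: CSV readers with schema validation and
# explicit unit normalisation (everything is µM internally), JSON fit
# reports, and a small named-analysis dispatcher for scripted runs.

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "actinfit_io_error")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing required column(s): %s",
                  what, path, paste(missing, collapse = ", ")),
          class = "actinfit_schema_error")
  }
  d
}

#' Read a fluorescence titration CSV
#'
#' Expected schema: `ligand_conc_uM, signal[, signal_sd]`, header
#' mandatory, UTF-8, dot decimal.
#'
#' @param path file path.
#' @return tibble ready for [fit_binding()].
#' @export
read_titration <- function(path) {
  read_checked_csv(path, c("ligand_conc_uM", "signal"), "titration")
}

#' Read a rate-titration CSV
#'
#' Expected schema:
#' `ligand_conc, ligand_unit, norm_rate_pct[, rate_sd, end, A0_uM,
#' seeds_nM]`. Ligand concentrations are converted to µM using the
#' per-row `ligand_unit` (nM or uM) and returned as `ligand_conc_uM`;
#' normalized rates are clipped to the 0-120% range.
#'
#' @param path file path.
#' @return tibble ready for [fit_kcap()], [fit_kseq()] or
#'   [discriminate_mechanism()].
#' @export
read_rate_titration <- function(path) {
  d <- read_checked_csv(path, c("ligand_conc", "ligand_unit", "norm_rate_pct"),
                        "rate titration")
  d$ligand_conc_uM <- purrr::map2_dbl(d$ligand_conc, d$ligand_unit,
                                      ~ convert_conc(.x, .y, "uM"))
  d$norm_rate_pct <- pmin(pmax(d$norm_rate_pct, 0), 120)
  dplyr::relocate(d, "ligand_conc_uM")
}

#' Read a nucleotide-exchange trace CSV
#'
#' Expected schema: `time_s, signal`.
#'
#' @param path file path.
#' @return tibble ready for [fit_exchange_trace()].
#' @export
read_exchange_trace <- function(path) {
  read_checked_csv(path, c("time_s", "signal"), "exchange trace")
}

#' Read a marker calibration CSV
#'
#' Expected schema: `marker, known_value, known_unit, observed_position`.
#'
#' @param path file path.
#' @return tibble ready for [linear_calibration()].
#' @export
read_calibration <- function(path) {
  read_checked_csv(path, c("marker", "known_value", "known_unit",
                           "observed_position"), "calibration")
}

#' Read peptide sequences from a FASTA file
#'
#' Minimal FASTA reader for short helix peptides (plain text, `>` headers,
#' unwrapped or wrapped sequence lines).
#'
#' @param path file path.
#' @return tibble with columns `id`, `sequence`.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "actinfit_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines))])
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) {
    abort("not a FASTA file (no '>' header)", class = "actinfit_schema_error")
  }
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  tibble(id = ids, sequence = unname(seqs[as.character(seq_along(ids))]))
}

#' Write a fit report as JSON
#'
#' Serialises a fitted model (parameters, standard errors, bootstrap CI,
#' RSS, convergence, seed, model name, package version) for a reproducible
#' record of a run.
#'
#' @param fit an `actinfit_fit` object.
#' @param path output path (`.json`).
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "actinfit_fit"))
  report <- list(
    model = fit$model,
    package_version = as.character(utils::packageVersion("actinfit")),
    parameters = as.list(fit$estimate),
    std_errors = as.list(fit$std_error),
    conf_int = if (is.null(fit$conf_int)) NULL else fit$conf_int,
    rss = fit$rss,
    n = fit$n,
    converged = fit$converged,
    seed = fit$seed
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run a named analysis on a data file
#'
#' Thin dispatcher binding the readers to the fitters, for scripted runs:
#' each analysis reads its input, fits, and (optionally) writes a JSON
#' report and a CSV of the fitted curve. Deterministic given the same
#' inputs and seed.
#'
#' @param command one of `"fit-binding"`, `"fit-capping"`,
#'   `"fit-sequestration"`, `"fit-exchange"`, `"discriminate"`.
#' @param input path to the input CSV (schema per the matching reader).
#' @param params named list of model options: `A0` (µM), `Cc` (µM),
#'   `ends0` (nM) as appropriate.
#' @param n_boot bootstrap resamples for the fit report.
#' @param seed integer seed.
#' @param out_dir if non-NULL, directory where `report.json` is written.
#' @return the fit or discrimination object.
#' @export
run_analysis <- function(command, input, params = list(), n_boot = 0,
                         seed = 1L, out_dir = NULL) {
  commands <- c("fit-binding", "fit-capping", "fit-sequestration",
                "fit-exchange", "discriminate")
  if (!command %in% commands) {
    abort(sprintf("unknown command '%s' (expected one of: %s)", command,
                  paste(commands, collapse = ", ")),
          class = "actinfit_invalid_input")
  }
  res <- switch(command,
    "fit-binding" = fit_binding(read_titration(input),
                                A0 = params$A0 %||% 1.5,
                                n_boot = n_boot, seed = seed),
    "fit-capping" = fit_kcap(read_rate_titration(input),
                             ends0 = params$ends0 %||% 2,
                             n_boot = n_boot, seed = seed),
    "fit-sequestration" = fit_kseq(read_rate_titration(input),
                                   A0 = params$A0 %||% 2,
                                   Cc = params$Cc %||% 0.6,
                                   n_boot = n_boot, seed = seed),
    "fit-exchange" = fit_exchange_trace(read_exchange_trace(input),
                                        n_boot = n_boot, seed = seed),
    "discriminate" = discriminate_mechanism(read_rate_titration(input),
                                            ends0 = params$ends0 %||% 2,
                                            Cc = params$Cc %||% 0.6))
  if (!is.null(out_dir) && inherits(res, "actinfit_fit")) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fit_json(res, file.path(out_dir, "report.json"))
  }
  res
}
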