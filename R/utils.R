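#' @importFrom rlang abort warn `%||%`
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise ungroup
#' @importFrom stats lm coef median quantile optimize uniroot rnorm predict setNames
#' @importFrom utils head tail
NULL

# Validate that all named arguments are finite numerics satisfying a predicate.
check_num <- function(..., finite = TRUE, .where = NULL) {
  vals <- list(...)
  for (nm in names(vals)) {
    x <- vals[[nm]]
    if (!is.numeric(x) || length(x) == 0L) {
      abort(sprintf("`%s` must be numeric%s", nm,
                    if (is.null(.where)) "" else paste0(" in ", .where)),
            class = "actinfit_invalid_input")
    }
    if (finite && !all(is.finite(x))) {
      abort(sprintf("`%s` contains non-finite values", nm),
            class = "actinfit_invalid_input")
    }
  }
  invisible(TRUE)
}

check_nonneg <- function(..., .where = NULL) {
  vals <- list(...)
  do.call(check_num, c(vals, list(.where = .where)))
  for (nm in names(vals)) {
    if (any(vals[[nm]] < 0)) {
      abort(sprintf("`%s` must be >= 0", nm), class = "actinfit_invalid_input")
    }
  }
  invisible(TRUE)
}

check_pos <- function(..., .where = NULL) {
  vals <- list(...)
  do.call(check_num, c(vals, list(.where = .where)))
  for (nm in names(vals)) {
    if (any(vals[[nm]] <= 0)) {
      abort(sprintf("`%s` must be > 0", nm), class = "actinfit_invalid_input")
    }
  }
  invisible(TRUE)
}

#' Convert a concentration between nanomolar and micromolar
#'
#' All model functions in the package work in micromolar (and seconds);
#' readers use this helper to normalise input units explicitly.
#'
#' @param x numeric vector of concentrations.
#' @param from,to `"nM"` or `"uM"` (also accepts `"µM"`).
#' @return numeric vector in the target unit.
#' @examples
#' convert_conc(1500, "nM", "uM")
#' @export
convert_conc <- function(x, from, to) {
  norm <- function(u) {
    u <- gsub("µ", "u", tolower(u))
    if (!u %in% c("nm", "um")) {
      abort(sprintf("unknown concentration unit '%s' (expected nM or uM)", u),
            class = "actinfit_unit_error")
    }
    u
  }
  from <- norm(from); to <- norm(to)
  scale <- c(nm = 1e-3, um = 1)
  x * scale[[from]] / scale[[to]]
}
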