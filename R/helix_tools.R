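# Helical-wheel projection and amphipathicity metrics for candidate
# actin-binding helices (WH2-like amphipathic helices).

# Eisenberg consensus and Kyte-Doolittle hydrophobicity scales.
.scales <- list(
  eisenberg = c(
    A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
    Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
    L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
    S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08),
  kyte_doolittle = c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
)

#' Hydrophobicity scales
#'
#' Returns a named per-residue hydrophobicity vector. The Eisenberg
#' consensus scale (default throughout the package) is zero-centred, so
#' its sign splits residues into hydrophobic (> 0) and hydrophilic (< 0);
#' the Kyte-Doolittle scale is provided as an alternative.
#'
#' @param name `"eisenberg"` or `"kyte_doolittle"`.
#' @return named numeric vector over the 20 canonical amino acids.
#' @examples
#' hydrophobicity_scale()[["L"]]
#' @export
hydrophobicity_scale <- function(name = c("eisenberg", "kyte_doolittle")) {
  .scales[[match.arg(name)]]
}

check_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0) {
    abort("peptide must be a single non-empty string", class = "actinfit_invalid_input")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(.scales$eisenberg))
  if (length(bad) > 0) {
    abort(sprintf("unknown residue letter(s): %s", paste(unique(bad), collapse = ", ")),
          class = "actinfit_invalid_input")
  }
  aa
}

#' Classify residues for helical-wheel display
#'
#' Acidic residues (D, E) are classed `negative`, basic residues (K, R, H)
#' `positive`, and the remainder `hydrophobic` or `hydrophilic` by the sign
#' of their value on the chosen hydrophobicity scale. The conventional
#' wheel glyphs are circle (hydrophilic), diamond (hydrophobic), triangle
#' (negative), pentagon (positive).
#'
#' @param aa character vector of one-letter residue codes.
#' @param scale named hydrophobicity vector (default Eisenberg consensus).
#' @return character vector of classes.
#' @examples
#' classify_residue(c("D", "L", "K", "S"))
#' @export
classify_residue <- function(aa, scale = hydrophobicity_scale()) {
  aa <- toupper(aa)
  bad <- setdiff(aa, names(scale))
  if (length(bad) > 0) {
    abort(sprintf("unknown residue letter(s): %s", paste(unique(bad), collapse = ", ")),
          class = "actinfit_invalid_input")
  }
  dplyr::case_when(
    aa %in% c("D", "E") ~ "negative",
    aa %in% c("K", "R", "H") ~ "positive",
    scale[aa] > 0 ~ "hydrophobic",
    TRUE ~ "hydrophilic"
  )
}

#' Helical-wheel layout of a peptide
#'
#' Projects an alpha-helix along its axis: residue `i` sits at angle
#' `(i - 1) * step` degrees (mod 360), counterclockwise, residue 1 at 0
#' degrees. The canonical alpha-helical step of 100 degrees per residue
#' places 18 residues on 18 distinct angles over exactly five turns.
#'
#' @param sequence one-letter peptide string.
#' @param step angular step per residue, degrees (default 100).
#' @param scale hydrophobicity scale for values and classing.
#' @return a tibble with columns `index`, `residue`, `angle_deg`, `class`,
#'   `hydrophobicity`, `glyph`.
#' @examples
#' wheel_layout("LKKLLKLLKKLLKLLKKL")
#' @export
wheel_layout <- function(sequence, step = 100, scale = hydrophobicity_scale()) {
  aa <- check_peptide(sequence)
  check_pos(step = step)
  glyphs <- c(hydrophilic = "circle", hydrophobic = "diamond",
              negative = "triangle", positive = "pentagon")
  cls <- classify_residue(aa, scale)
  tibble(
    index = seq_along(aa),
    residue = aa,
    angle_deg = ((seq_along(aa) - 1) * step) %% 360,
    class = cls,
    hydrophobicity = unname(scale[aa]),
    glyph = unname(glyphs[cls])
  )
}

#' Hydrophobic moment of a helix
#'
#' The first moment of the hydrophobicity distribution around the wheel:
#' \deqn{\mu_H = \left| \sum_i H_i (\cos\theta_i, \sin\theta_i) \right|,
#' \quad \theta_i = (i-1) \cdot step.}
#' A large moment relative to the residues' mean hydrophobicity indicates
#' an amphipathic helix — hydrophobic residues concentrated on one face.
#' The magnitude is invariant under a global rotation of all angles.
#'
#' @inheritParams wheel_layout
#' @return a list with `magnitude` (scale units), `direction_deg` (angle of
#'   the moment vector, degrees in [0, 360)), and `per_residue_mean`
#'   (magnitude divided by length).
#' @examples
#' hydrophobic_moment("LKKLLKLLKKLLKLLKKL")$magnitude
#' @export
hydrophobic_moment <- function(sequence, step = 100,
                               scale = hydrophobicity_scale()) {
  aa <- check_peptide(sequence)
  check_pos(step = step)
  h <- unname(scale[aa])
  th <- ((seq_along(aa) - 1) * step) * pi / 180
  mx <- sum(h * cos(th))
  my <- sum(h * sin(th))
  mag <- sqrt(mx^2 + my^2)
  dir <- (atan2(my, mx) * 180 / pi) %% 360
  list(magnitude = mag, direction_deg = dir,
       per_residue_mean = mag / length(aa))
}

#' Largest contiguous hydrophobic face of a wheel layout
#'
#' Orders the occupied wheel angles and finds the longest circular run of
#' positions whose residues are all classed `hydrophobic`. Ties are broken
#' by the smallest start angle. An all-hydrophobic helix yields a 360
#' degree face; a helix with no hydrophobic residue yields an empty face.
#'
#' @param layout a [wheel_layout()] tibble.
#' @return a list with `width_deg` (angular span of the face), `n_residues`,
#'   `start_angle_deg`, and `members` (tibble of the face's rows of
#'   `layout`).
#' @examples
#' hydrophobic_face(wheel_layout("LKKLLKLLKKLLKLLKKL"))$width_deg
#' @export
hydrophobic_face <- function(layout) {
  stopifnot(is.data.frame(layout),
            all(c("angle_deg", "class") %in% names(layout)))
  # group residues sharing an angle (coincident after full turns)
  ang <- layout |>
    dplyr::group_by(.data$angle_deg) |>
    dplyr::summarise(hydro = all(.data$class == "hydrophobic"),
                     .groups = "drop") |>
    dplyr::arrange(.data$angle_deg)
  m <- nrow(ang)
  if (!any(ang$hydro)) {
    return(list(width_deg = 0, n_residues = 0L, start_angle_deg = NA_real_,
                members = layout[0, ]))
  }
  if (all(ang$hydro)) {
    return(list(width_deg = 360, n_residues = nrow(layout),
                start_angle_deg = 0, members = layout))
  }
  # circular longest run of TRUE
  hydro2 <- c(ang$hydro, ang$hydro)
  best_len <- 0L; best_start <- NA_integer_
  run <- 0L
  for (i in seq_len(2 * m)) {
    run <- if (hydro2[i]) run + 1L else 0L
    run <- min(run, m)
    start <- i - run + 1L
    if (run > best_len && start <= m) {
      best_len <- run
      best_start <- start
    }
  }
  idx <- ((best_start - 1L + seq_len(best_len) - 1L) %% m) + 1L
  angles <- ang$angle_deg[idx]
  # angular span walked forward along the run (handles wrap-around)
  span <- if (best_len == 1L) 0 else {
    (ang$angle_deg[idx[best_len]] - ang$angle_deg[idx[1]]) %% 360
  }
  members <- layout[layout$angle_deg %in% angles &
                    layout$class == "hydrophobic", ]
  list(width_deg = span, n_residues = nrow(members),
       start_angle_deg = ang$angle_deg[idx[1]], members = members)
}

#' Plot a helical wheel
#'
#' Conventional wheel display: residues at their projected angles, glyph
#' shape by chemical class, fill by hydrophobicity, labels by residue and
#' position.
#'
#' @inheritParams wheel_layout
#' @return a ggplot object.
#' @export
plot_wheel <- function(sequence, step = 100, scale = hydrophobicity_scale()) {
  lay <- wheel_layout(sequence, step, scale)
  # spiral the radius slightly so coincident angles remain visible
  lay <- dplyr::mutate(lay,
    r = 1 + 0.08 * ((.data$index - 1) * step) %/% 360,
    x = .data$r * cos(.data$angle_deg * pi / 180),
    y = .data$r * sin(.data$angle_deg * pi / 180))
  ggplot2::ggplot(lay, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$class,
                                     fill = .data$hydrophobicity), size = 7) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$residue, .data$index)),
                       size = 2.6, vjust = -1.8) +
    ggplot2::scale_shape_manual(values = c(hydrophilic = 21, hydrophobic = 23,
                                           negative = 24, positive = 22)) +
    ggplot2::scale_fill_gradient2(low = "yellow", mid = "orange",
                                  high = "red", midpoint = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(shape = "class", fill = "hydrophobicity")
}
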