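# Helical-symmetry arithmetic for actin filaments and the segmenting
# geometry used when boxing filament images for averaging. Numbers only —
# no image processing.

#' Per-subunit rotation from helical twist
#'
#' F-actin's genetic (short-pitch) helix is left-handed: a twist of `t`
#' subunits per turn corresponds to a signed rotation of `-360/t` degrees
#' between symmetry neighbours. Canonical F-actin has a twist of 2.16
#' subunits per turn (rotation -166.67 degrees); ligand decoration can
#' change it (e.g. 2.14, rotation -168 degrees to the nearest degree).
#'
#' @param twist subunits per turn (> 1). Vectorised.
#' @param signed return the left-handed (negative) convention (default);
#'   `FALSE` returns the magnitude.
#' @return rotation per subunit, degrees.
#' @examples
#' rotation_from_twist(2.16)
#' round(rotation_from_twist(2.14))
#' @export
rotation_from_twist <- function(twist, signed = TRUE) {
  check_num(twist = twist)
  if (any(twist <= 1)) {
    abort("`twist` must exceed 1 subunit per turn", class = "actinfit_invalid_input")
  }
  r <- 360 / twist
  if (signed) -r else r
}

#' Helical twist from per-subunit rotation
#'
#' Inverse of [rotation_from_twist()]: `twist = -360/rotation` (the sign
#' of the rotation is ignored for the magnitude).
#'
#' @param rotation rotation per subunit, degrees (signed or magnitude).
#' @return twist in subunits per turn.
#' @examples
#' twist_from_rotation(-180)
#' @export
twist_from_rotation <- function(rotation) {
  check_num(rotation = rotation)
  if (any(rotation == 0) || any(abs(rotation) >= 360)) {
    abort("|rotation| must lie in (0, 360) degrees", class = "actinfit_invalid_input")
  }
  360 / abs(rotation)
}

#' Views contributed per asymmetric unit by an overlapping boxing scheme
#'
#' When a filament is cut into boxes of `box` pixels advanced by a stride
#' of `box - overlap` pixels, each asymmetric unit appears in
#' `box / (box - overlap)` boxes. The count is an integer whenever the
#' stride divides the box; otherwise the floor is returned with a
#' remainder flag.
#'
#' @param box box edge length, pixels.
#' @param overlap overlap between successive boxes, pixels
#'   (`0 <= overlap < box`).
#' @return a list with `views` (count), `exact` (logical: stride divides
#'   box), and `stride` (pixels).
#' @examples
#' views_per_unit(80, 60)$views # 4
#' @export
views_per_unit <- function(box, overlap) {
  check_pos(box = box)
  check_nonneg(overlap = overlap)
  if (overlap >= box) {
    abort("`overlap` must be smaller than `box`", class = "actinfit_invalid_input")
  }
  stride <- box - overlap
  ratio <- box / stride
  exact <- abs(ratio - round(ratio)) < 1e-9
  list(views = if (exact) round(ratio) else floor(ratio),
       exact = exact, stride = stride)
}

#' Number of helical subunits spanned by one box
#'
#' `box * pixel_size / rise`: how many asymmetric units of the helix fall
#' inside one segment box. With the canonical F-actin rise of 2.75 nm per
#' subunit, an 80-pixel box at 0.54 nm/pixel covers about 15.7 subunits —
#' a little over one actin crossover.
#'
#' @param box box edge length, pixels.
#' @param pixel_size nm per pixel.
#' @param rise axial rise per subunit, nm (default 2.75, canonical
#'   F-actin).
#' @return subunits per box (fractional).
#' @examples
#' subunits_per_box(80, 0.54)
#' @export
subunits_per_box <- function(box, pixel_size, rise = 2.75) {
  check_pos(box = box, pixel_size = pixel_size, rise = rise)
  box * pixel_size / rise
}

#' Helical-symmetry report
#'
#' Bundles the symmetry arithmetic into one tibble, from either a twist or
#' a signed rotation, optionally with a boxing scheme.
#'
#' @param twist subunits per turn (give exactly one of `twist`/`rotation`).
#' @param rotation signed rotation per subunit, degrees.
#' @param rise axial rise per subunit, nm.
#' @param box,overlap,pixel_size optional segmenting scheme (pixels,
#'   pixels, nm/pixel).
#' @return a one-row tibble: `twist`, `rotation_deg` (full precision),
#'   `rotation_2dp`, `rotation_nearest_deg`, `rise_nm`, and when a scheme
#'   is given `subunits_per_box`, `views_per_unit`.
#' @examples
#' symmetry_report(twist = 2.16, box = 80, overlap = 60, pixel_size = 0.54)
#' @export
symmetry_report <- function(twist = NULL, rotation = NULL, rise = 2.75,
                            box = NULL, overlap = NULL, pixel_size = NULL) {
  if (is.null(twist) == is.null(rotation)) {
    abort("supply exactly one of `twist` or `rotation`",
          class = "actinfit_invalid_input")
  }
  if (is.null(twist)) twist <- twist_from_rotation(rotation)
  rot <- rotation_from_twist(twist)
  out <- tibble(twist = twist,
                rotation_deg = rot,
                rotation_2dp = round(rot, 2),
                rotation_nearest_deg = round(rot),
                rise_nm = rise)
  if (!is.null(box) && !is.null(pixel_size)) {
    out$subunits_per_box <- subunits_per_box(box, pixel_size, rise)
    if (!is.null(overlap)) {
      out$views_per_unit <- views_per_unit(box, overlap)$views
    }
  }
  out
}
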