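#' Putamen region-of-interest box
#'
#' The posterior dorsal putamen target approximated as a rectangular box:
#' length, height and width, the width measured at two labelled levels
#' because the structure tapers. Defaults are atlas measurements of the
#' left posterior dorsal putamen (1.92 x 1.15 cm, widths 1.12 and 0.90 cm).
#'
#' @param length_cm,height_cm ROI extents, cm.
#' @param width_levels_cm Numeric vector of width measurements, cm.
#' @return An object of class `ced_roi`.
#' @export
roi_box <- function(length_cm = 1.92, height_cm = 1.15,
                    width_levels_cm = c(1.12, 0.90)) {
  stopifnot_positive(length_cm, "length_cm")
  stopifnot_positive(height_cm, "height_cm")
  if (any(width_levels_cm <= 0)) {
    abort("`width_levels_cm` must be positive.",
          class = "cedflow_invalid_parameter")
  }
  structure(
    list(length_cm = length_cm, height_cm = height_cm,
         width_levels_cm = width_levels_cm),
    class = "ced_roi"
  )
}

#' Cylindrical distribution model
#'
#' Reflux along the catheter track turns the spherical distribution into a
#' capsule: a hemisphere of radius r below the tip plus a cylinder of
#' height h (the reflux length) above it. The total distribution length is
#' r + h and the diameter 2r.
#'
#' @param radius_cm Hemisphere/cylinder radius r, cm (> 0).
#' @param reflux_length_cm Reflux length h, cm (>= 0).
#' @return An object of class `ced_cylinder` with derived `total_length_cm`
#'   and `diameter_cm`.
#' @export
cylinder_model <- function(radius_cm, reflux_length_cm) {
  stopifnot_positive(radius_cm, "radius_cm")
  stopifnot_nonnegative(reflux_length_cm, "reflux_length_cm")
  structure(
    list(radius_cm = radius_cm,
         reflux_length_cm = reflux_length_cm,
         total_length_cm = radius_cm + reflux_length_cm,
         diameter_cm = 2 * radius_cm),
    class = "ced_cylinder"
  )
}

#' @export
print.ced_cylinder <- function(x, ...) {
  cat(sprintf("<ced_cylinder> r %.3g cm | reflux %.3g cm | length %.3g cm | Vd %.3g mL\n",
              x$radius_cm, x$reflux_length_cm, x$total_length_cm,
              cylinder_vd(x)))
  invisible(x)
}

#' Sphere diameter achieving a distribution volume
#'
#' Inverts \eqn{V_d = (4/3)\pi r^3}: the diameter of the uniform sphere a
#' reflux-resistant catheter would produce for a given distribution
#' volume.
#'
#' @param vd_ml Distribution volume, mL (> 0).
#' @return Diameter in cm.
#' @examples
#' sphere_diameter_for_vd(0.5)  # ~0.98 cm
#' @export
sphere_diameter_for_vd <- function(vd_ml) {
  if (any(vd_ml <= 0)) {
    abort("`vd_ml` must be positive.", class = "cedflow_invalid_parameter")
  }
  2 * (3 * vd_ml / (4 * pi))^(1 / 3)
}

#' Volume of a cylindrical (hemisphere + cylinder) distribution
#'
#' \eqn{V_d = (2/3)\pi r^3 + \pi r^2 h}.
#'
#' @param model A [cylinder_model()].
#' @return Volume in mL.
#' @examples
#' cylinder_vd(cylinder_model(0.30, 1.60))  # ~0.5 mL
#' @export
cylinder_vd <- function(model) {
  if (!inherits(model, "ced_cylinder")) {
    abort("`model` must be a `ced_cylinder`.",
          class = "cedflow_invalid_parameter")
  }
  2 / 3 * pi * model$radius_cm^3 +
    pi * model$radius_cm^2 * model$reflux_length_cm
}

#' Solve cylinder dimensions for a target volume
#'
#' Given a target distribution volume and one fixed dimension (either the
#' diameter or the total length), returns the unique capsule geometry
#' matching both. Total length and diameter trade off inversely at fixed
#' volume.
#'
#' @param vd_ml Target volume, mL (> 0).
#' @param diameter_cm,total_length_cm Exactly one must be supplied, cm.
#' @return A [cylinder_model()] whose [cylinder_vd()] matches `vd_ml` to
#'   better than 1e-9 mL.
#' @examples
#' solve_cylinder(0.5, diameter_cm = 1.12)       # length ~0.69 cm
#' solve_cylinder(0.5, total_length_cm = 1.90)   # diameter ~0.60 cm
#' @export
solve_cylinder <- function(vd_ml, diameter_cm = NULL, total_length_cm = NULL) {
  stopifnot_positive(vd_ml, "vd_ml")
  if (is.null(diameter_cm) == is.null(total_length_cm)) {
    abort("Supply exactly one of `diameter_cm` or `total_length_cm`.",
          class = "cedflow_invalid_parameter")
  }
  if (!is.null(diameter_cm)) {
    stopifnot_positive(diameter_cm, "diameter_cm")
    r <- diameter_cm / 2
    hemi <- 2 / 3 * pi * r^3
    if (hemi > vd_ml + 1e-12) {
      abort(sprintf(
        "Infeasible geometry: hemisphere of diameter %.3g cm alone holds %.4g mL > %.4g mL.",
        diameter_cm, hemi, vd_ml
      ), class = "cedflow_infeasible_geometry")
    }
    h <- (vd_ml - hemi) / (pi * r^2)
    return(cylinder_model(r, max(h, 0)))
  }
  stopifnot_positive(total_length_cm, "total_length_cm")
  ell <- total_length_cm
  # V(r) = pi r^2 ell - (1/3) pi r^3 on r in (0, ell]; strictly increasing
  # up to r = 2*ell so the root on (0, ell] is unique.
  vol <- function(r) pi * r^2 * ell - pi * r^3 / 3
  if (vol(ell) < vd_ml - 1e-12) {
    abort(sprintf(
      "Infeasible geometry: total length %.3g cm cannot hold %.4g mL (max %.4g mL at h = 0).",
      ell, vd_ml, vol(ell)
    ), class = "cedflow_infeasible_geometry")
  }
  r <- uniroot(function(r) vol(r) - vd_ml, c(1e-12, ell),
               tol = 1e-14)$root
  cylinder_model(r, ell - r)
}

#' Check a distribution shape against the target ROI
#'
#' Compares the extents of a spherical or cylindrical distribution against
#' the ROI box, dimension by dimension: the cylinder axis is taken along
#' the ROI's long axis (catheter inclination is out of scope), the sphere
#' occupies its diameter in every dimension. Width is checked at each
#' measured level independently.
#'
#' @param shape Either a single number (sphere diameter, cm) or a
#'   [cylinder_model()].
#' @param roi A [roi_box()].
#' @return A tibble with one row per ROI dimension: `dimension`,
#'   `roi_cm`, `extent_cm`, `margin_cm`, `overflow`. Any negative margin
#'   flags overflow on that dimension.
#' @examples
#' check_roi_fit(sphere_diameter_for_vd(0.5), roi_box())
#' check_roi_fit(solve_cylinder(0.5, total_length_cm = 1.90), roi_box())
#' @export
check_roi_fit <- function(shape, roi = roi_box()) {
  if (!inherits(roi, "ced_roi")) {
    abort("`roi` must be a `ced_roi`.", class = "cedflow_invalid_parameter")
  }
  if (inherits(shape, "ced_cylinder")) {
    axial <- shape$total_length_cm
    lateral <- shape$diameter_cm
  } else if (is.numeric(shape) && length(shape) == 1L && shape >= 0) {
    axial <- lateral <- shape
  } else {
    abort("`shape` must be a sphere diameter (single number >= 0) or a `ced_cylinder`.",
          class = "cedflow_invalid_parameter")
  }
  dims <- c("length", "height",
            paste0("width_level_", seq_along(roi$width_levels_cm)))
  roi_dims <- c(roi$length_cm, roi$height_cm, roi$width_levels_cm)
  extents <- c(axial, rep(lateral, 1 + length(roi$width_levels_cm)))
  tibble(
    dimension = dims,
    roi_cm = roi_dims,
    extent_cm = extents,
    margin_cm = roi_dims - extents,
    overflow = roi_dims - extents < 0
  )
}
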