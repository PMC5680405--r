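#' Tissue transport properties
#'
#' Bulk properties of the infusion target: porosity (extracellular volume
#' fraction \eqn{\phi}), first-order elimination rate constant, and the
#' empirical ratio of distribution volume to infusion volume (Vd/Vi).
#'
#' Defaults are the putamen values used throughout: \eqn{\phi = 0.3}
#' (edema-adjusted; normal tissue is ~0.2), k = 3.72e-2 h^-1 (the
#' two-compartment k10 fitted to rat striatal GDNF data), and
#' Vd/Vi = 3.87 measured in the non-human-primate putamen.
#'
#' @param porosity Extracellular volume fraction, in (0, 1).
#' @param elimination_rate First-order elimination rate constant, h^-1.
#' @param vd_vi_ratio Empirical Vd/Vi ratio (dimensionless, > 0).
#' @return An object of class `ced_tissue`.
#' @examples
#' tissue_model()
#' @export
tissue_model <- function(porosity = 0.3,
                         elimination_rate = 3.72e-2,
                         vd_vi_ratio = 3.87) {
  if (!is.numeric(porosity) || length(porosity) != 1L ||
      porosity <= 0 || porosity >= 1) {
    abort("`porosity` must lie strictly between 0 and 1.",
          class = "cedflow_invalid_parameter")
  }
  stopifnot_nonnegative(elimination_rate, "elimination_rate")
  stopifnot_positive(vd_vi_ratio, "vd_vi_ratio")
  structure(
    list(porosity = porosity,
         elimination_rate = elimination_rate,
         vd_vi_ratio = vd_vi_ratio),
    class = "ced_tissue"
  )
}

#' @export
print.ced_tissue <- function(x, ...) {
  cat(sprintf("<ced_tissue> phi %.3g | k %.3g h^-1 | Vd/Vi %.3g\n",
              x$porosity, x$elimination_rate, x$vd_vi_ratio))
  invisible(x)
}

#' Infusion protocol
#'
#' Describes one convection-enhanced infusion: volumetric rate, infusate
#' concentration (the normalisation scale for concentration profiles),
#' total infusion volume, and the radius of the spherical source surface
#' from which transport is simulated. The source radius (default 0.2 cm)
#' is deliberately larger than the physical catheter tip radius: the
#' instantaneous exit velocity diverges as 1/r^2 and the tissue within a
#' couple of millimetres of the tip cannot be resolved by a continuum
#' porous-medium model.
#'
#' @param rate_ul_min Volumetric infusion rate Q, uL/min.
#' @param infusion_volume_ml Total infusion volume Vi, mL.
#' @param infusate_concentration Infusate concentration C0 (arbitrary
#'   units); profiles are reported normalised to it.
#' @param source_radius_cm Radius of the simulated source sphere, cm.
#' @param catheter_tip_radius_cm Physical catheter tip radius, cm
#'   (informational only).
#' @return An object of class `ced_protocol`. The infusion duration in
#'   minutes is available as `$duration_min` (= Vi/Q).
#' @examples
#' infusion_protocol(rate_ul_min = 5, infusion_volume_ml = 0.105)
#' @export
infusion_protocol <- function(rate_ul_min,
                              infusion_volume_ml,
                              infusate_concentration = 1,
                              source_radius_cm = 0.2,
                              catheter_tip_radius_cm = 0.03) {
  stopifnot_positive(rate_ul_min, "rate_ul_min")
  stopifnot_positive(infusion_volume_ml, "infusion_volume_ml")
  stopifnot_positive(infusate_concentration, "infusate_concentration")
  stopifnot_positive(source_radius_cm, "source_radius_cm")
  stopifnot_positive(catheter_tip_radius_cm, "catheter_tip_radius_cm")
  structure(
    list(rate_ul_min = rate_ul_min,
         infusion_volume_ml = infusion_volume_ml,
         infusate_concentration = infusate_concentration,
         source_radius_cm = source_radius_cm,
         catheter_tip_radius_cm = catheter_tip_radius_cm,
         duration_min = infusion_volume_ml * 1e3 / rate_ul_min),
    class = "ced_protocol"
  )
}

#' @export
print.ced_protocol <- function(x, ...) {
  cat(sprintf("<ced_protocol> Q %.3g uL/min | Vi %.3g mL | duration %.1f min | r'0 %.2f cm\n",
              x$rate_ul_min, x$infusion_volume_ml, x$duration_min,
              x$source_radius_cm))
  invisible(x)
}

#' Numerical settings for the radial transport solver
#'
#' @param dr_cm Target radial cell width, cm. The actual width is adjusted
#'   so that an integer number of cells spans the domain.
#' @param r_max_cm Outer domain radius, cm. Must comfortably exceed the
#'   advective front; the solver checks that the outermost concentration
#'   stays below `far_field_tol`.
#' @param cfl Safety factor applied to the stability-limited time step
#'   (advective CFL and diffusive limits), in (0, 1].
#' @param inner_boundary `"flux"` imposes the total solute flux Q*C0
#'   through the source sphere (mass-conserving, the default);
#'   `"fixed"` holds the source surface at the infusate concentration.
#' @param source_strength Multiplier on the source concentration scale
#'   (default 1). Exposed for calibration studies; the shipped defaults do
#'   not rescale the source.
#' @param limiter Advection face reconstruction: `"vanleer"` (second-order
#'   TVD, default) or `"upwind"` (first-order, more diffusive).
#' @param far_field_tol Maximum normalised concentration tolerated at
#'   `r_max_cm` before the domain is declared too small.
#' @return An object of class `ced_solver_settings`.
#' @export
solver_settings <- function(dr_cm = 0.0025,
                            r_max_cm = 3,
                            cfl = 0.4,
                            inner_boundary = c("flux", "fixed"),
                            source_strength = 1,
                            limiter = c("vanleer", "upwind"),
                            far_field_tol = 1e-6) {
  stopifnot_positive(dr_cm, "dr_cm")
  stopifnot_positive(r_max_cm, "r_max_cm")
  if (!is.numeric(cfl) || cfl <= 0 || cfl > 1) {
    abort("`cfl` must lie in (0, 1].", class = "cedflow_invalid_parameter")
  }
  stopifnot_positive(source_strength, "source_strength")
  structure(
    list(dr_cm = dr_cm,
         r_max_cm = r_max_cm,
         cfl = cfl,
         inner_boundary = match.arg(inner_boundary),
         source_strength = source_strength,
         limiter = match.arg(limiter),
         far_field_tol = far_field_tol),
    class = "ced_solver_settings"
  )
}
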