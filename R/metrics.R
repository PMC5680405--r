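#' Peclet number of a CED infusion
#'
#' Ratio of convective to diffusive mass transport at radial distance r
#' from the catheter: \eqn{Pe = Q / (4 \pi \phi (D/\lambda^2) r)}. Pe >> 1
#' marks convection-dominated, square-front distribution; Pe ~ 1 means
#' diffusion broadens (and homogenises less) the profile. Pe falls as 1/r,
#' so its minimum over a distribution is attained at the outermost radius
#' of interest.
#'
#' @param rate_ul_min Infusion rate Q, uL/min.
#' @param r_cm Radial distance(s), cm (> 0).
#' @param molecule A [molecule()].
#' @param tissue A [tissue_model()].
#' @return Dimensionless Peclet number (vectorised over `r_cm`).
#' @examples
#' peclet(5, 0.558, molecule_preset("r-metHuGDNF"), tissue_model())  # ~147
#' @export
peclet <- function(rate_ul_min, r_cm, molecule, tissue) {
  stopifnot_positive(rate_ul_min, "rate_ul_min")
  if (any(r_cm <= 0)) {
    abort("`r_cm` must be positive.", class = "cedflow_invalid_parameter")
  }
  ul_min_to_cm3_s(rate_ul_min) /
    (4 * pi * tissue$porosity * effective_diffusivity(molecule) * r_cm)
}

profile_slice <- function(profile, time_h) {
  times <- unique(profile$time_h)
  if (is.null(time_h)) time_h <- max(times)
  i <- which.min(abs(times - time_h))
  if (abs(times[i] - time_h) > 1e-6 + 1e-6 * abs(time_h)) {
    abort(sprintf("Profile has no stored slice at t = %g h (available: %s).",
                  time_h, paste(signif(times, 4), collapse = ", ")),
          class = "cedflow_invalid_parameter")
  }
  profile[profile$time_h == times[i], ]
}

#' Outermost threshold-crossing radius of a concentration profile
#'
#' Scans the profile from the outer edge inwards and returns the radius at
#' which the piecewise-linear interpolant of C_norm(r) crosses the
#' threshold. Scanning outside-in makes the result robust to small
#' non-monotonicity near the source, and the outermost crossing defines
#' the distribution boundary. A profile everywhere below the threshold
#' yields `NA` (a "no crossing" result, not an error).
#'
#' @param profile A `ced_profile` (or any data frame with `time_h`,
#'   `radius_cm`, `c_norm`).
#' @param threshold Normalised concentration threshold in (0, 1).
#' @param time_h Stored time to evaluate; defaults to the latest.
#' @return Crossing radius in cm, or `NA_real_` if the profile never
#'   reaches the threshold.
#' @export
crossing_radius <- function(profile, threshold, time_h = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].",
          class = "cedflow_invalid_parameter")
  }
  sl <- profile_slice(profile, time_h)
  sl <- sl[order(sl$radius_cm), ]
  r <- sl$radius_cm
  cc <- sl$c_norm
  n <- length(r)
  if (all(cc < threshold)) return(NA_real_)
  # outermost interval where the interpolant straddles the threshold
  for (i in seq(n - 1, 1)) {
    lo <- cc[i + 1] - threshold
    hi <- cc[i] - threshold
    if ((hi >= 0 && lo <= 0) || (hi <= 0 && lo >= 0)) {
      if (hi == lo) return(r[i])
      return(r[i] + (threshold - cc[i]) * (r[i + 1] - r[i]) / (cc[i + 1] - cc[i]))
    }
  }
  # threshold only met at/inside the innermost node
  r[1]
}

#' Spherical distribution volume from a radius
#'
#' Distribution volume of a uniform sphere, \eqn{V_d = (4/3)\pi r^3}. Used
#' to convert a threshold-crossing radius into the distribution volume the
#' infusion achieved.
#'
#' @param r_cm Radius, cm (>= 0). `NA` propagates to `NA`.
#' @return Volume in mL (vectorised).
#' @examples
#' vd_from_radius(0.4924)  # ~0.5 mL
#' @export
vd_from_radius <- function(r_cm) {
  if (any(r_cm < 0, na.rm = TRUE)) {
    abort("`r_cm` must be non-negative.", class = "cedflow_invalid_parameter")
  }
  4 / 3 * pi * r_cm^3
}

#' Homogeneity of a distribution profile
#'
#' Ratio of high-concentration coverage (C_norm >= 0.95) to total coverage
#' (C_norm >= 0.05), each converted to a spherical volume via the
#' outermost threshold crossing. A square, convection-dominated profile
#' has ratio near 1; a diffusion-broadened profile with no near-infusate
#' plateau has ratio near 0 (a missing 0.95 crossing counts as zero
#' high-concentration volume).
#'
#' @inheritParams crossing_radius
#' @param high,low The two thresholds (defaults 0.95 and 0.05).
#' @return A one-row tibble: `time_h`, `r_high_cm`, `r_total_cm`,
#'   `vd_high_ml`, `vd_total_ml`, `homogeneity_ratio`.
#' @export
homogeneity_ratio <- function(profile, time_h = NULL, high = 0.95,
                              low = 0.05) {
  sl <- profile_slice(profile, time_h)
  t_used <- sl$time_h[1]
  r_high <- crossing_radius(profile, high, t_used)
  r_total <- crossing_radius(profile, low, t_used)
  vd_high <- if (is.na(r_high)) 0 else vd_from_radius(r_high)
  vd_total <- if (is.na(r_total)) 0 else vd_from_radius(r_total)
  tibble(
    time_h = t_used,
    r_high_cm = r_high,
    r_total_cm = r_total,
    vd_high_ml = vd_high,
    vd_total_ml = vd_total,
    homogeneity_ratio = if (vd_total > 0) vd_high / vd_total else 0
  )
}

#' Compare tracer and drug distribution volumes
#'
#' Simulates the same infusion protocol for a drug and an imaging tracer
#' (elimination disabled: over the short observation horizon clearance is
#' assumed identical for the two impermeable species and cancels from the
#' comparison), then reports the spherical distribution volume at a
#' concentration threshold for each requested observation time after the
#' end of infusion, plus the tracer/drug volume ratio.
#'
#' @param protocol An [infusion_protocol()].
#' @param tissue A [tissue_model()].
#' @param drug,tracer [molecule()] objects.
#' @param observation_times_h Times after end of infusion, hours; 0 means
#'   immediately post-infusion.
#' @param threshold Normalised concentration threshold defining the
#'   distribution boundary (default 0.1).
#' @param settings A [solver_settings()].
#' @return A tibble with columns `time_h`, `vd_drug_ml`, `vd_tracer_ml`,
#'   `ratio`.
#' @export
compare_tracer_drug <- function(protocol, tissue, drug, tracer,
                                observation_times_h = c(0, 2),
                                threshold = 0.1,
                                settings = solver_settings()) {
  observation_times_h <- sort(unique(observation_times_h))
  no_elim <- tissue_model(porosity = tissue$porosity,
                          elimination_rate = 0,
                          vd_vi_ratio = tissue$vd_vi_ratio)

  vd_at_times <- function(mol) {
    inf <- solve_infusion(protocol, no_elim, mol, settings)
    vds <- numeric(length(observation_times_h))
    post_times <- observation_times_h[observation_times_h > 0]
    post <- NULL
    if (length(post_times)) {
      post <- solve_post_infusion(inf, duration_h = max(post_times),
                                  include_elimination = FALSE,
                                  save_times_h = post_times)
    }
    t_end <- max(inf$time_h)
    for (i in seq_along(observation_times_h)) {
      tt <- observation_times_h[i]
      r <- if (tt == 0) crossing_radius(inf, threshold, t_end)
           else crossing_radius(post, threshold, t_end + tt)
      vds[i] <- if (is.na(r)) 0 else vd_from_radius(r)
    }
    vds
  }

  vd_drug <- vd_at_times(drug)
  vd_tracer <- vd_at_times(tracer)
  tibble(
    time_h = observation_times_h,
    vd_drug_ml = vd_drug,
    vd_tracer_ml = vd_tracer,
    ratio = vd_tracer / vd_drug
  )
}
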