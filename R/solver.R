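# Spherically symmetric convection-diffusion-elimination solver.
#
# The transport equation for normalised interstitial concentration C(r, t),
#   dC/dt = (D/lambda^2) (1/r^2) d/dr (r^2 dC/dr) - v_r dC/dr - k C,
#   v_r   = Q / (4 pi phi r^2),
# is discretised by a conservative finite-volume scheme on [r'0, R_max].
# Because the interstitial flow is divergence-free, the advective solute flux
# through ANY spherical face equals Q * C_face, which the scheme uses exactly;
# face concentrations are reconstructed with a van Leer flux limiter (TVD,
# second order in smooth regions) so the convection-dominated front
# (Pe ~ 150) stays monotone. Time stepping is SSP-RK2 with a CFL-bounded
# fixed step.

make_grid <- function(r0, r_max, dr_target) {
  n <- max(8L, as.integer(round((r_max - r0) / dr_target)))
  dr <- (r_max - r0) / n
  faces <- r0 + dr * (0:n)
  centres <- (faces[-1] + faces[-(n + 1)]) / 2
  list(n = n, dr = dr, faces = faces, centres = centres)
}

# Geometry factors reused every RHS call: porosity-weighted face areas and
# cell volumes (cm^2, cm^3).
solver_geometry <- function(grid, porosity) {
  list(
    phi_area = 4 * pi * grid$faces^2 * porosity,
    phi_vol = 4 * pi / 3 * diff(grid$faces^3) * porosity
  )
}

vanleer_psi <- function(theta) (theta + abs(theta)) / (1 + abs(theta))

# Face concentrations for outward advection, faces 2..n (between cells
# i and i+1, upwind cell i). `ghost` is the value notionally just inside the
# inner boundary, used for the slope ratio of the first interior face.
advective_face_values <- function(conc, ghost, limiter) {
  n <- length(conc)
  up <- conc[-n]
  dn <- conc[-1]
  if (limiter == "upwind") return(up)
  upup <- c(ghost, conc[seq_len(n - 2)])
  denom <- dn - up
  denom_safe <- ifelse(abs(denom) < 1e-300, 1e-300, denom)
  theta <- (up - upup) / denom_safe
  up + 0.5 * vanleer_psi(theta) * denom
}

# Time derivative of cell-average concentrations. q_cm3_s == 0 selects the
# post-infusion regime (zero-flux inner boundary).
ced_rhs <- function(conc, q_cm3_s, d_eff, k_s, geom, grid, settings) {
  n <- grid$n
  dr <- grid$dr
  s <- settings$source_strength
  flux <- numeric(n + 1)

  # interior faces: advection (Q * C_face) + Fickian diffusion
  ghost <- if (q_cm3_s > 0 && settings$inner_boundary == "fixed") s else conc[1]
  cface <- advective_face_values(conc, ghost, settings$limiter)
  grad <- (conc[-1] - conc[-n]) / dr
  flux[2:n] <- q_cm3_s * cface - geom$phi_area[2:n] * d_eff * grad

  # inner boundary
  if (q_cm3_s > 0) {
    if (settings$inner_boundary == "flux") {
      # impose total solute flux Q * C0 * s through the source sphere
      flux[1] <- q_cm3_s * s
    } else {
      # fixed concentration s at the source surface
      flux[1] <- q_cm3_s * s -
        geom$phi_area[1] * d_eff * (conc[1] - s) / (dr / 2)
    }
  } # else zero-flux (post-infusion)

  # outer boundary: far-field C = 0 half-cell gradient + advective outflow
  flux[n + 1] <- q_cm3_s * conc[n] +
    geom$phi_area[n + 1] * d_eff * conc[n] / (dr / 2)

  (flux[-(n + 1)] - flux[-1]) / geom$phi_vol - k_s * conc
}

stable_dt <- function(q_cm3_s, d_eff, k_s, geom, grid, settings) {
  v_max <- if (q_cm3_s > 0) q_cm3_s / geom$phi_area[1] else 0
  rate <- v_max / grid$dr + 2 * d_eff / grid$dr^2
  dt <- if (rate > 0) settings$cfl / rate else Inf
  # accuracy (not stability) cap when the reaction term dominates
  if (k_s > 0) dt <- min(dt, 0.02 / k_s)
  dt
}

# SSP-RK2 march from t0 to t1 (seconds) with a fixed step <= dt_max.
march <- function(conc, t0, t1, dt_max, q_cm3_s, d_eff, k_s, geom, grid,
                  settings) {
  span <- t1 - t0
  if (span <= 0) return(conc)
  nst <- if (is.finite(dt_max)) max(1L, ceiling(span / dt_max)) else 1L
  h <- span / nst
  for (i in seq_len(nst)) {
    c1 <- conc + h * ced_rhs(conc, q_cm3_s, d_eff, k_s, geom, grid, settings)
    conc <- 0.5 * (conc + c1 +
                     h * ced_rhs(c1, q_cm3_s, d_eff, k_s, geom, grid, settings))
  }
  conc
}

new_ced_profile <- function(df, grid, protocol, tissue, molecule, settings) {
  out <- as_tibble(df)
  attr(out, "grid") <- grid
  attr(out, "protocol") <- protocol
  attr(out, "tissue") <- tissue
  attr(out, "molecule") <- molecule
  attr(out, "settings") <- settings
  class(out) <- c("ced_profile", class(out))
  out
}

check_far_field <- function(conc, settings) {
  if (conc[length(conc)] > settings$far_field_tol) {
    abort(sprintf(
      "Concentration at R_max = %.2f cm is %.2g (> %.1g): domain too small for this infusion.",
      settings$r_max_cm, conc[length(conc)], settings$far_field_tol
    ), class = "cedflow_domain_too_small")
  }
  invisible(TRUE)
}

#' Radial interstitial velocity during infusion
#'
#' Continuity of the divergence-free interstitial flow with the boundary
#' condition Q = 4 pi r0'^2 phi v_r at the source sphere gives
#' v_r = Q / (4 pi phi r^2) for r >= r0'.
#'
#' @param r_cm Radial distance(s) from the catheter tip, cm (>= source
#'   radius).
#' @param protocol An [infusion_protocol()].
#' @param tissue A [tissue_model()].
#' @return Velocity in cm/s (vectorised over `r_cm`).
#' @examples
#' p <- infusion_protocol(5, 0.105)
#' radial_velocity(0.2, p, tissue_model())
#' @export
radial_velocity <- function(r_cm, protocol, tissue) {
  if (any(r_cm < protocol$source_radius_cm)) {
    abort("`r_cm` must not be smaller than the source radius.",
          class = "cedflow_domain_error")
  }
  ul_min_to_cm3_s(protocol$rate_ul_min) /
    (4 * pi * tissue$porosity * r_cm^2)
}

#' Solve the infusion phase of a CED delivery
#'
#' Integrates the radial convection-diffusion-elimination equation from a
#' zero initial condition until the full infusion volume has been
#' delivered (duration Vi/Q). Concentrations are normalised to the
#' infusate concentration C0.
#'
#' Two inner-boundary modes are available (see [solver_settings()]): the
#' default `"flux"` mode imposes the total solute flux Q*C0 through the
#' source sphere and conserves mass exactly; `"fixed"` clamps the source
#' surface at the infusate concentration, a stronger source.
#'
#' @param protocol An [infusion_protocol()].
#' @param tissue A [tissue_model()]. Set `elimination_rate = 0` to disable
#'   clearance.
#' @param molecule A [molecule()].
#' @param settings A [solver_settings()].
#' @param save_times_h Times (hours from infusion start) at which to record
#'   the profile; the end of infusion is always included.
#' @return A `ced_profile`: a tibble with columns `time_h`, `radius_cm`,
#'   `c_norm`, `phase`, carrying the solver grid and inputs as attributes.
#' @examples
#' prof <- solve_infusion(
#'   infusion_protocol(5, 0.105), tissue_model(),
#'   molecule_preset("r-metHuGDNF"),
#'   solver_settings(dr_cm = 0.01, r_max_cm = 1.5)
#' )
#' crossing_radius(prof, 0.5)
#' @export
solve_infusion <- function(protocol, tissue, molecule,
                           settings = solver_settings(),
                           save_times_h = NULL) {
  stopifnot(inherits(protocol, "ced_protocol"),
            inherits(tissue, "ced_tissue"),
            inherits(molecule, "ced_molecule"),
            inherits(settings, "ced_solver_settings"))
  grid <- make_grid(protocol$source_radius_cm, settings$r_max_cm,
                    settings$dr_cm)
  geom <- solver_geometry(grid, tissue$porosity)
  q <- ul_min_to_cm3_s(protocol$rate_ul_min)
  d_eff <- effective_diffusivity(molecule)
  k_s <- per_h_to_per_s(tissue$elimination_rate)
  t_end <- protocol$duration_min * 60

  # advective mass balance estimate of the front; fail early if the domain
  # cannot contain it
  front <- (protocol$source_radius_cm^3 +
              3 * protocol$infusion_volume_ml * settings$source_strength /
              (4 * pi * tissue$porosity))^(1 / 3)
  if (front > 0.9 * settings$r_max_cm) {
    abort("Expected advective front exceeds 90% of R_max; enlarge the domain.",
          class = "cedflow_domain_too_small")
  }

  save_s <- sort(unique(c(save_times_h * 3600, t_end)))
  save_s <- save_s[save_s >= 0 & save_s <= t_end]
  dt_max <- stable_dt(q, d_eff, k_s, geom, grid, settings)

  conc <- numeric(grid$n)
  slices <- vector("list", length(save_s))
  t_now <- 0
  for (i in seq_along(save_s)) {
    conc <- march(conc, t_now, save_s[i], dt_max, q, d_eff, k_s, geom, grid,
                  settings)
    t_now <- save_s[i]
    slices[[i]] <- tibble(
      time_h = t_now / 3600,
      radius_cm = grid$centres,
      c_norm = conc,
      phase = "infusion"
    )
  }
  check_far_field(conc, settings)
  new_ced_profile(dplyr::bind_rows(slices), grid, protocol, tissue, molecule,
                  settings)
}

#' Solve the post-infusion phase
#'
#' After the pump stops the interstitial flow collapses and the deposited
#' drug spreads by diffusion alone (optionally with first-order
#' elimination). The inner boundary becomes zero-flux (no sink at the
#' catheter); the far field stays at zero.
#'
#' @param initial A `ced_profile` from [solve_infusion()]; its latest time
#'   slice is the initial condition.
#' @param tissue,molecule,settings As in [solve_infusion()]; default to the
#'   values carried by `initial`.
#' @param duration_h Length of the post-infusion phase, hours.
#' @param include_elimination Apply the tissue elimination rate constant?
#'   (Disable to mimic tracer-comparison simulations over short horizons.)
#' @param save_times_h Times (hours since end of infusion) to record; the
#'   end of the phase is always included.
#' @return A `ced_profile` whose `time_h` continues from the initial
#'   profile and whose `phase` is `"post-infusion"`.
#' @export
solve_post_infusion <- function(initial, tissue = NULL, molecule = NULL,
                                duration_h, include_elimination = TRUE,
                                settings = NULL, save_times_h = NULL) {
  stopifnot(inherits(initial, "ced_profile"))
  tissue <- tissue %||% attr(initial, "tissue")
  molecule <- molecule %||% attr(initial, "molecule")
  settings <- settings %||% attr(initial, "settings")
  grid <- attr(initial, "grid")
  geom <- solver_geometry(grid, tissue$porosity)
  stopifnot_positive(duration_h, "duration_h")

  t0_h <- max(initial$time_h)
  conc <- initial$c_norm[initial$time_h == t0_h]
  if (length(conc) != grid$n) {
    abort("Initial profile does not match its grid.",
          class = "cedflow_invalid_parameter")
  }

  d_eff <- effective_diffusivity(molecule)
  k_s <- if (include_elimination) per_h_to_per_s(tissue$elimination_rate) else 0
  dt_max <- stable_dt(0, d_eff, k_s, geom, grid, settings)

  save_s <- sort(unique(c(save_times_h * 3600, duration_h * 3600)))
  save_s <- save_s[save_s > 0 & save_s <= duration_h * 3600]
  slices <- vector("list", length(save_s))
  t_now <- 0
  for (i in seq_along(save_s)) {
    conc <- march(conc, t_now, save_s[i], dt_max, 0, d_eff, k_s, geom, grid,
                  settings)
    t_now <- save_s[i]
    slices[[i]] <- tibble(
      time_h = t0_h + t_now / 3600,
      radius_cm = grid$centres,
      c_norm = conc,
      phase = "post-infusion"
    )
  }
  check_far_field(conc, settings)
  new_ced_profile(dplyr::bind_rows(slices), grid, attr(initial, "protocol"),
                  tissue, molecule, settings)
}

#' Total solute mass carried by a profile
#'
#' Integrates phi * C * 4 pi r^2 dr over the domain for each stored time.
#' For normalised concentrations the result is in infusate-volume
#' equivalents (mL): with elimination off and the mass-conserving inner
#' boundary it equals the delivered volume Vi at the end of infusion.
#'
#' @param profile A `ced_profile`.
#' @return A tibble with columns `time_h`, `phase`, `mass_ml`.
#' @export
profile_mass <- function(profile) {
  stopifnot(inherits(profile, "ced_profile"))
  grid <- attr(profile, "grid")
  tissue <- attr(profile, "tissue")
  phi_vol <- solver_geometry(grid, tissue$porosity)$phi_vol
  profile |>
    dplyr::group_by(.data$time_h, .data$phase) |>
    dplyr::summarise(mass_ml = sum(.data$c_norm * phi_vol),
                     .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
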