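#' Configuration for synthetic striatal PK data
#'
#' Describes a simulated single-infusion striatal concentration-time study:
#' true two-compartment parameters, dose groups, sampling days, and a
#' measurement noise model. Defaults emulate the rat study the elimination
#' estimate rests on: doses of 15 and 3 ug infused by CED, whole-striatum
#' GDNF amounts measured at 3, 7, 14, 21 and 28 days post-infusion, with
#' 10% proportional (lognormal) assay error - the conventional choice for
#' ELISA-type measurements.
#'
#' @param true_params A [two_compartment_params()] holding the generating
#'   rates.
#' @param doses_ug Dose groups, ug.
#' @param sample_days Sampling times, days post-infusion.
#' @param noise_model `"proportional"` (lognormal, CV = `noise_cv`),
#'   `"additive"` (Gaussian, sd = `noise_cv` * mean amount), or `"none"`.
#' @param noise_cv Noise coefficient of variation (fraction, >= 0).
#' @param replicates Number of replicate datasets drawn per call.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `ced_pk_sim_config`.
#' @export
pk_sim_config <- function(true_params = two_compartment_params(),
                          doses_ug = c(15, 3),
                          sample_days = c(3, 7, 14, 21, 28),
                          noise_model = c("proportional", "additive", "none"),
                          noise_cv = 0.1,
                          replicates = 1,
                          seed = 1L) {
  stopifnot(inherits(true_params, "ced_pk_params"))
  if (any(doses_ug <= 0)) {
    abort("`doses_ug` must be positive.", class = "cedflow_invalid_parameter")
  }
  if (any(sample_days <= 0)) {
    abort("`sample_days` must be strictly positive.",
          class = "cedflow_invalid_parameter")
  }
  stopifnot_nonnegative(noise_cv, "noise_cv")
  structure(
    list(true_params = true_params,
         doses_ug = doses_ug,
         sample_days = sample_days,
         noise_model = match.arg(noise_model),
         noise_cv = noise_cv,
         replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "ced_pk_sim_config"
  )
}

#' Generate a synthetic striatal PK dataset
#'
#' Simulates central-compartment amounts from the two-compartment solution
#' for each dose and sampling day, then applies the configured measurement
#' noise. Draws are reproducible for a fixed seed and do not disturb the
#' caller's random-number state.
#'
#' @param config A [pk_sim_config()].
#' @return A tibble with columns `replicate`, `dose_ug`, `time_h`,
#'   `amount_ug` (observed) and `amount_true_ug` (noise-free), sorted by
#'   replicate, dose and time. Ready for [fit_two_compartment()].
#' @examples
#' generate_pk_dataset(pk_sim_config(noise_model = "none"))
#' @export
generate_pk_dataset <- function(config = pk_sim_config()) {
  stopifnot(inherits(config, "ced_pk_sim_config"))
  base <- tidyr::expand_grid(
    replicate = seq_len(config$replicates),
    dose_ug = config$doses_ug,
    time_h = sort(config$sample_days) * 24
  )
  tp <- config$true_params
  base$amount_true_ug <- two_cpt_central(tp$k10, tp$k12, tp$k21,
                                         base$time_h, base$dose_ug)

  amount <- withr::with_seed(config$seed, {
    switch(config$noise_model,
      none = base$amount_true_ug,
      proportional = {
        # lognormal multiplicative error with exact CV = noise_cv
        sdlog <- sqrt(log(1 + config$noise_cv^2))
        base$amount_true_ug *
          exp(rnorm(nrow(base), -sdlog^2 / 2, sdlog))
      },
      additive = pmax(
        base$amount_true_ug +
          rnorm(nrow(base), 0, config$noise_cv * mean(base$amount_true_ug)),
        0
      )
    )
  })
  base$amount_ug <- amount
  dplyr::relocate(base, "replicate", "dose_ug", "time_h", "amount_ug",
                  "amount_true_ug")
}

#' Generate an idealised square concentration profile
#'
#' A fixture profile: normalised concentration 1 inside `front_radius_cm`,
#' 0 outside, with a linear ramp across one grid cell at the front. Useful
#' for exercising threshold-crossing and homogeneity metrics against known
#' answers.
#'
#' @param front_radius_cm Front position, cm (inside the grid).
#' @param r_min_cm,r_max_cm,dr_cm Grid extent and spacing, cm.
#' @param porosity Porosity attached to the profile (used by
#'   [profile_mass()]).
#' @return A `ced_profile` at time 0.
#' @export
generate_square_profile <- function(front_radius_cm, r_min_cm = 0.2,
                                    r_max_cm = 1.5, dr_cm = 0.0025,
                                    porosity = 0.3) {
  stopifnot_positive(front_radius_cm, "front_radius_cm")
  grid <- make_grid(r_min_cm, r_max_cm, dr_cm)
  if (front_radius_cm <= r_min_cm || front_radius_cm >= r_max_cm - grid$dr) {
    abort("`front_radius_cm` must lie inside the grid.",
          class = "cedflow_invalid_parameter")
  }
  c_norm <- pmin(pmax((front_radius_cm - grid$centres) / grid$dr + 0.5, 0), 1)
  df <- tibble(time_h = 0, radius_cm = grid$centres, c_norm = c_norm,
               phase = "fixture")
  new_ced_profile(
    df, grid,
    protocol = NULL,
    tissue = tissue_model(porosity = porosity, elimination_rate = 0),
    molecule = NULL,
    settings = solver_settings(dr_cm = dr_cm, r_max_cm = r_max_cm)
  )
}
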