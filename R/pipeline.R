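#' Rate-comparison experiment
#'
#' Runs the full infusion simulation at several rates with a common
#' infusion volume, then summarises each end-of-infusion profile: the
#' C_norm = 0.5 crossing radius, the minimal Peclet number (evaluated at
#' that radius, the outermost relevant distance), the high-concentration
#' (C_norm >= 0.95) and total (C_norm >= 0.05) spherical distribution
#' volumes and their homogeneity ratio. Alongside, for the projected
#' per-catheter infusion volume (target Vd divided by the empirical Vd/Vi
#' ratio, rounded to the 0.01 mL a protocol would prescribe), it reports
#' the infusion duration and the closed-form volume lost to elimination
#' during the infusion.
#'
#' A rate whose solve fails is reported with `NA` metrics and the error
#' message in `note`; remaining rates still run.
#'
#' @param rates_ul_min Infusion rates to compare, uL/min.
#' @param tissue A [tissue_model()].
#' @param molecule A [molecule()].
#' @param infusion_volume_ml Simulated infusion volume Vi, mL.
#' @param target_vd_ml Projected per-catheter distribution volume, mL,
#'   used (with `tissue$vd_vi_ratio`) for the infusion-time and loss
#'   columns.
#' @param settings A [solver_settings()].
#' @param keep_profiles Return the solved profiles as well?
#' @return A list with `summary` (one row per rate: `rate_ul_min`,
#'   `r_half_cm`, `peclet_min`, `vd_high_ml`, `vd_total_ml`,
#'   `homogeneity_ratio`, `projected_vi_ml`, `infusion_time_min`,
#'   `loss_volume_ml`, `note`) and, if requested, `profiles` (a single
#'   tibble of end-of-infusion profiles tagged by rate).
#' @examples
#' \donttest{
#' res <- run_rate_comparison(
#'   rates_ul_min = c(3, 5),
#'   settings = solver_settings(dr_cm = 0.01, r_max_cm = 1.5)
#' )
#' res$summary
#' }
#' @export
run_rate_comparison <- function(rates_ul_min = c(0.1, 1, 3, 5),
                                tissue = tissue_model(),
                                molecule = molecule_preset("r-metHuGDNF"),
                                infusion_volume_ml = 0.105,
                                target_vd_ml = 0.5,
                                settings = solver_settings(),
                                keep_profiles = TRUE) {
  projected_vi <- round(target_vd_ml / tissue$vd_vi_ratio, 2)
  rows <- vector("list", length(rates_ul_min))
  profs <- vector("list", length(rates_ul_min))

  for (i in seq_along(rates_ul_min)) {
    q <- rates_ul_min[i]
    t_proj_min <- projected_vi * 1e3 / q
    loss <- loss_closed_form(q, vd_vi_ratio = tissue$vd_vi_ratio,
                             k_per_h = tissue$elimination_rate,
                             t_min = t_proj_min)
    res <- tryCatch({
      prof <- solve_infusion(
        infusion_protocol(q, infusion_volume_ml), tissue, molecule, settings
      )
      hom <- homogeneity_ratio(prof)
      r_half <- crossing_radius(prof, 0.5)
      list(prof = prof, hom = hom, r_half = r_half, note = NA_character_)
    }, error = function(e) {
      list(prof = NULL, hom = NULL, r_half = NA_real_,
           note = conditionMessage(e))
    })
    rows[[i]] <- tibble(
      rate_ul_min = q,
      r_half_cm = res$r_half,
      peclet_min = if (is.na(res$r_half)) NA_real_
                   else peclet(q, res$r_half, molecule, tissue),
      vd_high_ml = if (is.null(res$hom)) NA_real_ else res$hom$vd_high_ml,
      vd_total_ml = if (is.null(res$hom)) NA_real_ else res$hom$vd_total_ml,
      homogeneity_ratio = if (is.null(res$hom)) NA_real_
                          else res$hom$homogeneity_ratio,
      projected_vi_ml = projected_vi,
      infusion_time_min = t_proj_min,
      loss_volume_ml = loss$lost_volume_ml,
      note = res$note
    )
    if (keep_profiles && !is.null(res$prof)) {
      p <- as_tibble(res$prof)
      p$rate_ul_min <- q
      profs[[i]] <- p
    }
  }
  out <- list(summary = dplyr::bind_rows(rows))
  if (keep_profiles) out$profiles <- dplyr::bind_rows(profs)
  out
}

#' Tracer-comparison experiment
#'
#' Simulates the same infusion for the drug and an MRI-visible tracer and
#' reports their spherical distribution volumes (threshold C_norm = 0.1)
#' immediately after the infusion and at later observation times, together
#' with the tracer/drug ratio. Elimination is disabled, as its rate is the
#' same for both impermeable species and cancels over the short horizon.
#'
#' @param protocol An [infusion_protocol()]; default 5 uL/min, 0.105 mL.
#' @param tissue A [tissue_model()].
#' @param drug,tracer [molecule()] objects; defaults r-metHuGDNF and
#'   Gd-DTPA.
#' @param observation_times_h Hours after end of infusion (0 = at end).
#' @param threshold Distribution-boundary threshold on C_norm.
#' @param settings A [solver_settings()].
#' @return A tibble as returned by [compare_tracer_drug()].
#' @export
run_tracer_comparison <- function(protocol = infusion_protocol(5, 0.105),
                                  tissue = tissue_model(),
                                  drug = molecule_preset("r-metHuGDNF"),
                                  tracer = molecule_preset("Gd-DTPA"),
                                  observation_times_h = c(0, 2),
                                  threshold = 0.1,
                                  settings = solver_settings()) {
  compare_tracer_drug(protocol, tissue, drug, tracer,
                      observation_times_h = observation_times_h,
                      threshold = threshold, settings = settings)
}

# ---- configuration & serialization ----------------------------------------

#' Read a run configuration from YAML
#'
#' A configuration file bundles the molecule(s), tissue, infusion protocol
#' and solver settings for a run, with unit-bearing key names. Unknown
#' keys are rejected so silent typos cannot change a run. Molecules may be
#' given as a preset name or as explicit fields.
#'
#' @param path Path to a YAML file with (all optional) top-level keys
#'   `molecule`, `tracer`, `tissue`, `protocol`, `solver`, `seed`.
#' @return A list with elements `molecule`, `tracer` (may be `NULL`),
#'   `tissue`, `protocol`, `settings`, `seed`, plus `echo` (the raw parsed
#'   YAML, for provenance sidecars).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("molecule", "tracer", "tissue", "protocol", "solver", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(extra, collapse = ", ")),
          class = "cedflow_invalid_parameter")
  }
  parse_mol <- function(m) {
    if (is.null(m)) return(NULL)
    if (is.character(m)) return(molecule_preset(m))
    check_keys(m, c("name", "molecular_weight_da", "d_free_cm2_s",
                    "tortuosity"), "molecule")
    molecule(m$name, m$molecular_weight_da, m$d_free_cm2_s, m$tortuosity)
  }
  parse_tissue <- function(tm) {
    if (is.null(tm)) return(tissue_model())
    check_keys(tm, c("porosity", "elimination_rate_per_h", "vd_vi_ratio"),
               "tissue")
    do.call(tissue_model, setNames(
      tm, sub("elimination_rate_per_h", "elimination_rate", names(tm))
    ))
  }
  parse_protocol <- function(p) {
    if (is.null(p)) return(infusion_protocol(5, 0.105))
    check_keys(p, c("rate_ul_min", "infusion_volume_ml",
                    "infusate_concentration", "source_radius_cm",
                    "catheter_tip_radius_cm"), "protocol")
    do.call(infusion_protocol, p)
  }
  parse_solver <- function(s) {
    if (is.null(s)) return(solver_settings())
    check_keys(s, c("dr_cm", "r_max_cm", "cfl", "inner_boundary",
                    "source_strength", "limiter", "far_field_tol"), "solver")
    do.call(solver_settings, s)
  }
  list(
    molecule = parse_mol(raw$molecule) %||% molecule_preset("r-metHuGDNF"),
    tracer = parse_mol(raw$tracer),
    tissue = parse_tissue(raw$tissue),
    protocol = parse_protocol(raw$protocol),
    settings = parse_solver(raw$solver),
    seed = raw$seed %||% 1L,
    echo = raw
  )
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(sprintf("Unknown %s key(s): %s", where,
                  paste(extra, collapse = ", ")),
          class = "cedflow_invalid_parameter")
  }
  invisible(x)
}

#' Write a profile (or any result table) as deterministic CSV
#'
#' Numbers are formatted with a fixed 15-significant-digit format so
#' re-running the same configuration yields byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]])) x[[j]] <- sprintf("%.15g", x[[j]])
  }
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write metrics / fit reports / config echoes as JSON
#'
#' @param x A list or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
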