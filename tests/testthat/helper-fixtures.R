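# Shared fixtures. Expensive solver runs are cached so unit and acceptance
# tests can reuse them within one test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

gdnf <- molecule_preset("r-metHuGDNF")
gd_dtpa <- molecule_preset("Gd-DTPA")
putamen <- tissue_model()
putamen_no_elim <- tissue_model(elimination_rate = 0)

# near-zero diffusivity stand-in for pure-convection limits
convection_only <- molecule("convection-only", 30400, 1e-15, 2.2)

# coarse, fast settings for unit tests that do not probe accuracy
coarse_settings <- solver_settings(dr_cm = 0.005, r_max_cm = 1.5)

default_protocol <- function(rate_ul_min) infusion_protocol(rate_ul_min, 0.105)

# advective mass-balance front radius for Vi delivered into porosity phi
expected_front <- function(r0, vi_ml, phi) {
  (r0^3 + 3 * vi_ml / (4 * pi * phi))^(1 / 3)
}

# default-resolution end-of-infusion GDNF profiles (elimination on)
profile_gdnf <- function(rate_ul_min) {
  cached(paste0("gdnf_", rate_ul_min), {
    solve_infusion(default_protocol(rate_ul_min), putamen, gdnf,
                   solver_settings())
  })
}

tracer_comparison <- function() {
  cached("tracer_cmp", run_tracer_comparison())
}

# independent bisection-on-interpolant oracle for threshold crossings
bisect_crossing <- function(profile, threshold, time_h = NULL) {
  sl <- profile[profile$time_h == max(profile$time_h), ]
  if (!is.null(time_h)) sl <- profile[abs(profile$time_h - time_h) < 1e-9, ]
  f <- approxfun(sl$radius_cm, sl$c_norm - threshold)
  r <- sl$radius_cm
  hi <- NULL
  for (i in rev(seq_len(length(r) - 1))) {
    if (sign(f(r[i])) != sign(f(r[i + 1])) || f(r[i]) == 0) {
      hi <- c(r[i], r[i + 1]); break
    }
  }
  if (is.null(hi)) return(NA_real_)
  uniroot(f, hi, tol = 1e-12)$root
}
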