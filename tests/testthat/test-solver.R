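test_that("radial velocity satisfies continuity through every sphere", {
  prot <- default_protocol(5)
  v <- radial_velocity(0.2, prot, putamen)
  expect_equal(v, (5e-3 / 60) / (4 * pi * 0.3 * 0.04), tolerance = 1e-12)
  # inverse-square decay
  expect_equal(radial_velocity(0.4, prot, putamen), v / 4, tolerance = 1e-12)
  # Q = 4 pi r^2 phi v_r at several radii
  for (r in c(0.2, 0.4, 0.8)) {
    q <- 4 * pi * r^2 * putamen$porosity * radial_velocity(r, prot, putamen)
    expect_equal(q, 5e-3 / 60, tolerance = 1e-12)
  }
  expect_error(radial_velocity(0.1, prot, putamen),
               class = "cedflow_domain_error")
})

test_that("mass-conserving infusion accumulates exactly the delivered volume", {
  prof <- solve_infusion(default_protocol(5), putamen_no_elim, gdnf,
                         coarse_settings)
  m <- profile_mass(prof)
  expect_equal(m$mass_ml, 0.105, tolerance = 1e-3)
  # bounded, monotone front at end of infusion
  expect_true(all(prof$c_norm >= -1e-9 & prof$c_norm <= 1 + 1e-6))
  expect_true(all(diff(prof$c_norm) <= 1e-9))
})

test_that("mass balance with elimination follows dM/dt = Q - kM", {
  prof <- solve_infusion(default_protocol(5), putamen, gdnf, coarse_settings)
  m <- profile_mass(prof)$mass_ml
  k_s <- putamen$elimination_rate / 3600
  t_end <- 0.105e3 / 5 * 60                       # seconds
  q <- 5e-3 / 60                                  # cm^3/s
  expected <- q / k_s * (1 - exp(-k_s * t_end))   # mL
  expect_equal(m, expected, tolerance = 1e-2)
})

test_that("fixed-concentration mode pins the source surface at the infusate level", {
  st <- solver_settings(dr_cm = 0.005, r_max_cm = 1.5,
                        inner_boundary = "fixed")
  prof <- solve_infusion(default_protocol(5), putamen_no_elim, gdnf, st)
  expect_equal(prof$c_norm[1], 1, tolerance = 1e-3)
  # the fixed source is at least as strong as the flux source
  flux <- solve_infusion(default_protocol(5), putamen_no_elim, gdnf,
                         coarse_settings)
  expect_gte(profile_mass(prof)$mass_ml, profile_mass(flux)$mass_ml - 1e-6)
})

test_that("post-infusion decay of a uniform interior region is exponential", {
  # near-zero diffusivity: pure first-order decay everywhere
  init <- generate_square_profile(0.8, r_min_cm = 0.2, r_max_cm = 1.5,
                                  dr_cm = 0.005)
  k <- 0.05
  tis <- tissue_model(elimination_rate = k)
  post <- solve_post_infusion(init, tissue = tis, molecule = convection_only,
                              duration_h = 10, include_elimination = TRUE)
  inner <- post$c_norm[post$radius_cm < 0.5]
  expect_equal(inner, rep(exp(-k * 10), length(inner)), tolerance = 1e-4)
  # with elimination disabled nothing happens
  frozen <- solve_post_infusion(init, tissue = tis,
                                molecule = convection_only,
                                duration_h = 10, include_elimination = FALSE)
  expect_equal(frozen$c_norm[frozen$radius_cm < 0.5],
               rep(1, length(inner)), tolerance = 1e-9)
})

test_that("free diffusion of a thin shell matches the analytic kernel", {
  # initial Gaussian shell at 1 cm, far from both boundaries
  grid <- cedflow:::make_grid(0.2, 2, 0.0025)
  a <- 1; sig0 <- 0.02
  c0 <- exp(-(grid$centres - a)^2 / (2 * sig0^2))
  init <- cedflow:::new_ced_profile(
    tibble::tibble(time_h = 0, radius_cm = grid$centres, c_norm = c0,
                   phase = "fixture"),
    grid, protocol = NULL, tissue = putamen_no_elim, molecule = gdnf,
    settings = solver_settings(dr_cm = 0.0025, r_max_cm = 2)
  )
  t_h <- 0.5
  post <- solve_post_infusion(init, tissue = putamen_no_elim,
                              molecule = gdnf, duration_h = t_h,
                              include_elimination = FALSE)
  # oracle: u = r C obeys the 1-D heat equation; convolve with the image
  # kernel by quadrature
  d_eff <- effective_diffusivity(gdnf)
  tt <- t_h * 3600
  rho <- seq(0.8, 1.2, by = 2e-4)
  u0 <- rho * exp(-(rho - a)^2 / (2 * sig0^2))
  kern <- function(x) exp(-x^2 / (4 * d_eff * tt)) / sqrt(4 * pi * d_eff * tt)
  c_exact <- vapply(grid$centres, function(r) {
    sum((kern(r - rho) - kern(r + rho)) * u0) * 2e-4 / r
  }, numeric(1))
  num <- post$c_norm
  l2 <- sqrt(sum((num - c_exact)^2) / sum(c_exact^2))
  expect_lt(l2, 0.01)
})

test_that("a too-small domain is reported as such", {
  expect_error(
    solve_infusion(default_protocol(5), putamen, gdnf,
                   solver_settings(dr_cm = 0.005, r_max_cm = 0.45)),
    class = "cedflow_domain_too_small"
  )
})
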