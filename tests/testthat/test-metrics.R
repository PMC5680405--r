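test_that("Peclet number reproduces the tabulated rate/radius pairs", {
  expect_equal(peclet(0.1, 0.467, gdnf, putamen), 3.5, tolerance = 0.05 / 3.5)
  expect_equal(round(peclet(1, 0.553, gdnf, putamen)), 30)
  expect_equal(round(peclet(3, 0.558, gdnf, putamen)), 88)
  expect_lt(abs(peclet(5, 0.558, gdnf, putamen) - 147), 0.6)
  # inverse-linear in r
  pe <- peclet(5, 0.3, gdnf, putamen)
  expect_equal(peclet(5, 0.6, gdnf, putamen), pe / 2, tolerance = 1e-12)
})

test_that("crossing radius finds thresholds on ideal and simulated profiles", {
  sq <- generate_square_profile(0.45, dr_cm = 0.005)
  expect_equal(crossing_radius(sq, 0.5), 0.45, tolerance = 0.0025 / 0.45)
  # threshold 1 on a strictly sub-unity profile: no crossing
  sub <- sq
  sub$c_norm <- sub$c_norm * 0.999
  expect_true(is.na(crossing_radius(sub, 1)))
  low <- sq
  low$c_norm <- low$c_norm * 0.3
  expect_true(is.na(crossing_radius(low, 0.5)))
  expect_error(crossing_radius(sq, 0), class = "cedflow_invalid_parameter")
})

test_that("crossing radius agrees with a bisection-on-interpolant oracle", {
  prof <- profile_gdnf(5)
  for (thr in c(0.95, 0.5, 0.05)) {
    expect_equal(crossing_radius(prof, thr), bisect_crossing(prof, thr),
                 tolerance = 1e-6)
  }
})

test_that("spherical volume conversion is exact and inverts the diameter solve", {
  expect_equal(vd_from_radius(0), 0)
  expect_equal(vd_from_radius(0.4924), 0.5, tolerance = 1e-3)
  expect_equal(vd_from_radius(0.578), 0.81, tolerance = 1e-2)
  r <- c(0.1, 0.3, 0.5624)
  expect_equal(sphere_diameter_for_vd(vd_from_radius(r)) / 2, r,
               tolerance = 1e-12)
})

test_that("square profiles have unit homogeneity and consistent volume", {
  sq <- generate_square_profile(0.45, dr_cm = 0.0025)
  h <- homogeneity_ratio(sq)
  expect_equal(h$homogeneity_ratio, 1, tolerance = 0.05)
  # quadrature oracle: integral of c over the domain vs nominal sphere
  grid <- attr(sq, "grid")
  vol_int <- sum(sq$c_norm * 4 * pi * grid$centres^2 * grid$dr) +
    4 / 3 * pi * 0.2^3   # add the (fully inside) region below the grid
  expect_equal(vol_int, vd_from_radius(0.45), tolerance = 0.01)
})

test_that("homogeneity ratio vanishes without a high-concentration plateau", {
  sq <- generate_square_profile(0.45, dr_cm = 0.005)
  diffuse <- sq
  diffuse$c_norm <- 0.5 * exp(-(diffuse$radius_cm / 0.3)^2)
  h <- homogeneity_ratio(diffuse)
  expect_equal(h$vd_high_ml, 0)
  expect_equal(h$homogeneity_ratio, 0)
})

test_that("tracer-drug comparison is the identity for identical molecules", {
  cmp <- compare_tracer_drug(default_protocol(5), putamen, gdnf, gdnf,
                             observation_times_h = c(0, 1),
                             settings = coarse_settings)
  expect_equal(cmp$ratio, c(1, 1), tolerance = 1e-12)
})
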