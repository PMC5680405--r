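test_that("sphere diameter for a target volume matches the planning values", {
  expect_equal(round(sphere_diameter_for_vd(0.5), 2), 0.98)
  expect_equal(sphere_diameter_for_vd(4 * pi / 3), 2, tolerance = 1e-12)
})

test_that("cylindrical volume covers hemisphere and reflux scenarios", {
  expect_equal(cylinder_vd(cylinder_model(0.30, 1.60)), 0.509,
               tolerance = 1e-3)
  expect_equal(cylinder_vd(cylinder_model(0.56, 0.14)), 0.506,
               tolerance = 1e-2)
  # zero reflux reduces to the hemisphere
  expect_equal(cylinder_vd(cylinder_model(0.4, 0)), 2 / 3 * pi * 0.4^3,
               tolerance = 1e-12)
})

test_that("cylinder solve inverts the volume for either fixed dimension", {
  wide <- solve_cylinder(0.5, diameter_cm = 1.12)
  expect_equal(wide$total_length_cm, 0.70, tolerance = 0.015 / 0.7)
  long <- solve_cylinder(0.5, total_length_cm = 1.90)
  expect_equal(long$diameter_cm, 0.60, tolerance = 0.01 / 0.6)
  # residuals below 1e-9 mL, across a grid of feasible scenarios
  for (vd in c(0.3, 0.5, 1.0)) {
    for (d in c(0.6, 0.8)) {
      m <- solve_cylinder(vd, diameter_cm = d)
      expect_lt(abs(cylinder_vd(m) - vd), 1e-9)
    }
    for (l in c(1.2, 1.6, 2.0)) {
      m <- solve_cylinder(vd, total_length_cm = l)
      expect_lt(abs(cylinder_vd(m) - vd), 1e-9)
    }
  }
  # hemisphere limit: vd exactly the hemisphere volume gives h = 0
  r <- 0.35
  m <- solve_cylinder(2 / 3 * pi * r^3, diameter_cm = 2 * r)
  expect_equal(m$reflux_length_cm, 0, tolerance = 1e-9)
})

test_that("infeasible cylinder dimensions raise a distinct error", {
  expect_error(solve_cylinder(0.1, diameter_cm = 1.2),
               class = "cedflow_infeasible_geometry")
  expect_error(solve_cylinder(5, total_length_cm = 1.0),
               class = "cedflow_infeasible_geometry")
})

test_that("total length decreases as diameter grows at fixed volume", {
  ds <- seq(0.6, 1.2, by = 0.1)
  ls <- vapply(ds, function(d)
    solve_cylinder(0.5, diameter_cm = d)$total_length_cm, numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("ROI fit report flags overflow per dimension", {
  roi <- roi_box()
  # the 0.98 cm sphere overflows the narrow width level only
  sph <- check_roi_fit(sphere_diameter_for_vd(0.5), roi)
  expect_true(sph$overflow[sph$dimension == "width_level_2"])
  expect_false(any(sph$overflow[sph$dimension != "width_level_2"]))
  # the long-thin cylinder fits everywhere
  cyl <- check_roi_fit(cylinder_model(0.30, 1.60), roi)
  expect_false(any(cyl$overflow))
  # degenerate zero-size shape leaves margins equal to the ROI dims
  zero <- check_roi_fit(0, roi)
  expect_equal(zero$margin_cm, zero$roi_cm)
})
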