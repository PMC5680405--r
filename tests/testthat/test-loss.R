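test_that("closed-form loss reproduces the projected-volume loss table", {
  vdvi <- 3.87; k <- 3.72e-2
  expect_equal(loss_closed_form(1, vd_vi_ratio = vdvi, k_per_h = k,
                                t_min = 130)$lost_volume_ml,
               0.020, tolerance = 0.02 / 0.02 * 0.03)
  expect_equal(loss_closed_form(3, vd_vi_ratio = vdvi, k_per_h = k,
                                t_min = 130 / 3)$lost_volume_ml,
               0.007, tolerance = 0.05)
  expect_equal(loss_closed_form(5, vd_vi_ratio = vdvi, k_per_h = k,
                                t_min = 26)$lost_volume_ml,
               0.004, tolerance = 0.05)
})

test_that("loss limits behave analytically", {
  # no elimination: exactly zero loss, not NaN
  z <- loss_closed_form(5, vd_vi_ratio = 3.87, k_per_h = 0, t_min = 30)
  expect_identical(z$amount_lost, 0)
  expect_identical(loss_closed_form(5, vd_vi_ratio = 3.87, k_per_h = 0.04,
                                    t_min = 0)$amount_lost, 0)
  # small-t expansion A_loss ~ Q C0 R k t^2 / 2
  k_h <- 0.0372; q <- 2; r <- 3.87
  t_small <- 1e-3 / (k_h / 60)   # kt = 1e-3
  got <- loss_closed_form(q, vd_vi_ratio = r, k_per_h = k_h,
                          t_min = t_small)$amount_lost
  series <- q * r * (k_h / 60) * t_small^2 / 2 / 1e3
  expect_equal(got, series, tolerance = 0.01)
})

test_that("numerical ODE route agrees with the closed form across a grid", {
  for (q in c(0.5, 1, 5)) {
    for (k in c(1e-3, 3.72e-2, 0.5)) {
      for (t in c(10, 26, 130)) {
        a <- loss_closed_form(q, vd_vi_ratio = 3.87, k_per_h = k, t_min = t)
        b <- loss_numeric(q, vd_vi_ratio = 3.87, k_per_h = k, t_min = t)
        expect_equal(b$amount_lost, a$amount_lost, tolerance = 1e-8)
        expect_equal(b$amount_in_tissue, a$amount_in_tissue,
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("conservation: tissue amount plus loss equals the influx integral", {
  q <- 3; r <- 3.87; k <- 3.72e-2
  for (t in c(5, 43.33, 130)) {
    res <- loss_closed_form(q, vd_vi_ratio = r, k_per_h = k, t_min = t)
    influx_ml <- q * r * t / 1e3
    expect_equal(res$amount_in_tissue + res$amount_lost, influx_ml,
                 tolerance = 1e-10)
  }
})

test_that("loss grows with elimination and time but its fraction falls with rate", {
  ks <- c(0.01, 0.037, 0.1)
  losses <- vapply(ks, function(k)
    loss_closed_form(1, vd_vi_ratio = 3.87, k_per_h = k,
                     t_min = 130)$amount_lost, numeric(1))
  expect_true(all(diff(losses) > 0))
  ts <- c(20, 60, 130)
  losses_t <- vapply(ts, function(t)
    loss_closed_form(1, vd_vi_ratio = 3.87, k_per_h = 0.0372,
                     t_min = t)$amount_lost, numeric(1))
  expect_true(all(diff(losses_t) > 0))
  # fixed Vi = 0.13 mL: slower infusions lose a larger fraction of Vd
  fr <- vapply(c(1, 3, 5), function(q)
    loss_closed_form(q, vd_vi_ratio = 3.87, k_per_h = 0.0372,
                     t_min = 130 / q)$fraction_of_vd, numeric(1))
  expect_true(all(diff(fr) < 0))
  # the high-rate infusions lose about 1% of Vd
  expect_lt(fr[3], 0.015)
  expect_gt(fr[2], 0.005)
})
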