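test_that("two-compartment solution matches an independent ODE integration", {
  p <- two_compartment_params(initial_amount = 15)
  times <- c(0, 24, 72, 168, 400, 672)
  closed <- simulate_two_compartment(p, times)
  rhs <- function(t, y, parms) {
    list(c(-(p$k10 + p$k12) * y[1] + p$k21 * y[2],
           p$k12 * y[1] - p$k21 * y[2]))
  }
  ode <- deSolve::ode(y = c(a1 = 15, a2 = 0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-12, atol = 1e-14)
  expect_equal(closed$amount_central, unname(ode[, "a1"]), tolerance = 1e-8)
  expect_equal(closed$amount_peripheral, unname(ode[, "a2"]), tolerance = 1e-8)
})

test_that("two-compartment solution respects limits and conservation", {
  # one-compartment limit: k12 = k21 = 0 gives a pure exponential
  p1 <- two_compartment_params(k10 = 0.05, k12 = 0, k21 = 0,
                               initial_amount = 10)
  out <- simulate_two_compartment(p1, c(0, 10, 50))
  expect_equal(out$amount_central, 10 * exp(-0.05 * c(0, 10, 50)),
               tolerance = 1e-12)
  # mass accounting sums to the dose at all times
  p <- two_compartment_params()
  out <- simulate_two_compartment(p, seq(0, 700, by = 50))
  expect_equal(out$amount_central + out$amount_peripheral +
                 out$amount_eliminated,
               rep(p$initial_amount, nrow(out)), tolerance = 1e-12)
  expect_equal(out$amount_central[1], p$initial_amount)
})

test_that("dominant elimination rate returns k10 and warns when k12 is large", {
  expect_identical(dominant_elimination_rate(two_compartment_params()),
                   3.72e-2)
  expect_warning(
    dominant_elimination_rate(
      two_compartment_params(k10 = 0.03, k12 = 0.03, k21 = 0.01)
    ),
    "k12/k10"
  )
  expect_silent(
    dominant_elimination_rate(
      two_compartment_params(k10 = 0.03, k12 = 0, k21 = 0.01)
    )
  )
})

test_that("half-life inverts first-order rates", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(3.40e-2), 20.4, tolerance = 1e-2)
  expect_equal(half_life(3.72e-2) * 3.72e-2, log(2), tolerance = 1e-12)
  expect_error(half_life(0), class = "cedflow_invalid_parameter")
})

test_that("ISF bulk-flow clearance arithmetic and its invariances hold", {
  base <- isf_flux_elimination(isf_flow_model(0.17, 1.8, 0.3))
  expect_equal(base$q_isf_ul_min, 0.306)
  expect_equal(base$v_isf_ul, 540)
  expect_equal(base$k_per_h, 0.034, tolerance = 1e-12)
  # brain mass cancels; rate scales with outflow and inversely with porosity
  doubled <- isf_flux_elimination(isf_flow_model(0.17, 3.6, 0.3))
  expect_equal(doubled$k_per_h, base$k_per_h, tolerance = 1e-12)
  expect_equal(
    isf_flux_elimination(isf_flow_model(0.34, 1.8, 0.3))$k_per_h,
    2 * base$k_per_h, tolerance = 1e-12
  )
  expect_equal(
    isf_flux_elimination(isf_flow_model(0.17, 1.8, 0.15))$k_per_h,
    2 * base$k_per_h, tolerance = 1e-12
  )
})

test_that("noise-free generate-then-fit round trip recovers the rates", {
  d <- generate_pk_dataset(pk_sim_config(noise_model = "none"))
  fit <- fit_two_compartment(d)
  est <- tidy(fit)$estimate
  truth <- c(3.72e-2, 7.12e-4, 3.81e-3)
  expect_true(fit$converged)
  expect_lt(max(abs(est - truth) / truth), 1e-4)
})

test_that("fit degrades gracefully on nested and deficient data", {
  # mono-exponential data drive k12 towards zero
  p1 <- two_compartment_params(k10 = 0.0372, k12 = 0, k21 = 0.004,
                               initial_amount = 15)
  d <- tibble::tibble(
    time_h = c(72, 168, 336, 504, 672),
    dose_ug = 15,
    amount_ug = simulate_two_compartment(p1, c(72, 168, 336, 504, 672))$amount_central
  )
  fit <- fit_two_compartment(d)
  expect_lt(tidy(fit)$estimate[2], 1e-5)
  # fewer than 4 distinct times is under-determined
  expect_error(fit_two_compartment(d[1:3, ]),
               class = "cedflow_underdetermined")
})

test_that("fit reports and serialisation round-trip", {
  d <- generate_pk_dataset(pk_sim_config(noise_cv = 0.1, seed = 11))
  fit <- fit_two_compartment(d, n_starts = 3)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_gt(gl$half_life_h, 0)
  rep <- pk_fit_report(fit)
  expect_named(rep$estimates, c("k10", "k12", "k21"))
  # CSV round trip through the deterministic writer
  path <- withr::local_tempfile(fileext = ".csv")
  write_result_csv(d[, c("time_h", "amount_ug", "dose_ug")], path)
  back <- read_pk_dataset(path)
  expect_equal(back$amount_ug, d$amount_ug, tolerance = 1e-12)
})
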