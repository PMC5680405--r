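#' Two-compartment disposition parameters
#'
#' Micro rate constants for a linear two-compartment model in which the
#' brain extracellular space is the central compartment: elimination k10
#' from central, exchange k12 (central to peripheral) and k21 (peripheral
#' to central). Defaults are the estimates fitted to rat striatal GDNF
#' concentration-time data.
#'
#' @param k10,k12,k21 Rate constants, h^-1 (all >= 0).
#' @param initial_amount Amount in the central compartment at t = 0 (ug).
#' @param standard_errors Optional named numeric vector of standard errors
#'   for k10, k12, k21 (h^-1).
#' @return An object of class `ced_pk_params`.
#' @examples
#' two_compartment_params()
#' @export
two_compartment_params <- function(k10 = 3.72e-2,
                                   k12 = 7.12e-4,
                                   k21 = 3.81e-3,
                                   initial_amount = 15,
                                   standard_errors = NULL) {
  stopifnot_nonnegative(k10, "k10")
  stopifnot_nonnegative(k12, "k12")
  stopifnot_nonnegative(k21, "k21")
  stopifnot_positive(initial_amount, "initial_amount")
  structure(
    list(k10 = k10, k12 = k12, k21 = k21,
         initial_amount = initial_amount,
         standard_errors = standard_errors),
    class = "ced_pk_params"
  )
}

#' @export
print.ced_pk_params <- function(x, ...) {
  cat(sprintf("<ced_pk_params> k10 %.4g | k12 %.4g | k21 %.4g h^-1 | A0 %.3g ug\n",
              x$k10, x$k12, x$k21, x$initial_amount))
  invisible(x)
}

# Hybrid macro constants alpha >= beta for the biexponential solution.
two_cpt_eigenrates <- function(k10, k12, k21) {
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  c(alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

# Vectorised central-compartment amounts; the fast path used by the fitter
# and the data generator (no tibble construction).
two_cpt_central <- function(k10, k12, k21, times_h, doses) {
  ab <- two_cpt_eigenrates(k10, k12, k21)
  alpha <- ab[["alpha"]]; beta <- ab[["beta"]]
  if (alpha - beta < 1e-12 * max(alpha, 1e-300)) {
    return(doses * exp(-alpha * times_h) * (1 + (k21 - alpha) * times_h))
  }
  doses * ((k21 - alpha) * exp(-alpha * times_h) -
             (k21 - beta) * exp(-beta * times_h)) / (beta - alpha)
}

#' Simulate the two-compartment model
#'
#' Analytic biexponential solution of the bolus-input two-compartment
#' system dA1/dt = -(k10 + k12) A1 + k21 A2, dA2/dt = k12 A1 - k21 A2 with
#' A1(0) = A0, A2(0) = 0. Amounts in central and peripheral compartments
#' and the cumulative amount eliminated are returned; the three always sum
#' to A0.
#'
#' @param params A [two_compartment_params()].
#' @param times_h Numeric vector of times, hours (>= 0).
#' @param dose Initial central amount; defaults to `params$initial_amount`.
#' @return A tibble with columns `time_h`, `amount_central`,
#'   `amount_peripheral`, `amount_eliminated`.
#' @examples
#' simulate_two_compartment(two_compartment_params(), times_h = c(0, 72, 168))
#' @export
simulate_two_compartment <- function(params, times_h, dose = NULL) {
  if (!inherits(params, "ced_pk_params")) {
    abort("`params` must be a `ced_pk_params`.",
          class = "cedflow_invalid_parameter")
  }
  if (any(times_h < 0)) {
    abort("`times_h` must be non-negative.",
          class = "cedflow_invalid_parameter")
  }
  a0 <- if (is.null(dose)) params$initial_amount else dose
  k10 <- params$k10; k12 <- params$k12; k21 <- params$k21
  ab <- two_cpt_eigenrates(k10, k12, k21)
  alpha <- ab[["alpha"]]; beta <- ab[["beta"]]
  if (alpha - beta < 1e-12 * max(alpha, 1e-300)) {
    # Degenerate repeated-root case (only reachable for contrived inputs):
    # A1 = A0 e^{-alpha t} (1 + (k21 - alpha) t)
    a1 <- a0 * exp(-alpha * times_h) * (1 + (k21 - alpha) * times_h)
    a2 <- a0 * k12 * times_h * exp(-alpha * times_h)
  } else {
    a1 <- a0 * ((k21 - alpha) * exp(-alpha * times_h) -
                  (k21 - beta) * exp(-beta * times_h)) / (beta - alpha)
    a2 <- a0 * k12 * (exp(-alpha * times_h) - exp(-beta * times_h)) /
      (beta - alpha)
  }
  tibble(
    time_h = as.numeric(times_h),
    amount_central = a1,
    amount_peripheral = a2,
    amount_eliminated = a0 - a1 - a2
  )
}

#' Dominant elimination rate
#'
#' When peripheral exchange is slow relative to elimination
#' (k12 << k10), the terminal disposition of the central compartment is
#' governed by k10 alone and the overall elimination rate constant can be
#' taken as k10. A warning is emitted when k12/k10 > 0.1, i.e. when that
#' approximation is questionable.
#'
#' @param params A [two_compartment_params()].
#' @return k10 in h^-1.
#' @export
dominant_elimination_rate <- function(params) {
  if (!inherits(params, "ced_pk_params")) {
    abort("`params` must be a `ced_pk_params`.",
          class = "cedflow_invalid_parameter")
  }
  if (params$k10 > 0 && params$k12 / params$k10 > 0.1) {
    warn(sprintf(
      "k12/k10 = %.2f > 0.1: the single-rate approximation k_el ~ k10 is poor.",
      params$k12 / params$k10
    ))
  }
  params$k10
}

#' Half-life of first-order decay
#'
#' @param k Rate constant (any reciprocal-time unit).
#' @return ln(2)/k, in the reciprocal of `k`'s unit.
#' @examples
#' half_life(3.72e-2)  # ~18.6 h
#' @export
half_life <- function(k) {
  stopifnot_positive(k, "k")
  log(2) / k
}

#' ISF bulk-flow clearance model
#'
#' The slow bulk outflow of brain interstitial fluid (ISF) is the proposed
#' clearance route for macromolecules that neither bind nor cross the
#' blood-brain barrier. With an outflow of `outflow_per_gram` uL per gram
#' of brain per minute and brain density taken as 1 g/mL, the flow rate is
#' Q_ISF = outflow_per_gram * brain_mass and the ISF volume is
#' V_ISF = porosity * brain volume, giving a first-order clearance rate
#' k = Q_ISF / V_ISF. Note the brain mass cancels: k depends only on the
#' per-gram outflow and the porosity.
#'
#' @param outflow_per_gram ISF outflow, uL/(g min). Default 0.17.
#' @param brain_mass_g Brain mass, g. Default 1.8 (rat).
#' @param porosity Extracellular volume fraction, in (0, 1). Default 0.3.
#' @return For `isf_flow_model`, an object of class `ced_isf_model`; for
#'   `isf_flux_elimination`, a one-row tibble with `q_isf_ul_min`,
#'   `v_isf_ul` and `k_per_h`.
#' @examples
#' isf_flux_elimination(isf_flow_model())
#' @export
isf_flow_model <- function(outflow_per_gram = 0.17,
                           brain_mass_g = 1.8,
                           porosity = 0.3) {
  stopifnot_positive(outflow_per_gram, "outflow_per_gram")
  stopifnot_positive(brain_mass_g, "brain_mass_g")
  if (porosity <= 0 || porosity >= 1) {
    abort("`porosity` must lie strictly between 0 and 1.",
          class = "cedflow_invalid_parameter")
  }
  structure(
    list(outflow_per_gram = outflow_per_gram,
         brain_mass_g = brain_mass_g,
         porosity = porosity),
    class = "ced_isf_model"
  )
}

#' @rdname isf_flow_model
#' @param model A `ced_isf_model`.
#' @export
isf_flux_elimination <- function(model = isf_flow_model()) {
  if (!inherits(model, "ced_isf_model")) {
    abort("`model` must be a `ced_isf_model`.",
          class = "cedflow_invalid_parameter")
  }
  q_isf <- model$outflow_per_gram * model$brain_mass_g        # uL/min
  v_isf <- model$porosity * model$brain_mass_g * 1e3          # uL (1 g = 1 mL)
  k_per_h <- q_isf / v_isf * MINUTES_PER_HOUR                 # h^-1
  tibble(q_isf_ul_min = q_isf, v_isf_ul = v_isf, k_per_h = k_per_h)
}

# ---- fitting ---------------------------------------------------------------

check_pk_dataset <- function(data) {
  needed <- c("time_h", "amount_ug", "dose_ug")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("PK dataset is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cedflow_invalid_parameter")
  }
  if (any(data$time_h <= 0)) {
    abort("PK observation times must be strictly positive.",
          class = "cedflow_invalid_parameter")
  }
  if (any(data$amount_ug < 0)) {
    abort("PK amounts must be non-negative.",
          class = "cedflow_invalid_parameter")
  }
  invisible(data)
}

two_cpt_log_residuals <- function(logk, data) {
  k <- exp(logk)
  pred <- two_cpt_central(k[1], k[2], k[3], data$time_h, data$dose_ug)
  log(pmax(pred, 1e-300)) - log(pmax(data$amount_ug, 1e-300))
}

#' Fit the two-compartment model to concentration-time data
#'
#' Weighted least squares on log-transformed amounts (a proportional-error
#' assumption, the standard surrogate when the original error model is
#' unknown), with the three rate constants shared across dose groups and
#' each record's initial amount fixed to its dose. Optimisation is
#' log-parameterised (rates stay positive) Levenberg-Marquardt with
#' multi-start: `n_starts` starting points log-spaced around the initial
#' guess guard against local minima. Asymptotic standard errors come from
#' the Gauss-Newton approximation sigma^2 (J'J)^-1 at the optimum,
#' delta-transformed back to the natural scale.
#'
#' @param data A data frame with columns `time_h`, `amount_ug`, `dose_ug`
#'   (at least 4 distinct time points).
#' @param initial_guess A [two_compartment_params()] used as the centre of
#'   the multi-start; defaults to a generic guess derived from the data's
#'   overall decline.
#' @param n_starts Number of multi-start points (>= 1).
#' @return An object of class `ced_pk_fit`: a list with elements `params`
#'   (a `ced_pk_params` carrying standard errors), `converged`,
#'   `objective` (residual sum of squares on the log scale), `n_obs`,
#'   `sigma`, `data` and `fitted`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' d <- generate_pk_dataset(pk_sim_config(noise_model = "none"))
#' fit <- fit_two_compartment(d)
#' tidy(fit)
#' @export
fit_two_compartment <- function(data, initial_guess = NULL, n_starts = 5) {
  data <- check_pk_dataset(as_tibble(data))
  n_times <- length(unique(data$time_h))
  if (n_times < 4) {
    abort("At least 4 distinct time points are required to fit 3 rate constants.",
          class = "cedflow_underdetermined")
  }
  if (is.null(initial_guess)) {
    # crude mono-exponential slope as a seed for k10
    slope <- -stats::coef(stats::lm(log(pmax(amount_ug, 1e-12)) ~ time_h,
                                    data = data))[["time_h"]]
    k0 <- max(slope, 1e-4)
    initial_guess <- two_compartment_params(k10 = k0, k12 = k0 / 50,
                                            k21 = k0 / 10,
                                            initial_amount = max(data$dose_ug))
  }
  centre <- log(c(initial_guess$k10, initial_guess$k12, initial_guess$k21))
  # deterministic log-spaced multi-start lattice around the centre
  offsets <- seq(-1.5, 1.5, length.out = max(n_starts, 1))
  starts <- lapply(offsets, function(o) centre + o * c(1, -1, 1) * 0.8)
  starts[[1]] <- centre

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = two_cpt_log_residuals, data = data,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-15, ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    abort("Two-compartment fit failed to converge from any start.",
          class = "cedflow_nonconvergence")
  }

  logk <- best$par
  k <- exp(logk)
  n <- nrow(data)
  rss <- best$deviance
  sigma2 <- rss / max(n - 3, 1)
  # finite-difference Jacobian of log-residuals wrt log-params
  jac <- vapply(1:3, function(j) {
    h <- 1e-6
    ej <- replace(numeric(3), j, h)
    (two_cpt_log_residuals(logk + ej, data) -
        two_cpt_log_residuals(logk - ej, data)) / (2 * h)
  }, numeric(n))
  jtj <- crossprod(jac)
  cov_log <- tryCatch(sigma2 * solve(jtj), error = function(e) {
    matrix(NA_real_, 3, 3)
  })
  se_log <- sqrt(pmax(diag(cov_log), 0))
  se <- k * se_log  # delta method for k = exp(log k)

  params <- two_compartment_params(
    k10 = k[1], k12 = k[2], k21 = k[3],
    initial_amount = max(data$dose_ug),
    standard_errors = setNames(se, c("k10", "k12", "k21"))
  )
  fitted <- two_cpt_central(k[1], k[2], k[3], data$time_h, data$dose_ug)

  structure(
    list(params = params,
         converged = best$info %in% 1:4,
         objective = rss,
         sigma = sqrt(sigma2),
         n_obs = n,
         data = data,
         fitted = fitted),
    class = "ced_pk_fit"
  )
}

#' @export
print.ced_pk_fit <- function(x, ...) {
  cat("<ced_pk_fit> two-compartment fit (log least squares)\n")
  print(tidy(x))
  cat(sprintf("converged: %s | RSS(log) %.4g | n %d\n",
              x$converged, x$objective, x$n_obs))
  invisible(x)
}

#' @method tidy ced_pk_fit
#' @export
tidy.ced_pk_fit <- function(x, ...) {
  se <- x$params$standard_errors
  tibble(
    term = c("k10", "k12", "k21"),
    estimate = c(x$params$k10, x$params$k12, x$params$k21),
    std.error = if (is.null(se)) rep(NA_real_, 3) else unname(se)
  )
}

#' @method glance ced_pk_fit
#' @export
glance.ced_pk_fit <- function(x, ...) {
  tibble(
    sigma = x$sigma,
    objective = x$objective,
    n_obs = x$n_obs,
    converged = x$converged,
    half_life_h = half_life(x$params$k10)
  )
}

#' Read a PK dataset from CSV
#'
#' Expects (at least) the columns `time_h`, `amount_ug`, `dose_ug` and
#' validates them.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_pk_dataset <- function(path) {
  check_pk_dataset(as_tibble(utils::read.csv(path)))
}

#' Serialisable report for a two-compartment fit
#'
#' Collects estimates, standard errors, the objective and convergence into
#' a plain list, ready for [write_metrics_json()].
#'
#' @param fit A `ced_pk_fit`.
#' @return A named list.
#' @export
pk_fit_report <- function(fit) {
  stopifnot(inherits(fit, "ced_pk_fit"))
  est <- tidy(fit)
  list(
    estimates = setNames(as.list(est$estimate), est$term),
    standard_errors = setNames(as.list(est$std.error), est$term),
    objective_log_rss = fit$objective,
    sigma = fit$sigma,
    n_obs = fit$n_obs,
    converged = fit$converged,
    half_life_h = half_life(fit$params$k10)
  )
}

#' @method autoplot ced_pk_fit
#' @export
autoplot.ced_pk_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  grid <- tidyr::expand_grid(
    dose_ug = unique(d$dose_ug),
    time_h = seq(min(d$time_h) * 0.5, max(d$time_h), length.out = 100)
  )
  grid$amount_ug <- vapply(seq_len(nrow(grid)), function(i) {
    simulate_two_compartment(object$params, grid$time_h[i],
                             dose = grid$dose_ug[i])$amount_central
  }, numeric(1))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$amount_ug,
                                  colour = factor(.data$dose_ug))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "Amount in striatum (ug)",
                  colour = "Dose (ug)",
                  title = "Two-compartment fit") +
    ggplot2::theme_minimal()
}
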