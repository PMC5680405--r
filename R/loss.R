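# Drug amount cleared during the infusion phase, under the lumped
# approximation: tissue concentration stays at the infusate level C0, Vd
# grows proportionally to Vi at constant rate Q, diffusion and binding are
# neglected. The mass balance
#   dA/dt      = -k A + Q C0 (Vd/Vi),    A(0) = 0
#   dA_Loss/dt =  k A,                   A_Loss(0) = 0
# has the closed-form solution
#   A_Loss(t) = Q C0 (Vd/Vi) (t - (1 - e^{-kt}) / k).

loss_result <- function(q_ul_min, c0, ratio, a_ul, a_loss_ul, t_min) {
  vd_ml <- ratio * q_ul_min * t_min / 1e3
  tibble(
    amount_in_tissue = a_ul * c0 / 1e3,          # dose units: C0 * mL
    amount_lost = a_loss_ul * c0 / 1e3,
    lost_volume_ml = a_loss_ul / 1e3,            # A_Loss / C0, mL
    fraction_of_vd = if (vd_ml > 0) (a_loss_ul / 1e3) / vd_ml else 0
  )
}

#' Closed-form drug loss during infusion
#'
#' Evaluates the analytic solution of the lumped infusion-loss mass
#' balance. At k = 0 the exact limit (zero loss) is returned rather than
#' the indeterminate 0/0 form.
#'
#' @param rate_ul_min Infusion rate Q, uL/min.
#' @param c0 Infusate concentration (arbitrary units; default 1 so amounts
#'   are in infusate-volume equivalents).
#' @param vd_vi_ratio Empirical Vd/Vi ratio.
#' @param k_per_h First-order elimination rate constant, h^-1 (>= 0).
#' @param t_min Elapsed infusion time, minutes (>= 0).
#' @return A one-row tibble: `amount_in_tissue` and `amount_lost`
#'   (C0 * mL), `lost_volume_ml` (the infusate-volume equivalent
#'   A_Loss/C0), and `fraction_of_vd` (lost volume over the Vd delivered
#'   by time t).
#' @examples
#' loss_closed_form(1, vd_vi_ratio = 3.87, k_per_h = 3.72e-2, t_min = 130)
#' @export
loss_closed_form <- function(rate_ul_min, c0 = 1, vd_vi_ratio,
                             k_per_h, t_min) {
  stopifnot_positive(rate_ul_min, "rate_ul_min")
  stopifnot_positive(c0, "c0")
  stopifnot_positive(vd_vi_ratio, "vd_vi_ratio")
  stopifnot_nonnegative(k_per_h, "k_per_h")
  stopifnot_nonnegative(t_min, "t_min")
  k <- k_per_h / MINUTES_PER_HOUR                 # min^-1
  influx <- rate_ul_min * vd_vi_ratio             # uL(C0)/min
  if (k == 0 || t_min == 0) {
    a <- influx * t_min
    a_loss <- 0
  } else {
    a <- influx * (1 - exp(-k * t_min)) / k
    a_loss <- influx * (t_min - (1 - exp(-k * t_min)) / k)
  }
  loss_result(rate_ul_min, c0, vd_vi_ratio, a, a_loss, t_min)
}

#' Numerical drug loss during infusion
#'
#' Integrates the infusion-loss ODE pair with a stiff solver and reports
#' the same quantities as [loss_closed_form()]; the two agree to high
#' relative accuracy and the numerical route serves as a cross-check of
#' the closed form.
#'
#' @inheritParams loss_closed_form
#' @return As [loss_closed_form()].
#' @export
loss_numeric <- function(rate_ul_min, c0 = 1, vd_vi_ratio, k_per_h, t_min) {
  stopifnot_positive(rate_ul_min, "rate_ul_min")
  stopifnot_positive(c0, "c0")
  stopifnot_positive(vd_vi_ratio, "vd_vi_ratio")
  stopifnot_nonnegative(k_per_h, "k_per_h")
  stopifnot_nonnegative(t_min, "t_min")
  if (t_min == 0) {
    return(loss_result(rate_ul_min, c0, vd_vi_ratio, 0, 0, 0))
  }
  k <- k_per_h / MINUTES_PER_HOUR
  influx <- rate_ul_min * vd_vi_ratio
  rhs <- function(t, y, parms) {
    list(c(-k * y[1] + influx, k * y[1]))
  }
  sol <- deSolve::ode(y = c(a = 0, a_loss = 0), times = c(0, t_min),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE integration of the loss balance failed.",
          class = "cedflow_numerical_error")
  }
  loss_result(rate_ul_min, c0, vd_vi_ratio,
              unname(sol[nrow(sol), "a"]), unname(sol[nrow(sol), "a_loss"]),
              t_min)
}
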