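# Internal unit system is cgs (cm, s, mL == cm^3). Public constructors accept
# the units practitioners use (uL/min, h^-1, Da) and convert once here.

# 1 uL/min in cm^3/s
UL_MIN_TO_CM3_S <- 1e-3 / 60

# 1 h^-1 in s^-1
PER_H_TO_PER_S <- 1 / 3600

SECONDS_PER_HOUR <- 3600
MINUTES_PER_HOUR <- 60

ul_min_to_cm3_s <- function(q) q * UL_MIN_TO_CM3_S

per_h_to_per_s <- function(k) k * PER_H_TO_PER_S

stopifnot_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", what),
          class = "cedflow_invalid_parameter")
  }
  invisible(x)
}

stopifnot_nonnegative <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative finite number.", what),
          class = "cedflow_invalid_parameter")
  }
  invisible(x)
}
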