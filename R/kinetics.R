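#' I_h steady-state activation
#'
#' Logistic activation curve `1 / (1 + exp(-(V - Vl_half)/kl))`. With the
#' physiological `kl < 0` the curve decreases monotonically with voltage
#' (the channel opens on hyperpolarization) and equals exactly 0.5 at
#' `Vl_half`.
#'
#' @param V membrane voltage, mV (finite; vectorized)
#' @param p an [ih_params()] object
#' @return activation fraction in (0, 1)
#' @export
ih_steady_state <- function(V, p) {
  stopifnot(inherits(p, "ih_params"))
  if (!all(is.finite(V))) stop("V must be finite")
  1 / (1 + exp(.clamp_exp(-(V - p$Vl_half) / p$kl)))
}

#' I_h activation time constant
#'
#' `tau_l(V) = beta(V) / (qt * a0t * (1 + alpha(V)))` with
#' `alpha = exp(c * zetat * (V - Vt_half))`,
#' `beta = exp(c * zetat * gmt * (V - Vt_half))` and
#' `qt = q10^((temperature - T_ref)/10)`. Exponents are clamped at |x| = 50
#' so extreme voltages cannot overflow. At `V = Vt_half` the closed form
#' reduces to `1 / (2 * qt * a0t)`.
#'
#' @param V membrane voltage, mV (vectorized)
#' @param p an [ih_params()] object
#' @param temperature simulation temperature, degrees C
#' @return time constant, ms (strictly positive)
#' @export
ih_time_constant <- function(V, p, temperature = 34) {
  stopifnot(inherits(p, "ih_params"))
  if (!all(is.finite(V))) stop("V must be finite")
  qt <- p$q10^((temperature - p$T_ref) / 10)
  x <- V - p$Vt_half
  alpha <- exp(.clamp_exp(p$c_per_mV * p$zetat * x))
  beta <- exp(.clamp_exp(p$c_per_mV * p$zetat * p$gmt * x))
  beta / (qt * p$a0t * (1 + alpha))
}

.clamp_exp <- function(x) pmin(50, pmax(-50, x))

.qt <- function(p, temperature) p$q10^((temperature - p$T_ref) / 10)
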