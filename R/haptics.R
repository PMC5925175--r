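## Haptic force-feedback modelling. Measured cutting forces oscillate around
## a downtrending value rather than decaying monotonously, so the computed
## internal force is modulated by a decaying oscillation
## Gamma(t, d) = exp(-a t) sin(b t) * Upsilon(d) with a linear depth factor
## Upsilon(d) = k d. An empirical double-Gaussian fit of a porcine-liver
## cutting-force/displacement curve is included for comparison, plus RMSE.

#' Oscillation parameters for the feedback model
#'
#' @param a envelope decay rate (1/s), >= 0.
#' @param b angular frequency (rad/s), > 0.
#' @param k slope of the linear depth factor `Upsilon(d) = k d` (force/mm).
#' @return Object of class `oscillation_params`.
#' @export
oscillation_params <- function(a = 1, b = 2 * pi, k = 1) {
  if (!is_number(a) || a < 0) stopf("a must be >= 0")
  if (!is_number(b) || b <= 0) stopf("b must be > 0")
  if (!is_number(k) || k < 0) stopf("k must be >= 0")
  structure(list(a = a, b = b, k = k), class = "oscillation_params")
}

#' Oscillating force modulation
#'
#' `Gamma(t, d) = exp(-a t) sin(b t) * k d`; the magnitude is bounded by the
#' envelope `exp(-a t) k d` and vanishes at `t = 0`.
#'
#' @param t time(s) since the cut started (s), >= 0.
#' @param d cutting depth (mm), >= 0.
#' @param p an [oscillation_params].
#' @return Modulation value(s).
#' @export
oscillation <- function(t, d, p = oscillation_params()) {
  if (any(t < 0)) stopf("t must be >= 0")
  if (any(d < 0)) stopf("d must be >= 0")
  exp(-p$a * t) * sin(p$b * t) * (p$k * d)
}

#' Modulated feedback force
#'
#' Scales the accumulated internal force of a point (the Eq.-13-style total
#' including its pair terms) by the oscillation value; `Gamma = 1` returns
#' the unmodulated force, `Gamma = 0` no feedback.
#'
#' @param force force vector (or n x 3 matrix of forces).
#' @param gamma modulation value from [oscillation].
#' @return Scaled force(s).
#' @export
feedback_force <- function(force, gamma) force * gamma

#' Double-Gaussian cutting-force fit coefficients
#'
#' Defaults are the published fit of a porcine-liver blade-insertion force
#' versus displacement curve.
#'
#' @param a1,b1,c1,a2,b2,c2 Gaussian amplitudes (N), centres (mm) and widths
#'   (mm); widths must be positive.
#' @return Object of class `force_fit_coeffs`.
#' @export
force_fit_coeffs <- function(a1 = 15.29, b1 = 3.164, c1 = 0.2933,
                             a2 = 27.69, b2 = 3.288, c2 = 1.746) {
  if (c1 <= 0 || c2 <= 0) stopf("Gaussian widths c1, c2 must be > 0")
  structure(list(a1 = a1, b1 = b1, c1 = c1, a2 = a2, b2 = b2, c2 = c2),
            class = "force_fit_coeffs")
}

#' Empirical cutting force at a displacement
#'
#' `f(x) = a1 exp(-((x - b1)/c1)^2) + a2 exp(-((x - b2)/c2)^2)`.
#'
#' @param x blade displacement(s) (mm).
#' @param coeffs a [force_fit_coeffs].
#' @return Force value(s) (N).
#' @export
empirical_force <- function(x, coeffs = force_fit_coeffs()) {
  coeffs$a1 * exp(-((x - coeffs$b1) / coeffs$c1)^2) +
    coeffs$a2 * exp(-((x - coeffs$b2) / coeffs$c2)^2)
}

#' Root-mean-square error between two force series
#'
#' @param f,f_star equal-length numeric series.
#' @return `sqrt(mean((f - f_star)^2))`.
#' @export
rmse <- function(f, f_star) {
  if (length(f) != length(f_star) || length(f) < 1L)
    stopf("series must have equal length >= 1")
  sqrt(mean((f - f_star)^2))
}
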