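#' Bernstein basis function
#'
#' `B(i, n, t) = C(n, i) t^i (1 - t)^(n - i)`; the basis is a partition of
#' unity on `[0, 1]`.
#'
#' @param i basis index, `0 <= i <= n`.
#' @param n degree.
#' @param t parameter(s) in `[0, 1]` (vectorized).
#' @return Numeric vector of basis values.
#' @export
bernstein <- function(i, n, t) {
  if (!is_count(i) || !is_count(n) || i < 0L || i > n)
    stopf("require 0 <= i <= n")
  if (any(t < 0 | t > 1)) stopf("t must lie in [0, 1]")
  choose(n, i) * t^i * (1 - t)^(n - i)
}

#' Quadratic Bezier curve point
#'
#' `P(t) = (P2 - 2 P1 + P0) t^2 + 2 (P1 - P0) t + P0`, i.e. the Bernstein
#' combination of the three control points. Endpoints are interpolated:
#' `P(0) = P0`, `P(1) = P2`.
#'
#' @param p0,p1,p2 3D control points.
#' @param t parameter(s) in `[0, 1]`.
#' @return A `length(t)` x 3 matrix of curve points (a vector if one `t`).
#' @export
bezier_quadratic <- function(p0, p1, p2, t) {
  if (any(t < 0 | t > 1)) stopf("t must lie in [0, 1]")
  p0 <- as.numeric(p0); p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  out <- outer(t^2, p2 - 2 * p1 + p0) + outer(2 * t, p1 - p0) +
    matrix(p0, length(t), 3L, byrow = TRUE)
  if (length(t) == 1L) drop(out) else out
}
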