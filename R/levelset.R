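## Virtual scalpel and level-set bookkeeping. The scalpel is a tip point P,
## a handle point P' and a vertical direction; the blade plane contains P and
## P' and is perpendicular to the tissue surface. Two signed-distance level
## sets classify point elements: phi (blade plane) separates the "+" and "-"
## sides, psi (vertical plane at cut depth) separates affected from
## unaffected points. Rigid scalpel motion advances the level sets exactly by
## recomputing the signed distances from the new pose.

#' Virtual scalpel pose
#'
#' @param tip blade tip position P (mm).
#' @param handle handle point P' (mm); must differ from the tip.
#' @param vertical unit "up" direction; must not be parallel to the scalpel
#'   axis. Default +z.
#' @return An object of class `scalpel`.
#' @export
scalpel <- function(tip, handle, vertical = c(0, 0, 1)) {
  tip <- as.numeric(tip); handle <- as.numeric(handle)
  vertical <- as.numeric(vertical)
  if (length(tip) != 3L || length(handle) != 3L || length(vertical) != 3L)
    stopf("tip, handle and vertical must be 3-vectors")
  axis <- handle - tip
  if (norm3(axis) < 1e-12)
    stopf("degenerate scalpel: tip equals handle", class = "tissuecut_invalid_scalpel")
  vertical <- normalize3(vertical)
  if (norm3(cross3(axis, vertical)) < 1e-12 * norm3(axis))
    stopf("degenerate scalpel: vertical parallel to axis",
          class = "tissuecut_invalid_scalpel")
  structure(list(tip = tip, handle = handle, vertical = vertical),
            class = "scalpel")
}

#' Cut planes from a scalpel pose
#'
#' The blade plane contains the tip and handle with unit normal
#' `normalize((P' - P) x v)`; the vertical plane passes through the lowest
#' cut point (tip shifted by `cut_depth` along `-v`) with normal `-v`.
#' Dense point samples of both planes are attached (`path_points`,
#' `vertical_points`) for the sample-based signed-distance evaluation.
#'
#' @param s a [scalpel].
#' @param cut_depth cutting depth below the tip (mm), >= 0.
#' @param sample_n samples per plane axis for the attached sample grids.
#' @return An object of class `cut_planes`.
#' @export
planes_from_scalpel <- function(s, cut_depth, sample_n = 11L) {
  stopifnot(inherits(s, "scalpel"))
  if (!is_number(cut_depth) || cut_depth < 0) stopf("cut_depth must be >= 0")
  axis <- s$handle - s$tip
  blade_normal <- normalize3(cross3(axis, s$vertical))
  vertical_point <- s$tip - cut_depth * s$vertical
  half <- max(norm3(axis), cut_depth, 1)
  u1 <- normalize3(axis)
  ## in-plane bases: blade plane contains the axis and the vertical; the
  ## vertical plane is spanned by the horizontal axis component and its
  ## in-plane perpendicular
  e1 <- normalize3(axis - sum(axis * s$vertical) * s$vertical)
  e2 <- cross3(s$vertical, e1)
  path_points <- plane_samples(s$tip, u1, s$vertical, half, sample_n)
  vertical_points <- plane_samples(vertical_point, e1, e2, half, sample_n)
  structure(list(blade_point = s$tip, blade_normal = blade_normal,
                 vertical_point = vertical_point, vertical_normal = -s$vertical,
                 axis = axis, depth = cut_depth,
                 path_points = path_points, vertical_points = vertical_points),
            class = "cut_planes")
}

## Regular (2n+1)^2 sample grid on the plane through `p` spanned by u, v.
plane_samples <- function(p, u, v, half, n = 11L) {
  g <- seq(-half, half, length.out = n)
  gr <- expand.grid(a = g, b = g)
  t(apply(gr, 1L, function(r) p + r[[1L]] * u + r[[2L]] * v))
}

## Analytic signed point-plane distance (the dense-sample limit of
## signed_distance); used by classify for exactness and speed.
plane_signed_distance <- function(x, point, normal) {
  x <- as_mat3(x)
  drop(sweep(x, 2L, as.numeric(point)) %*% as.numeric(normal))
}

#' Sample-based signed distance to a level-set interface
#'
#' `+/- min_i ||X - X_i||` over the interface samples, the sign taken from
#' the side of the nearest sample along `side_normal`. For a densely sampled
#' plane this converges to the analytic point-plane signed distance.
#'
#' @param x query point(s), 3-vector or n x 3 matrix.
#' @param samples m x 3 matrix of interface sample points (non-empty).
#' @param side_normal unit vector defining the positive side.
#' @return Numeric vector of signed distances (mm).
#' @export
signed_distance <- function(x, samples, side_normal) {
  samples <- as_mat3(samples, "samples")
  if (nrow(samples) == 0L) stopf("empty interface sample set")
  x <- as_mat3(x)
  side_normal <- as.numeric(side_normal)
  vapply(seq_len(nrow(x)), function(i) {
    d <- sweep(samples, 2L, x[i, ], `-`)
    r2 <- rowSums(d * d)
    j <- which.min(r2)
    s <- sum((x[i, ] - samples[j, ]) * side_normal)
    sign(s) * sqrt(r2[j])
  }, numeric(1L))
}

#' Classify point elements against the cut planes
#'
#' Points at height `psi <= 0` relative to the vertical plane (measured along
#' the up direction) are unaffected and skipped by the solver. Above it, the
#' blade-plane sign splits points into `affected_plus` (`phi >= 0`; points
#' exactly on the blade go to "+") and `affected_minus` (`phi < 0`).
#'
#' @param points a [point_element_set] (classified at current positions).
#' @param planes a [planes_from_scalpel] result.
#' @return An object of class `region_labels`: per-point `label`, `phi`
#'   (signed blade distance, mm) and `psi` (height above the vertical plane,
#'   mm).
#' @export
classify <- function(points, planes) {
  x <- current_positions(points)
  phi <- plane_signed_distance(x, planes$blade_point, planes$blade_normal)
  psi <- plane_signed_distance(x, planes$vertical_point, -planes$vertical_normal)
  label <- ifelse(psi <= 0, "unaffected",
                  ifelse(phi >= 0, "affected_plus", "affected_minus"))
  structure(list(label = label, phi = phi, psi = psi), class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  print(table(factor(x$label, levels = c("unaffected", "affected_plus",
                                         "affected_minus"))))
  invisible(x)
}

#' Advance the level sets to a new scalpel pose
#'
#' For a rigidly moving plane, recomputing signed distances from the new pose
#' solves the level-set advection equation exactly, so this simply rebuilds
#' the planes.
#'
#' @param planes current `cut_planes` (unused except for the sample density).
#' @param new_scalpel the new [scalpel] pose.
#' @param cut_depth cutting depth (mm).
#' @return Updated `cut_planes`.
#' @export
advance <- function(planes, new_scalpel, cut_depth = planes$depth) {
  planes_from_scalpel(new_scalpel, cut_depth)
}

#' Export region labels as a data frame
#'
#' @param labels a [classify] result.
#' @return data.frame with columns index, label, phi, psi.
#' @export
labels_as_df <- function(labels) {
  data.frame(index = seq_along(labels$label), label = labels$label,
             phi = labels$phi, psi = labels$psi)
}
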