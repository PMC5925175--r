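## Mesh-meshless coupling: virtual points are interpolated on the incision
## boundary polylines, carry prescribed displacements derived from the local
## separation of the two Bezier curves, and enter the meshless solve as
## Dirichlet-style boundary neighbors. They are constraints, not matter:
## never rendered, never integrated, excluded from momentum bookkeeping.

#' Generate virtual points on the incision boundary
#'
#' For every edge of each sampled incision polyline, `per_edge` points are
#' placed at uniform interpolation weights `lambda = i / (per_edge + 1)`.
#' Each point records its parent edge (sample indices), side (`"plus"` for
#' the left curve, `"minus"` for the right) and curve parameter.
#'
#' @param mesh the `surface_mesh` the incision was built on (kept for
#'   interface symmetry; the polylines define the boundary).
#' @param curves an [build_incision] result, or NULL for no incision.
#' @param per_edge virtual points per boundary edge, >= 1.
#' @return An object of class `virtual_point_set` (0 rows when there is no
#'   incision).
#' @export
generate_virtual_points <- function(mesh, curves, per_edge = 1L) {
  if (is.null(curves) || length(curves$path_vertex_set) < 2L) {
    return(structure(list(side = character(), edge_a = integer(),
                          edge_b = integer(), lambda = numeric(),
                          t = numeric(), rest = matrix(0, 0L, 3L),
                          displacement = matrix(0, 0L, 3L)),
                     class = "virtual_point_set"))
  }
  if (per_edge < 1L) stopf("per_edge must be >= 1")
  lam <- seq_len(per_edge) / (per_edge + 1L)
  one_side <- function(poly, side) {
    ns <- nrow(poly)
    out <- list()
    for (e in seq_len(ns - 1L)) {
      for (l in lam) {
        out[[length(out) + 1L]] <- list(
          side = side, edge_a = e, edge_b = e + 1L, lambda = l,
          t = (1 - l) * curves$t[e] + l * curves$t[e + 1L],
          rest = (1 - l) * poly[e, ] + l * poly[e + 1L, ])
      }
    }
    out
  }
  rows <- c(one_side(curves$left_polyline, "plus"),
            one_side(curves$right_polyline, "minus"))
  structure(list(side = vapply(rows, `[[`, character(1L), "side"),
                 edge_a = vapply(rows, `[[`, integer(1L), "edge_a"),
                 edge_b = vapply(rows, `[[`, integer(1L), "edge_b"),
                 lambda = vapply(rows, `[[`, numeric(1L), "lambda"),
                 t = vapply(rows, `[[`, numeric(1L), "t"),
                 rest = do.call(rbind, lapply(rows, `[[`, "rest")),
                 displacement = matrix(0, length(rows), 3L)),
            class = "virtual_point_set")
}

#' @export
print.virtual_point_set <- function(x, ...) {
  cat(sprintf("virtual_point_set: %d points (%d plus, %d minus)\n",
              length(x$side), sum(x$side == "plus"), sum(x$side == "minus")))
  invisible(x)
}

n_virtual <- function(vp) length(vp$side)

## Unit opening direction: perpendicular to the chord within the patch
## plane, pointing to the positive (plus / left-curve) side.
opening_normal <- function(curves) {
  normalize3(cross3(curves$normal, curves$B - curves$A))
}

#' Prescribe virtual-point displacements from the incision opening
#'
#' At curve parameter `t` the half-separation of the two polylines is
#' `s(t) = ||left(t) - right(t)|| / 2`; plus-side points are displaced by
#' `+opening_scale * s(t)` along the opening normal, minus-side points by the
#' exact opposite, so displacements cancel pairwise at matched parameters.
#' Degenerate (chordal) curves give zero displacements everywhere.
#'
#' @param vp a [generate_virtual_points] result.
#' @param curves the matching [build_incision] result.
#' @param opening_scale dimensionless opening factor, default 1.
#' @return `vp` with the `displacement` rows filled in.
#' @export
prescribe_displacements <- function(vp, curves, opening_scale = 1) {
  if (n_virtual(vp) == 0L) return(vp)
  nb <- opening_normal(curves)
  left <- bezier_quadratic(curves$A, curves$C, curves$B, vp$t)
  right <- bezier_quadratic(curves$A, curves$D, curves$B, vp$t)
  if (n_virtual(vp) == 1L) { left <- matrix(left, 1L); right <- matrix(right, 1L) }
  s <- row_norms(left - right) / 2
  sgn <- ifelse(vp$side == "plus", 1, -1)
  vp$displacement <- (opening_scale * s * sgn) %o% nb
  vp
}

#' Merge real and virtual points into one solver cloud
#'
#' Virtual points are appended after the real points with label `"virtual"`,
#' their prescribed displacements and zero velocity; neighborhoods for
#' [coupled_step] are built on this cloud.
#'
#' @param points the real [point_element_set].
#' @param vp a [virtual_point_set].
#' @return A `point_element_set` of length `n_real + n_virtual`.
#' @export
coupling_cloud <- function(points, vp) {
  nv <- n_virtual(vp)
  if (nv == 0L) return(points)
  mv <- mean(points$masses); vv <- mean(points$volumes)
  point_element_set(rbind(points$positions, vp$rest),
                    masses = c(points$masses, rep(mv, nv)),
                    volumes = c(points$volumes, rep(vv, nv)),
                    displacements = rbind(points$displacements, vp$displacement),
                    velocities = rbind(points$velocities, matrix(0, nv, 3L)),
                    labels = c(points$labels, rep("virtual", nv)))
}

#' Side signs of a coupled cloud
#'
#' +1 for cutting-affected "+" points and plus-side virtual points, -1 for
#' the "-" side, 0 for unaffected points (the intact base of the wound).
#'
#' @param points real [point_element_set] with labels applied.
#' @param vp a [virtual_point_set].
#' @return Integer vector over the [coupling_cloud] ordering.
#' @export
cloud_sides <- function(points, vp) {
  real <- ifelse(points$labels == "affected_plus", 1L,
                 ifelse(points$labels == "affected_minus", -1L, 0L))
  c(real, ifelse(vp$side == "plus", 1L, -1L))
}

#' Sever neighbor pairs across the cut
#'
#' The blade separates the "+" and "-" regions, so point elements on opposite
#' sides of the cut must stop seeing each other as neighbors; pairs involving
#' an unaffected point (side 0) are kept, which leaves the two flaps hinged
#' at the intact tissue below the cut depth. Moment matrices of the affected
#' points are rebuilt from the retained neighbors.
#'
#' @param nb a [build_neighborhoods] result.
#' @param sides per-point side signs from [cloud_sides].
#' @return The pruned `neighborhoods` object.
#' @export
sever_cut_pairs <- function(nb, sides) {
  if (length(sides) != length(nb$idx)) stopf("sides length must match the cloud")
  for (i in seq_along(nb$idx)) {
    if (sides[i] == 0L) next
    keep <- sides[nb$idx[[i]]] * sides[i] >= 0L
    if (all(keep)) next
    nb$idx[[i]] <- nb$idx[[i]][keep]
    nb$d[[i]] <- nb$d[[i]][keep, , drop = FALSE]
    nb$w[[i]] <- nb$w[[i]][keep]
    if (length(nb$idx[[i]]) < 4L) {
      nb$rigid[i] <- TRUE
      nb$Minv[[i]] <- matrix(0, 3L, 3L)
      next
    }
    M <- crossprod(nb$d[[i]] * sqrt(nb$w[[i]]))
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (ev[3L] <= 0 || ev[1L] / ev[3L] > 1e8) {
      M <- M + diag(1e-9 * sum(diag(M)) / 3, 3L)
      nb$singular[i] <- TRUE
    }
    nb$Minv[[i]] <- solve(M)
  }
  nb
}

#' One coupled solver step
#'
#' Virtual points act as ordinary neighbors with displacements held at their
#' prescribed values; internal forces are evaluated for the cutting-affected
#' real points only, which are then integrated. Unaffected points keep their
#' state bit-identically.
#'
#' @param points real [point_element_set] (its `labels` select the affected
#'   set; see [apply_labels]).
#' @param vp a [virtual_point_set] with prescribed displacements.
#' @param nb neighborhoods built on [coupling_cloud] of `points` and `vp`.
#' @param params a [material_params].
#' @return List: updated `points`, the force matrix of the full cloud
#'   (`forces`), and the `gradient_evals` work counter.
#' @export
coupled_step <- function(points, vp, nb, params) {
  nr <- n_points(points)
  cloud <- coupling_cloud(points, vp)
  if (n_virtual(vp) > 0L) {
    iso <- which(vapply(seq(nr + 1L, nr + n_virtual(vp)),
                        function(i) length(nb$idx[[i]]) == 0L, logical(1L)))
    if (length(iso) > 0L)
      warnf("%d virtual point(s) have no real neighbor in support", length(iso))
  }
  active <- which(startsWith(cloud$labels, "affected"))
  fr <- internal_forces(cloud, nb, params, active = active)
  cloud <- integrate_points(cloud, fr$forces, params, active = active)
  points$displacements <- cloud$displacements[seq_len(nr), , drop = FALSE]
  points$velocities <- cloud$velocities[seq_len(nr), , drop = FALSE]
  list(points = points, forces = fr$forces, gradient_evals = fr$gradient_evals)
}

#' Copy region labels onto a point set
#'
#' @param points a [point_element_set].
#' @param labels a [classify] result for the same points.
#' @return The point set with its `labels` field replaced.
#' @export
apply_labels <- function(points, labels) {
  if (length(labels$label) != n_points(points))
    stopf("labels length must equal point count")
  points$labels <- labels$label
  points
}
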