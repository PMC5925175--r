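## Surface incision: from an ordered cutting path on the mesh, build two
## quadratic Bezier curves bounding the wound (five-step construction) and
## retriangulate the affected region so the curves become free boundaries.

#' Vertices of all triangles incident to the cutting path
#'
#' The cutting-affected surface region: the union of the vertices of every
#' triangle containing at least one path vertex (a superset of the path).
#'
#' @param mesh a [surface_mesh].
#' @param path_vertices integer vertex indices of the cutting path.
#' @return Sorted integer vector of affected vertex indices (empty for an
#'   empty path).
#' @export
collect_affected <- function(mesh, path_vertices) {
  path_vertices <- as.integer(path_vertices)
  if (length(path_vertices) == 0L) return(integer())
  if (min(path_vertices) < 1L || max(path_vertices) > nrow(mesh$vertices))
    stopf("path vertex index out of range")
  tr <- mesh$triangles
  hit <- matrix(tr %in% path_vertices, ncol = 3L)
  keep <- hit[, 1L] | hit[, 2L] | hit[, 3L]
  sort(unique(c(as.vector(tr[keep, , drop = FALSE]), path_vertices)))
}

#' Split points by the side of the chord AB
#'
#' Each point is classified by the sign of `((B - A) x (P - A)) . n` where
#' `n` is the surface normal; points exactly on the chord count as positive
#' (documented tie rule). "Positive" is the left side seen along A->B with
#' the normal up.
#'
#' @param points n x 3 matrix of positions.
#' @param a,b chord endpoints (A != B).
#' @param surface_normal unit normal of the (locally flat) surface patch.
#' @return List with integer index vectors `positive` and `negative`.
#' @export
split_by_chord <- function(points, a, b, surface_normal) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (norm3(b - a) < .Machine$double.eps)
    stopf("chord endpoints coincide", class = "tissuecut_invalid_chord")
  points <- as_mat3(points)
  ab <- b - a
  rel <- sweep(points, 2L, a)
  cr <- cbind(ab[2L] * rel[, 3L] - ab[3L] * rel[, 2L],
              ab[3L] * rel[, 1L] - ab[1L] * rel[, 3L],
              ab[1L] * rel[, 2L] - ab[2L] * rel[, 1L])
  s <- cr %*% as.numeric(surface_normal)
  list(positive = which(s >= 0), negative = which(s < 0))
}

#' Control points with maximal distance to the chord
#'
#' C is the positive-side point farthest from the line AB, D the negative-side
#' one. Distances are measured in the patch plane (component along the
#' surface normal removed). Ties go to the lowest index; an empty side yields
#' the chord midpoint, collapsing that curve to the chord.
#'
#' @param positive,negative n x 3 matrices (possibly 0-row) of side points.
#' @param a,b chord endpoints.
#' @param surface_normal unit patch normal used for the in-plane projection.
#' @return List with 3-vectors `C` and `D`.
#' @export
select_control_points <- function(positive, negative, a, b,
                                  surface_normal = c(0, 0, 1)) {
  a <- as.numeric(a); b <- as.numeric(b)
  mid <- (a + b) / 2
  nrm <- as.numeric(surface_normal)
  dir <- normalize3(b - a)
  line_dist <- function(p) {
    rel <- p - a
    rel <- rel - sum(rel * nrm) * nrm       # project into the patch plane
    perp <- rel - sum(rel * dir) * dir
    norm3(perp)
  }
  pick <- function(set) {
    if (is.null(set) || nrow(set) == 0L) return(mid)
    d <- apply(set, 1L, line_dist)
    set[which.max(d), ]                      # which.max: first (lowest) index on ties
  }
  list(C = pick(if (is.null(positive)) NULL else as_mat3(positive)),
       D = pick(if (is.null(negative)) NULL else as_mat3(negative)))
}

#' Build the two-curve incision from a cutting path
#'
#' Five-step construction: the chord runs from the first to the last path
#' vertex; the affected vertex set is collected; affected vertices are split
#' by the chord; the extremal point on each side becomes the middle control
#' point; both quadratic Bezier curves are sampled at uniform parameters.
#'
#' @param mesh a [surface_mesh].
#' @param path_vertices ordered integer indices of the cutting path (>= 2).
#' @param samples_per_curve number of samples per curve (>= 2), default 16.
#' @return An object of class `incision_curves` with chord endpoints `A`,
#'   `B`, control points `C`, `D`, sample parameters `t`, the two sampled
#'   polylines, the path and affected vertex sets and the patch normal.
#' @export
build_incision <- function(mesh, path_vertices, samples_per_curve = 16L) {
  path_vertices <- as.integer(path_vertices)
  if (length(path_vertices) < 2L)
    stopf("cutting path needs at least 2 vertices", class = "tissuecut_no_cut")
  if (samples_per_curve < 2L) stopf("samples_per_curve must be >= 2")
  affected <- collect_affected(mesh, path_vertices)
  a <- mesh$vertices[path_vertices[1L], ]
  b <- mesh$vertices[path_vertices[length(path_vertices)], ]
  nrm <- average_normal(mesh, affected)
  cand <- setdiff(affected, path_vertices)
  pts <- mesh$vertices[cand, , drop = FALSE]
  sides <- if (length(cand) > 0L) split_by_chord(pts, a, b, nrm) else
    list(positive = integer(), negative = integer())
  cd <- select_control_points(pts[sides$positive, , drop = FALSE],
                              pts[sides$negative, , drop = FALSE],
                              a, b, nrm)
  tt <- seq(0, 1, length.out = samples_per_curve)
  structure(list(A = a, B = b, C = cd$C, D = cd$D, t = tt,
                 left_polyline = bezier_quadratic(a, cd$C, b, tt),
                 right_polyline = bezier_quadratic(a, cd$D, b, tt),
                 path_vertex_set = path_vertices,
                 affected_vertex_set = affected,
                 normal = nrm),
            class = "incision_curves")
}

#' @export
print.incision_curves <- function(x, ...) {
  cat(sprintf("incision_curves: %d path vertices, %d affected, %d samples/curve\n",
              length(x$path_vertex_set), length(x$affected_vertex_set), length(x$t)))
  invisible(x)
}

#' Retriangulate the incision region so the curves become free boundaries
#'
#' Interior path vertices are duplicated into left/right copies (triangles
#' assigned by centroid side of the chord), the split chains are moved onto
#' the sampled Bezier polylines, and remaining curve samples are inserted as
#' new boundary vertices by fanning the adjacent triangle from its opposite
#' vertex. The two polylines end up as free boundary chains (the open wound);
#' the rest of the mesh boundary is untouched.
#'
#' @param mesh the `surface_mesh` the curves were built on.
#' @param curves an [build_incision] result.
#' @return A new `surface_mesh` with the open incision.
#' @export
remesh_incision <- function(mesh, curves) {
  path <- curves$path_vertex_set
  if (length(path) < 2L) return(mesh)
  if (anyDuplicated(path) > 0L)
    stopf("self-intersecting cutting path", class = "tissuecut_unsupported_path")
  v <- mesh$vertices
  tr <- mesh$triangles
  flags <- mesh$vertex_flags
  a <- curves$A; b <- curves$B; nrm <- curves$normal
  side_of <- function(p) {                   # +1 left/positive (ties -> +1)
    s <- sum(cross3(b - a, p - a) * nrm)
    if (s >= 0) 1 else -1
  }
  m <- length(path)
  ns <- length(curves$t)
  ## chain parameters snap onto sample parameters (when enough samples) so
  ## that moved path vertices coincide with polyline points and the final
  ## boundary is exactly the sampled polyline, in order
  tpar <- if (ns >= m)
    curves$t[round((seq_len(m) - 1L) * (ns - 1L) / (m - 1L)) + 1L]
  else seq(0, 1, length.out = m)
  interior <- if (m > 2L) path[2:(m - 1L)] else integer()

  ## 1. split triangle fans around interior path vertices by centroid side
  dup <- integer(length(interior))           # right-side copies
  if (length(interior) > 0L) {
    for (k in seq_along(interior)) {
      dup[k] <- nrow(v) + 1L
      v <- rbind(v, v[interior[k], , drop = FALSE])
      flags <- c(flags, "path")
    }
    for (ti in seq_len(nrow(tr))) {
      hit <- tr[ti, ] %in% interior
      if (!any(hit)) next
      cen <- colMeans(v[tr[ti, ], , drop = FALSE])
      if (side_of(cen) < 0)                  # right side uses the copies
        tr[ti, hit] <- dup[match(tr[ti, hit], interior)]
    }
  }
  left_chain <- path
  right_chain <- c(path[1L], dup, path[m])

  ## 2. move chain vertices onto the curves (A, B stay: curve endpoints)
  for (k in seq_len(m)) {
    v[left_chain[k], ] <- bezier_quadratic(a, curves$C, b, tpar[k])
    v[right_chain[k], ] <- bezier_quadratic(a, curves$D, b, tpar[k])
  }

  ## 3. insert the remaining curve samples as boundary vertices
  insert_side <- function(chain, ctrl, side_sign) {
    ts <- curves$t
    degenerate <- max(row_norms(bezier_quadratic(a, ctrl, b, ts) -
                                bezier_quadratic(a, (a + b) / 2, b, ts))) < 1e-12
    if (degenerate) return(invisible(NULL))
    new_ts <- ts[vapply(ts, function(t) all(abs(t - tpar) > 1e-12), logical(1L))]
    if (length(new_ts) == 0L) return(invisible(NULL))
    for (k in seq_len(m - 1L)) {
      seg <- new_ts[new_ts > tpar[k] & new_ts < tpar[k + 1L]]
      if (length(seg) == 0L) next
      u <- chain[k]; w <- chain[k + 1L]
      has <- which(apply(tr, 1L, function(trow) u %in% trow && w %in% trow))
      if (length(has) == 0L) next            # path not edge-connected here
      if (length(has) > 1L) {                # shared edge: pick by centroid side
        sides <- vapply(has, function(ti) side_of(colMeans(v[tr[ti, ], , drop = FALSE])),
                        numeric(1L))
        has <- has[sides == side_sign]
        if (length(has) == 0L) next
        has <- has[1L]
      }
      trow <- tr[has, ]
      opp <- trow[!(trow %in% c(u, w))][1L]
      ## orient so the fan preserves the triangle's winding
      fwd <- (trow[1L] == u && trow[2L] == w) || (trow[2L] == u && trow[3L] == w) ||
        (trow[3L] == u && trow[1L] == w)
      new_idx <- integer(length(seg))
      for (q in seq_along(seg)) {
        new_idx[q] <- nrow(v) + 1L
        v <<- rbind(v, matrix(bezier_quadratic(a, ctrl, b, seg[q]), 1L))
        flags <<- c(flags, "boundary")
      }
      seqv <- c(u, new_idx, w)
      fans <- do.call(rbind, lapply(seq_len(length(seqv) - 1L), function(q) {
        if (fwd) c(seqv[q], seqv[q + 1L], opp) else c(seqv[q + 1L], seqv[q], opp)
      }))
      tr <<- rbind(tr[-has, , drop = FALSE], fans)
    }
    invisible(NULL)
  }
  insert_side(left_chain, curves$C, 1)
  insert_side(right_chain, curves$D, -1)

  flags[path] <- "path"
  if (length(dup) > 0L) flags[dup] <- "path"
  surface_mesh(v, tr, flags)
}

#' Extract a cutting path from the blade plane
#'
#' Analytic stand-in for hardware collision detection: surface edges crossing
#' the blade plane are found, each crossing is snapped to its nearest edge
#' endpoint, vertices below the vertical plane are discarded, and the result
#' is ordered along the scalpel axis (tip to handle).
#'
#' @param mesh a [surface_mesh].
#' @param planes a [planes_from_scalpel] result.
#' @return Ordered integer vector of path vertex indices (possibly empty).
#' @export
extract_cut_path <- function(mesh, planes) {
  v <- mesh$vertices
  phi <- plane_signed_distance(v, planes$blade_point, planes$blade_normal)
  up <- -planes$vertical_normal               # vertical normal stores -v_hat
  psi <- plane_signed_distance(v, planes$vertical_point, up)
  edges <- mesh_edges(mesh)
  sa <- phi[edges[, 1L]]; sb <- phi[edges[, 2L]]
  crossing <- which(sa * sb < 0)
  snapped <- ifelse(abs(sa[crossing]) <= abs(sb[crossing]),
                    edges[crossing, 1L], edges[crossing, 2L])
  cand <- unique(c(snapped, which(abs(phi) < 1e-9)))
  cand <- cand[psi[cand] > 0]
  ## keep only vertices under the blade segment (tip to handle sweep)
  axis <- normalize3(planes$axis)
  proj <- drop(sweep(v[cand, , drop = FALSE], 2L, planes$blade_point) %*% axis)
  cand <- cand[proj >= 0 & proj <= norm3(planes$axis)]
  if (length(cand) < 2L) return(integer())
  proj <- drop(sweep(v[cand, , drop = FALSE], 2L, planes$blade_point) %*% axis)
  cand[order(proj)]
}
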