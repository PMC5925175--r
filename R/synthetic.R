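## Synthetic tissue models: triangulated surface plus interior point elements
## generated by equal-distance interpolation (axis-aligned lattice clipped to
## the solid). Coordinates are mm, right-handed, +z vertical.

#' Synthetic box tissue model
#'
#' Generates a box-shaped tissue model: a closed triangulated box surface and
#' an interior axis-aligned lattice of point elements with step `spacing`,
#' anchored at the minimum corner and inclusive of the faces. Each point
#' element gets volume `spacing^3` and mass `density * volume`.
#'
#' @param extent length-3 positive box dimensions (mm).
#' @param spacing lattice step (mm); must be positive and no larger than the
#'   smallest extent.
#' @param density mass density (g/mm^3), default 1.
#' @param surface_segments integer n; each box face is an n x n quad grid of
#'   triangles. Default 1 gives the minimal 12-triangle box.
#' @return List with components `mesh` (a [surface_mesh]) and `points`
#'   (a [point_element_set]).
#' @export
make_box_model <- function(extent, spacing, density = 1, surface_segments = 1L) {
  extent <- as.numeric(extent)
  if (length(extent) != 3L || any(!is.finite(extent)) || any(extent <= 0))
    stopf("extent must be 3 positive lengths")
  if (!is_number(spacing) || spacing <= 0 || spacing > min(extent))
    stopf("spacing must be positive and <= every extent")
  axes <- lapply(extent, function(e) seq(0, by = spacing, length.out = floor(e / spacing) + 1L))
  grid <- expand.grid(x = axes[[1L]], y = axes[[2L]], z = axes[[3L]])
  pos <- as.matrix(grid)
  vol <- spacing^3
  points <- point_element_set(pos, masses = rep(density * vol, nrow(pos)),
                              volumes = rep(vol, nrow(pos)))
  mesh <- box_surface(extent, as.integer(surface_segments))
  list(mesh = mesh, points = points)
}

#' Synthetic ellipsoid ("liver-like") tissue model
#'
#' Interior point elements are the lattice points (step `spacing`, centred at
#' the origin) inside the ellipsoid; the surface is a UV-sphere triangulation
#' scaled by the semi-axes.
#'
#' @param semi_axes length-3 positive semi-axes (mm).
#' @param spacing lattice step (mm).
#' @param mesh_resolution number of latitude bands of the surface
#'   triangulation (>= 3), default 12.
#' @param density mass density (g/mm^3), default 1.
#' @return List with components `mesh` and `points` as in [make_box_model].
#' @export
make_ellipsoid_model <- function(semi_axes, spacing, mesh_resolution = 12L,
                                 density = 1) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stopf("semi_axes must be 3 positive lengths")
  if (!is_number(spacing) || spacing <= 0) stopf("spacing must be positive")
  axes <- lapply(semi_axes, function(a) {
    k <- floor(a / spacing)
    seq(-k, k) * spacing
  })
  grid <- as.matrix(expand.grid(x = axes[[1L]], y = axes[[2L]], z = axes[[3L]]))
  inside <- (grid[, 1L] / semi_axes[1L])^2 + (grid[, 2L] / semi_axes[2L])^2 +
    (grid[, 3L] / semi_axes[3L])^2 <= 1
  pos <- grid[inside, , drop = FALSE]
  if (nrow(pos) == 0L) stopf("spacing too large: no interior lattice point")
  vol <- spacing^3
  points <- point_element_set(pos, masses = rep(density * vol, nrow(pos)),
                              volumes = rep(vol, nrow(pos)))
  mesh <- ellipsoid_surface(semi_axes, as.integer(mesh_resolution))
  list(mesh = mesh, points = points)
}

## Closed box surface [0,extent], each face an n x n quad grid, duplicate
## vertices along face borders merged so the mesh is closed (Euler = 2).
box_surface <- function(extent, n = 1L) {
  if (n < 1L) stopf("surface_segments must be >= 1")
  verts <- list(); tris <- list(); nv <- 0L
  add_face <- function(origin, du, dv, flip) {
    idx <- matrix(0L, n + 1L, n + 1L)
    fv <- matrix(0, (n + 1L)^2, 3L)
    k <- 0L
    for (i in 0:n) for (j in 0:n) {
      k <- k + 1L
      fv[k, ] <- origin + du * (i / n) + dv * (j / n)
      idx[i + 1L, j + 1L] <- nv + k
    }
    ft <- matrix(0L, 2L * n * n, 3L)
    k <- 0L
    for (i in 1:n) for (j in 1:n) {
      a <- idx[i, j]; b <- idx[i + 1L, j]; d <- idx[i, j + 1L]; cc <- idx[i + 1L, j + 1L]
      t1 <- c(a, b, cc); t2 <- c(a, cc, d)
      if (flip) { t1 <- rev(t1); t2 <- rev(t2) }
      ft[k + 1L, ] <- t1; ft[k + 2L, ] <- t2
      k <- k + 2L
    }
    verts[[length(verts) + 1L]] <<- fv
    tris[[length(tris) + 1L]] <<- ft
    nv <<- nv + nrow(fv)
  }
  ex <- c(extent[1L], 0, 0); ey <- c(0, extent[2L], 0); ez <- c(0, 0, extent[3L])
  ## windings chosen so every face normal points outward
  add_face(c(0, 0, 0), ex, ey, flip = TRUE)           # bottom  (z = 0)
  add_face(ez, ex, ey, flip = FALSE)                  # top     (z = max)
  add_face(c(0, 0, 0), ey, ez, flip = TRUE)           # x = 0
  add_face(ex, ey, ez, flip = FALSE)                  # x = max
  add_face(c(0, 0, 0), ex, ez, flip = FALSE)          # y = 0
  add_face(ey, ex, ez, flip = TRUE)                   # y = max
  v <- do.call(rbind, verts); tr <- do.call(rbind, tris)
  merge_duplicate_vertices(v, tr)
}

## UV-sphere scaled by the semi-axes; `bands` latitude bands, 2*bands
## longitudes; closed genus-0 triangulation.
ellipsoid_surface <- function(semi_axes, bands = 12L) {
  if (bands < 3L) stopf("mesh_resolution must be >= 3")
  nlon <- 2L * bands
  verts <- matrix(0, 2L + (bands - 1L) * nlon, 3L)
  verts[1L, ] <- c(0, 0, semi_axes[3L])
  verts[2L, ] <- c(0, 0, -semi_axes[3L])
  k <- 2L
  for (i in seq_len(bands - 1L)) {
    th <- pi * i / bands
    for (j in seq_len(nlon)) {
      ph <- 2 * pi * (j - 1L) / nlon
      k <- k + 1L
      verts[k, ] <- c(semi_axes[1L] * sin(th) * cos(ph),
                      semi_axes[2L] * sin(th) * sin(ph),
                      semi_axes[3L] * cos(th))
    }
  }
  ring <- function(i, j) 2L + (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L
  tris <- list()
  for (j in seq_len(nlon)) {
    tris[[length(tris) + 1L]] <- c(1L, ring(1L, j), ring(1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(2L, ring(bands - 1L, j + 1L), ring(bands - 1L, j))
  }
  if (bands > 2L) {
    for (i in seq_len(bands - 2L)) for (j in seq_len(nlon)) {
      a <- ring(i, j); b <- ring(i, j + 1L); cc <- ring(i + 1L, j); d <- ring(i + 1L, j + 1L)
      tris[[length(tris) + 1L]] <- c(a, cc, b)
      tris[[length(tris) + 1L]] <- c(b, cc, d)
    }
  }
  surface_mesh(verts, do.call(rbind, tris))
}

## Merge vertices that coincide to 1e-9 mm and drop collapsed triangles.
merge_duplicate_vertices <- function(v, tr) {
  key <- apply(round(v / 1e-9) * 1e-9, 1L, paste, collapse = ",")
  first <- match(key, key)
  keep <- sort(unique(first))
  remap <- match(first, keep)
  v2 <- v[keep, , drop = FALSE]
  tr2 <- matrix(remap[tr], ncol = 3L)
  ok <- tr2[, 1L] != tr2[, 2L] & tr2[, 1L] != tr2[, 3L] & tr2[, 2L] != tr2[, 3L]
  surface_mesh(v2, tr2[ok, , drop = FALSE])
}
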