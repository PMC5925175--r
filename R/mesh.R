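#' Surface triangle mesh
#'
#' Container for the surface component of the coupled tissue model: vertex
#' positions in millimetres, triangle connectivity, and per-vertex flags used
#' by the incision pipeline (`"none"`, `"path"`, `"affected"`, `"boundary"`).
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param vertex_flags optional character vector of per-vertex marks;
#'   defaults to `"none"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, vertex_flags = NULL) {
  vertices <- as_mat3(vertices, "vertices")
  if (is.null(dim(triangles))) triangles <- matrix(triangles, ncol = 3L, byrow = TRUE)
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3L) stopf("triangles must have 3 columns")
  storage.mode(triangles) <- "integer"
  nv <- nrow(vertices)
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > nv)
      stopf("triangle index out of range [1, %d]", nv)
    if (any(triangles[, 1L] == triangles[, 2L] |
            triangles[, 1L] == triangles[, 3L] |
            triangles[, 2L] == triangles[, 3L]))
      stopf("degenerate triangle (repeated vertex index)")
  }
  if (is.null(vertex_flags)) vertex_flags <- rep("none", nv)
  if (length(vertex_flags) != nv) stopf("vertex_flags length must equal vertex count")
  structure(list(vertices = vertices, triangles = triangles,
                 vertex_flags = as.character(vertex_flags)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  b <- mesh_boundary_edges(x)
  cat(sprintf("  boundary edges: %d, Euler characteristic: %d\n",
              nrow(b), euler_characteristic(x)))
  invisible(x)
}

## Unique undirected edges, one row per edge (sorted index pairs).
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e), , drop = FALSE]
}

#' Euler characteristic V - E + F of a mesh
#'
#' Genus-0 closed meshes (the synthetic generators) satisfy V - E + F = 2.
#' @param mesh a `surface_mesh`.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$triangles)
}

## Edges belonging to exactly one triangle (free boundary of the mesh).
mesh_boundary_edges <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(matrix(integer(), ncol = 2L))
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  free <- names(cnt)[cnt == 1L]
  if (length(free) == 0L) return(matrix(integer(), ncol = 2L))
  m <- do.call(rbind, strsplit(free, " ", fixed = TRUE))
  matrix(as.integer(m), ncol = 2L)
}

## Number of closed boundary loops, by walking directed boundary edges with
## fan-aware successors (handles pinch vertices where two loops touch).
## Assumes consistently oriented triangles, as all generators here produce.
boundary_loop_count <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(0L)
  dir_e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  tri_of <- rep(seq_len(nrow(tr)), 3L)
  key <- paste(dir_e[, 1L], dir_e[, 2L])
  rkey <- paste(dir_e[, 2L], dir_e[, 1L])
  has_rev <- key %in% rkey
  bnd <- which(!has_rev)                     # directed boundary edges
  if (length(bnd) == 0L) return(0L)
  edge_lookup <- stats::setNames(seq_along(key), key)
  bset <- stats::setNames(seq_along(bnd), key[bnd])
  successor <- integer(length(bnd))
  third <- function(trow, u, v) trow[!(trow %in% c(u, v))][1L]
  for (q in seq_along(bnd)) {
    u <- dir_e[bnd[q], 1L]; v <- dir_e[bnd[q], 2L]
    t_cur <- tri_of[bnd[q]]
    w <- third(tr[t_cur, ], u, v)
    repeat {
      nxt <- bset[paste(v, w)]
      if (!is.na(nxt)) { successor[q] <- nxt; break }
      ## pivot around v into the triangle holding directed edge (w, v)
      opp <- edge_lookup[paste(w, v)]
      if (is.na(opp)) { successor[q] <- q; break }   # non-manifold guard
      t_cur <- tri_of[opp]
      w <- third(tr[t_cur, ], v, w)
    }
  }
  seen <- logical(length(bnd)); loops <- 0L
  for (q in seq_along(bnd)) {
    if (seen[q]) next
    loops <- loops + 1L
    cur <- q
    while (!seen[cur]) { seen[cur] <- TRUE; cur <- successor[cur] }
  }
  loops
}

## Per-triangle areas (mm^2).
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (nrow(tr) == 0L) return(numeric())
  ab <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  ac <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  cr <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
              ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
              ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
  0.5 * row_norms(cr)
}

## Area-weighted average triangle normal over a vertex subset (unit vector).
average_normal <- function(mesh, vertex_set = NULL) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (!is.null(vertex_set)) {
    keep <- apply(matrix(tr %in% vertex_set, ncol = 3L), 1L, any)
    tr <- tr[keep, , drop = FALSE]
  }
  if (nrow(tr) == 0L) return(c(0, 0, 1))
  n <- c(0, 0, 0)
  for (k in seq_len(nrow(tr))) {
    a <- v[tr[k, 1L], ]; b <- v[tr[k, 2L], ]; ce <- v[tr[k, 3L], ]
    n <- n + cross3(b - a, ce - a)
  }
  if (norm3(n) < 1e-12) c(0, 0, 1) else normalize3(n)
}
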