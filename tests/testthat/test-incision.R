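# Bezier incision construction and retriangulation.

test_that("Bernstein basis: values, bounds and partition of unity", {
  expect_equal(bernstein(0, 2, 0), 1)
  expect_equal(bernstein(1, 2, 0.5), 0.5)
  tt <- seq(0, 1, length.out = 101L)
  for (n in 1:3) {
    s <- Reduce(`+`, lapply(0:n, function(i) bernstein(i, n, tt)))
    expect_lt(max(abs(s - 1)), 1e-12)
    for (i in 0:n) expect_true(all(bernstein(i, n, tt) >= 0))
  }
  expect_error(bernstein(3, 2, 0.5), "i <= n")
  expect_error(bernstein(0, 2, 1.5), "\\[0, 1\\]")
})

test_that("quadratic Bezier interpolates endpoints and stays in the hull", {
  p0 <- c(0, 0, 0); p1 <- c(1, 2, 0); p2 <- c(2, 0, 0)
  expect_equal(bezier_quadratic(p0, p1, p2, 0), p0)
  expect_equal(bezier_quadratic(p0, p1, p2, 1), p2)
  expect_equal(bezier_quadratic(p0, p1, p2, 0.5), c(1, 1, 0))
  set.seed(11)
  for (r in 1:20) {
    ctrl <- matrix(rnorm(9), 3L)
    tt <- runif(5)
    pts <- bezier_quadratic(ctrl[1, ], ctrl[2, ], ctrl[3, ], tt)
    # Bernstein weights are nonnegative and sum to one => hull containment
    w <- cbind((1 - tt)^2, 2 * tt * (1 - tt), tt^2)
    expect_equal(pts, w %*% ctrl, tolerance = 1e-12)
    expect_equal(bezier_quadratic(ctrl[1, ], ctrl[2, ], ctrl[3, ], 0), ctrl[1, ])
    expect_equal(bezier_quadratic(ctrl[1, ], ctrl[2, ], ctrl[3, ], 1), ctrl[3, ])
  }
})

test_that("collect_affected returns the one-ring union of the path", {
  star <- vertex_star(6L)
  expect_equal(collect_affected(star, 1L), 1:7)
  patch <- flat_patch(3L)
  # brute-force incidence oracle over all triangles
  oracle <- function(mesh, path) {
    out <- path
    for (k in seq_len(nrow(mesh$triangles)))
      if (any(mesh$triangles[k, ] %in% path))
        out <- c(out, mesh$triangles[k, ])
    sort(unique(out))
  }
  for (path in list(1L, 6L, c(2L, 6L, 10L)))
    expect_equal(collect_affected(patch, path), oracle(patch, path))
  all_v <- seq_len(nrow(patch$vertices))
  expect_equal(collect_affected(patch, all_v), all_v)
  expect_equal(collect_affected(patch, integer()), integer())
})

test_that("split_by_chord signs match a brute-force oracle with on-chord ties positive", {
  a <- c(0, 0, 0); b <- c(2, 0, 0); n <- c(0, 0, 1)
  s <- split_by_chord(rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 0)), a, b, n)
  expect_equal(s$positive, c(1L, 3L))  # on-chord point 3 goes positive
  expect_equal(s$negative, 2L)
  expect_error(split_by_chord(rbind(c(1, 1, 0)), a, a, n), class = "tissuecut_invalid_chord")

  set.seed(21)
  pts <- matrix(rnorm(300), ncol = 3L)
  a <- c(-1, 0, 0); b <- c(2, 0, 0); n <- c(0, 0, 1)
  got <- split_by_chord(pts, a, b, n)
  # independent signed-volume oracle
  sgn <- apply(pts, 1L, function(p) det(rbind(b - a, p - a, n)))
  expect_equal(got$positive, which(sgn >= 0))
  expect_equal(got$negative, which(sgn < 0))

  # mirroring the points across the chord plane (xz) swaps the side sets
  refl <- pts; refl[, 2] <- -refl[, 2]
  got2 <- split_by_chord(refl, a, b, n)
  expect_equal(sort(got2$negative), which(sgn > 0))
  expect_equal(sort(got2$positive), which(sgn <= 0))
})

test_that("control points maximize distance to the chord with documented ties", {
  a <- c(0, 0, 0); b <- c(4, 0, 0)
  cd <- select_control_points(rbind(c(1, 2, 0), c(1, 1, 0)), rbind(c(1, -3, 0)), a, b)
  expect_equal(cd$C, c(1, 2, 0))
  expect_equal(cd$D, c(1, -3, 0))
  # tie: equidistant candidates -> lowest row index
  cd2 <- select_control_points(rbind(c(3, 2, 0), c(1, 2, 0)), NULL, a, b)
  expect_equal(cd2$C, c(3, 2, 0))
  # empty side degenerates to the chord midpoint
  expect_equal(cd2$D, c(2, 0, 0))
})

test_that("build_incision produces mirror-symmetric curves on a symmetric patch", {
  patch <- flat_patch(4L)                     # path along y = 2, mid row
  path <- which(patch$vertices[, 2] == 2)
  path <- path[order(patch$vertices[path, 1])]
  cur <- build_incision(patch, path, samples_per_curve = 9L)
  refl <- cur$right_polyline
  refl[, 2] <- 4 - refl[, 2]                  # mirror about y = 2
  expect_equal(cur$left_polyline, refl, tolerance = 1e-9)
  expect_equal(cur$left_polyline[1, ], cur$A)
  expect_equal(cur$left_polyline[9, ], cur$B)
  expect_equal(cur$right_polyline[1, ], cur$A)

  # two samples -> polylines are exactly the chord endpoints
  cur2 <- build_incision(patch, path, samples_per_curve = 2L)
  expect_equal(cur2$left_polyline, rbind(cur$A, cur$B))

  expect_error(build_incision(patch, path[1], 8L), class = "tissuecut_no_cut")
})

test_that("points collinear with the chord collapse both curves to the chord", {
  a <- c(0, 0, 0); b <- c(3, 0, 0)
  on_chord <- rbind(c(1, 0, 0), c(2, 0, 0))
  cd <- select_control_points(on_chord, on_chord, a, b)
  tt <- seq(0, 1, length.out = 7)
  for (ctrl in list(cd$C, cd$D)) {
    poly <- bezier_quadratic(a, ctrl, b, tt)
    # every sampled point lies on the chord line (zero cross product)
    for (k in seq_len(nrow(poly))) {
      cr <- c((b - a)[2] * (poly[k, 3] - a[3]) - (b - a)[3] * (poly[k, 2] - a[2]),
              (b - a)[3] * (poly[k, 1] - a[1]) - (b - a)[1] * (poly[k, 3] - a[3]),
              (b - a)[1] * (poly[k, 2] - a[2]) - (b - a)[2] * (poly[k, 1] - a[1]))
      expect_lt(max(abs(cr)), 1e-12)
    }
  }
})

test_that("remesh bookkeeping: duplicates, samples, one extra boundary loop", {
  patch <- flat_patch(2L)                     # interior cut, path y = 1
  path <- which(patch$vertices[, 2] == 1)
  path <- path[order(patch$vertices[path, 1])]
  cur <- build_incision(patch, path, samples_per_curve = 8L)
  m2 <- remesh_incision(patch, cur)
  n_dup <- length(path) - 2L
  n_samples <- 2L * (8L - length(path))       # chain vertices occupy samples
  expect_equal(nrow(m2$vertices), nrow(patch$vertices) + n_dup + n_samples)
  expect_equal(tissuecut:::boundary_loop_count(m2),
               tissuecut:::boundary_loop_count(patch) + 1L)
  expect_true(all(tissuecut:::triangle_areas(m2) > 1e-12))

  # 2-vertex path across a quad: no duplicates, samples only
  qm <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4)))
  qc <- build_incision(qm, c(1L, 3L), samples_per_curve = 5L)
  qm2 <- remesh_incision(qm, qc)
  expect_equal(nrow(qm2$vertices), 4L + 0L + 2L * 3L)
  expect_equal(tissuecut:::boundary_loop_count(qm2), 2L)
})

test_that("remesh is the identity for empty cuts and rejects self-intersections", {
  patch <- flat_patch(2L)
  cur <- build_incision(patch, c(2L, 5L, 8L), 6L)
  cur$path_vertex_set <- integer()
  expect_identical(remesh_incision(patch, cur), patch)
  bad <- build_incision(patch, c(2L, 5L, 8L), 6L)
  bad$path_vertex_set <- c(2L, 5L, 2L)
  expect_error(remesh_incision(patch, bad), class = "tissuecut_unsupported_path")
})

test_that("the new boundary follows the sampled polylines in order", {
  patch <- flat_patch(2L)
  path <- which(patch$vertices[, 2] == 1)
  path <- path[order(patch$vertices[path, 1])]
  cur <- build_incision(patch, path, samples_per_curve = 8L)
  m2 <- remesh_incision(patch, cur)
  be <- tissuecut:::mesh_boundary_edges(m2)
  has_edge <- function(u, v) any((be[, 1] == u & be[, 2] == v) |
                                 (be[, 1] == v & be[, 2] == u))
  # walk each polyline: every consecutive sample pair must be a boundary edge
  for (side in c("left", "right")) {
    poly <- if (side == "left") cur$left_polyline else cur$right_polyline
    idx <- apply(poly, 1L, function(p) {
      d <- sweep(m2$vertices, 2L, p); which.min(rowSums(d * d))
    })
    expect_lt(max(abs(m2$vertices[idx, ] - poly)), 1e-9)
    for (k in seq_len(nrow(poly) - 1L))
      expect_true(has_edge(idx[k], idx[k + 1L]))
  }
})
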