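# Small geometric fixtures built in code.

# Flat (2n x 2n)-triangle grid patch on z = 0 spanning [0, n] x [0, n].
flat_patch <- function(n = 2L) {
  id <- function(i, j) i * (n + 1L) + j + 1L
  v <- cbind(rep(0:n, each = n + 1L), rep(0:n, n + 1L), 0)
  tri <- list()
  for (i in 0:(n - 1L)) for (j in 0:(n - 1L)) {
    a <- id(i, j); b <- id(i + 1L, j); cc <- id(i, j + 1L); d <- id(i + 1L, j + 1L)
    tri[[length(tri) + 1L]] <- c(a, b, d)
    tri[[length(tri) + 1L]] <- c(a, d, cc)
  }
  surface_mesh(v, do.call(rbind, tri))
}

# Vertex star: centre vertex 1 ringed by k vertices, k triangles.
vertex_star <- function(k = 6L) {
  th <- 2 * pi * (seq_len(k) - 1L) / k
  v <- rbind(c(0, 0, 0), cbind(cos(th), sin(th), 0))
  tri <- cbind(1L, 1L + seq_len(k), 1L + c(seq_len(k)[-1L], 1L))
  surface_mesh(v, tri)
}

# Uniformly random point cloud in a box, as a point_element_set.
random_cloud <- function(n, lo = 0, hi = 10) {
  point_element_set(matrix(stats::runif(3L * n, lo, hi), ncol = 3L))
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Canonical triangle-set representation: vertices keyed by rounded position,
# each triangle's keys sorted, then rows sorted lexicographically.
canonical_triangles <- function(mesh, digits = 9L) {
  key <- apply(round(mesh$vertices, digits), 1L, paste, collapse = ",")
  tr <- matrix(key[mesh$triangles], ncol = 3L)
  tr <- t(apply(tr, 1L, sort))
  tr[order(tr[, 1L], tr[, 2L], tr[, 3L]), , drop = FALSE]
}
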