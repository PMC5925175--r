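## Meshless elasticity core: compact-support kernel weights, moment matrix,
## MLS displacement gradients, Green strain, single-parameter Hookean stress,
## antisymmetric internal force pairs and explicit (damped) Euler
## integration. All quantities are evaluated on rest-position neighborhoods;
## deformation enters through the displacement field only.

#' Material and integration parameters
#'
#' @param E stiffness (force/mm^2); the model's single material parameter.
#' @param h kernel support radius (mm); a practical default is 2.2 x the
#'   lattice spacing, giving >= 10 interior neighbors.
#' @param dt explicit time step (s).
#' @param damping per-step velocity damping c in `[0, 1]`; 0 reproduces the
#'   undamped integrator.
#' @param density mass density (g/mm^3), used by the synthetic generators.
#' @return An object of class `material_params`.
#' @export
material_params <- function(E = 1, h, dt = 0.01, damping = 0, density = 1) {
  if (!is_number(E) || E <= 0) stopf("E must be > 0")
  if (!is_number(h) || h <= 0) stopf("support radius h must be > 0")
  if (!is_number(dt) || dt <= 0) stopf("dt must be > 0")
  if (!is_number(damping) || damping < 0 || damping > 1)
    stopf("damping must lie in [0, 1]")
  structure(list(E = E, h = h, dt = dt, damping = damping, density = density),
            class = "material_params")
}

#' Compactly supported smoothing kernel
#'
#' `w(r) = (1 - (r/h)^2)^3` for `r < h`, else 0: C2-smooth, monotone
#' non-increasing, `w(0) = 1`. Used as the MLS weight omega_ij (symmetric in
#' i, j since it depends on the distance only).
#'
#' @param r distance(s), >= 0 (mm).
#' @param h support radius (mm), > 0.
#' @return Kernel value(s).
#' @export
mls_weight <- function(r, h) {
  if (!is_number(h) || h <= 0) stopf("support radius h must be > 0")
  q2 <- (r / h)^2
  ifelse(r < h, (1 - q2)^3, 0)
}

#' Build MLS neighborhoods and moment matrices
#'
#' Neighbors within the support radius are found by uniform spatial hashing
#' on rest positions; the per-point moment matrix
#' `M_i = sum_j x_ij x_ij^T omega_ij` is assembled and inverted. Near-singular
#' matrices (condition number > 1e8) get a Tikhonov regularization
#' `eps I, eps = 1e-9 trace(M)/3` and are flagged. Points with fewer than 4
#' neighbors are flagged rigid (zero gradient) with a warning.
#'
#' @param points a [point_element_set] (rest positions are used).
#' @param params a [material_params] (support radius `h`).
#' @param quiet suppress the few-neighbor warning.
#' @return An object of class `neighborhoods`: per point the neighbor
#'   indices `idx`, offsets `d` (rows `x_j - x_i`; the conventional offset
#'   `x_ij = x_i - x_j` is the negative), weights `w`, inverse moment matrix
#'   `Minv`, and `singular` / `rigid` flags.
#' @export
build_neighborhoods <- function(points, params, quiet = FALSE) {
  x <- points$positions
  n <- nrow(x)
  h <- params$h
  cell <- floor(sweep(x, 2L, apply(x, 2L, min)) / h)
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  buckets <- split(seq_len(n), key)
  cell_of <- match(key, names(buckets))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  neigh_cells <- lapply(seq_len(n), function(i) {
    ks <- paste(cell[i, 1L] + offs[, 1L], cell[i, 2L] + offs[, 2L],
                cell[i, 3L] + offs[, 3L])
    unlist(buckets[ks], use.names = FALSE)
  })
  idx <- vector("list", n); dl <- vector("list", n); wl <- vector("list", n)
  Minv <- vector("list", n)
  singular <- logical(n); rigid <- logical(n)
  for (i in seq_len(n)) {
    cand <- neigh_cells[[i]]
    cand <- cand[cand != i]
    d <- x[cand, , drop = FALSE] - matrix(x[i, ], length(cand), 3L, byrow = TRUE)
    r <- row_norms(d)
    keep <- r <= h & r > 0
    cand <- cand[keep]; d <- d[keep, , drop = FALSE]; r <- r[keep]
    w <- mls_weight(r, h)
    idx[[i]] <- cand; dl[[i]] <- d; wl[[i]] <- w
    if (length(cand) < 4L) {
      rigid[i] <- TRUE
      Minv[[i]] <- matrix(0, 3L, 3L)
      next
    }
    M <- crossprod(d * sqrt(w))              # sum_j w_ij d_ij d_ij^T
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (ev[3L] <= 0 || ev[1L] / ev[3L] > 1e8) {
      M <- M + diag(1e-9 * sum(diag(M)) / 3, 3L)
      singular[i] <- TRUE
    }
    Minv[[i]] <- solve(M)
  }
  if (!quiet && any(rigid))
    warnf("%d point(s) have fewer than 4 neighbors and are treated as rigid",
          sum(rigid))
  structure(list(idx = idx, d = dl, w = wl, Minv = Minv,
                 singular = singular, rigid = rigid, h = h),
            class = "neighborhoods")
}

#' @export
print.neighborhoods <- function(x, ...) {
  k <- lengths(x$idx)
  cat(sprintf("neighborhoods: %d points, %d-%d neighbors (median %d), h = %g\n",
              length(k), min(k), max(k), as.integer(stats::median(k)), x$h))
  if (any(x$singular)) cat(sprintf("  %d regularized moment matrices\n", sum(x$singular)))
  invisible(x)
}

#' MLS displacement gradient at one point
#'
#' Recovers the physical gradient: for an affine field `U(x) = A (x - x_i)`
#' the result is exactly `A` (to round-off) whenever the moment matrix is
#' well conditioned. Row `a` holds the spatial gradient of displacement
#' component `a`.
#'
#' @param i point index.
#' @param U n x 3 displacement matrix for all points.
#' @param nb a [build_neighborhoods] result.
#' @return 3 x 3 gradient matrix (zero for rigid-flagged points).
#' @export
displacement_gradient <- function(i, U, nb) {
  if (nb$rigid[i]) return(matrix(0, 3L, 3L))
  j <- nb$idx[[i]]
  dU <- U[j, , drop = FALSE] - matrix(U[i, ], length(j), 3L, byrow = TRUE)
  t(nb$Minv[[i]] %*% crossprod(nb$d[[i]], dU * nb$w[[i]]))
}

#' Green strain tensor from a displacement gradient
#'
#' `eps = (G + G^T + G^T G) / 2`; the quadratic term makes the strain vanish
#' identically under rigid rotations (`G = R - I`).
#'
#' @param gradU 3 x 3 displacement gradient.
#' @return 3 x 3 symmetric strain tensor.
#' @export
green_strain <- function(gradU) {
  0.5 * (gradU + t(gradU) + crossprod(gradU))
}

#' Hookean stress from strain
#'
#' Componentwise single-parameter law `sigma = E eps`.
#' @param strain 3 x 3 symmetric strain tensor.
#' @param E stiffness.
#' @return 3 x 3 stress tensor.
#' @export
stress <- function(strain, E) E * strain

## Per-point force matrix B_i = -2 v_i (gradU + I) sigma M^-1.
force_matrix <- function(gradU, sigma, vol, Minv) {
  -2 * vol * (gradU + diag(3L)) %*% sigma %*% Minv
}

#' Internal elastic forces
#'
#' For each active point the displacement gradient, Green strain, stress and
#' force matrix `B_i = -2 v_i (gradU + I) sigma M^-1` are evaluated; the pair
#' term `B_i (x_j - x_i) omega_ij` is added to each neighbor and subtracted
#' from the point itself, so forces sum to zero by construction and oppose
#' the deformation.
#'
#' @param points a [point_element_set].
#' @param nb a [build_neighborhoods] result.
#' @param params a [material_params].
#' @param active indices of points whose strain state is evaluated (default:
#'   all non-virtual points). Unlisted points still receive pair forces but
#'   incur no gradient work.
#' @return List: `forces` (n x 3), `states` (per active point: gradU,
#'   strain, stress, B), `gradient_evals` (solver work counter).
#' @export
internal_forces <- function(points, nb, params,
                            active = which(points$labels != "virtual")) {
  U <- points$displacements
  n <- nrow(U)
  f <- matrix(0, n, 3L)
  states <- vector("list", length(active))
  names(states) <- as.character(active)
  for (s in seq_along(active)) {
    i <- active[s]
    G <- displacement_gradient(i, U, nb)
    eps <- green_strain(G)
    sig <- stress(eps, params$E)
    B <- force_matrix(G, sig, points$volumes[i], nb$Minv[[i]])
    j <- nb$idx[[i]]
    if (length(j) > 0L) {
      contrib <- (nb$d[[i]] * nb$w[[i]]) %*% t(B)   # rows: B (x_j - x_i) w
      f[j, ] <- f[j, , drop = FALSE] + contrib
      f[i, ] <- f[i, ] - colSums(contrib)
    }
    states[[s]] <- list(gradU = G, strain = eps, stress = sig, B = B)
  }
  list(forces = f, states = states, gradient_evals = length(active))
}

#' Explicit damped Euler step
#'
#' `v <- (1 - c)(v + dt f / m)`, `U <- U + dt v`; only the listed points are
#' integrated (unaffected points keep their state bit-identically, virtual
#' points keep their prescribed displacements and zero velocity). Current
#' positions are always rest + displacement, so no drift accumulates.
#'
#' @param points a [point_element_set].
#' @param forces n x 3 force matrix.
#' @param params a [material_params].
#' @param active indices of points to integrate (default: affected points).
#' @return The updated `point_element_set`.
#' @export
integrate_points <- function(points, forces, params,
                             active = which(startsWith(points$labels, "affected"))) {
  if (length(active) == 0L) return(points)
  fa <- forces[active, , drop = FALSE]
  if (any(!is.finite(fa))) {
    bad <- active[which(!is.finite(rowSums(fa)))[1L]]
    stopf("numerical blowup: non-finite force at point %d", bad,
          class = "tissuecut_blowup")
  }
  acc <- fa / points$masses[active]
  v <- (1 - params$damping) * (points$velocities[active, , drop = FALSE] +
                                 params$dt * acc)
  points$velocities[active, ] <- v
  points$displacements[active, ] <- points$displacements[active, , drop = FALSE] +
    params$dt * v
  points
}
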