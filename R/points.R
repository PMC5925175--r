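#' Internal meshless point elements
#'
#' The interior of the tissue is discretized as independent point elements
#' carrying mass, volume, displacement and velocity state. Labels partition
#' the set into `"unaffected"`, `"affected_plus"`, `"affected_minus"` and
#' `"virtual"` points (the latter are coupling constraints, not matter).
#'
#' @param positions n x 3 rest positions (mm).
#' @param masses per-point masses (g), strictly positive.
#' @param volumes per-point volumes (mm^3), strictly positive.
#' @param displacements n x 3 displacements U_i (mm), default zero.
#' @param velocities n x 3 velocities (mm/s), default zero.
#' @param labels per-point region labels, default `"unaffected"`.
#' @return An object of class `point_element_set`.
#' @export
point_element_set <- function(positions, masses = NULL, volumes = NULL,
                              displacements = NULL, velocities = NULL,
                              labels = NULL) {
  positions <- as_mat3(positions, "positions")
  n <- nrow(positions)
  masses <- if (is.null(masses)) rep(1, n) else as.numeric(masses)
  volumes <- if (is.null(volumes)) rep(1, n) else as.numeric(volumes)
  if (length(masses) != n || length(volumes) != n)
    stopf("masses/volumes length must equal point count")
  if (any(masses <= 0) || any(volumes <= 0))
    stopf("masses and volumes must be strictly positive")
  displacements <- if (is.null(displacements)) matrix(0, n, 3L) else as_mat3(displacements, "displacements")
  velocities <- if (is.null(velocities)) matrix(0, n, 3L) else as_mat3(velocities, "velocities")
  if (nrow(displacements) != n || nrow(velocities) != n)
    stopf("state matrices must match point count")
  labels <- if (is.null(labels)) rep("unaffected", n) else as.character(labels)
  if (length(labels) != n) stopf("labels length must equal point count")
  ok <- labels %in% c("unaffected", "affected_plus", "affected_minus", "virtual")
  if (!all(ok)) stopf("unknown label: %s", labels[!ok][1L])
  structure(list(positions = positions, masses = masses, volumes = volumes,
                 displacements = displacements, velocities = velocities,
                 labels = labels),
            class = "point_element_set")
}

#' @export
print.point_element_set <- function(x, ...) {
  cat(sprintf("point_element_set: %d points\n", nrow(x$positions)))
  print(table(x$labels))
  invisible(x)
}

#' Current (deformed) positions of point elements
#'
#' Rest position plus displacement; rest positions are kept fixed so that
#' integration never accumulates drift.
#' @param points a `point_element_set`.
#' @return n x 3 matrix of deformed positions (mm).
#' @export
current_positions <- function(points) points$positions + points$displacements

n_points <- function(points) nrow(points$positions)
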