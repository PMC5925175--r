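## Batch cutting session: per scalpel pose, update the cut planes, classify
## point elements, extract the surface path, build the Bezier incision,
## regenerate virtual points, run a fixed number of coupled solver steps and
## record the modulated feedback force. Deterministic for a fixed seed.

#' Simulation configuration
#'
#' @param model model source: either `list(type = "box", extent, spacing,
#'   density, surface_segments)`, `list(type = "ellipsoid", semi_axes,
#'   spacing, mesh_resolution, density)`, or `list(mesh_path, points_path)`.
#' @param trajectory non-empty list of scalpel poses, each
#'   `list(tip, handle, vertical, depth)` (vertical defaults to +z).
#' @param material a [material_params]; when NULL a default is derived from
#'   the model spacing (`h = 2.2 * spacing`).
#' @param oscillation an [oscillation_params].
#' @param fit a [force_fit_coeffs].
#' @param samples_per_curve incision samples per Bezier curve.
#' @param per_edge virtual points per incision boundary edge.
#' @param opening_scale incision opening factor.
#' @param steps_per_pose coupled solver steps per scalpel pose.
#' @param seed integer RNG seed; fixed seed implies bit-reproducible runs.
#' @param output_dir optional directory for the exported files.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(model, trajectory, material = NULL,
                       oscillation = oscillation_params(),
                       fit = force_fit_coeffs(),
                       samples_per_curve = 16L, per_edge = 1L,
                       opening_scale = 1, steps_per_pose = 10L,
                       seed = 1L, output_dir = NULL) {
  problems <- character()
  if (!is.list(model)) problems <- c(problems, "model")
  if (!is.list(trajectory) || length(trajectory) == 0L)
    problems <- c(problems, "trajectory")
  if (!is.null(material) && !inherits(material, "material_params"))
    problems <- c(problems, "material")
  if (!inherits(oscillation, "oscillation_params")) problems <- c(problems, "oscillation")
  if (!inherits(fit, "force_fit_coeffs")) problems <- c(problems, "fit")
  if (!is_count(samples_per_curve) || samples_per_curve < 2L)
    problems <- c(problems, "samples_per_curve")
  if (!is_count(per_edge) || per_edge < 1L) problems <- c(problems, "per_edge")
  if (!is_number(opening_scale)) problems <- c(problems, "opening_scale")
  if (!is_count(steps_per_pose) || steps_per_pose < 1L)
    problems <- c(problems, "steps_per_pose")
  if (!is_count(seed)) problems <- c(problems, "seed")
  if (length(problems) > 0L)
    stopf("invalid config field(s): %s", paste(problems, collapse = ", "),
          class = "tissuecut_config_error")
  structure(list(model = model, trajectory = trajectory, material = material,
                 oscillation = oscillation, fit = fit,
                 samples_per_curve = as.integer(samples_per_curve),
                 per_edge = as.integer(per_edge),
                 opening_scale = opening_scale,
                 steps_per_pose = as.integer(steps_per_pose),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields map directly onto the [sim_config] arguments; `material`,
#' `oscillation` and `fit` are given as key-value blocks.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    stopf("config file not found: %s", path, class = "tissuecut_config_error")
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stopf("config is not a mapping", class = "tissuecut_config_error")
  args <- list(model = y$model, trajectory = y$trajectory)
  if (!is.null(y$material)) args$material <- do.call(material_params, y$material)
  if (!is.null(y$oscillation)) args$oscillation <- do.call(oscillation_params, y$oscillation)
  if (!is.null(y$fit)) args$fit <- do.call(force_fit_coeffs, y$fit)
  for (f in c("samples_per_curve", "per_edge", "opening_scale",
              "steps_per_pose", "seed", "output_dir"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(sim_config, args)
}

build_model <- function(model) {
  if (!is.null(model$mesh_path)) {
    list(mesh = read_mesh(model$mesh_path),
         points = read_points(model$points_path),
         spacing = model$spacing %||% NA_real_)
  } else if (identical(model$type, "box")) {
    m <- make_box_model(model$extent, model$spacing,
                        density = model$density %||% 1,
                        surface_segments = model$surface_segments %||% 1L)
    c(m, list(spacing = model$spacing))
  } else if (identical(model$type, "ellipsoid")) {
    m <- make_ellipsoid_model(model$semi_axes, model$spacing,
                              mesh_resolution = model$mesh_resolution %||% 12L,
                              density = model$density %||% 1)
    c(m, list(spacing = model$spacing))
  } else {
    stopf("model must give mesh_path/points_path or type box/ellipsoid",
          class = "tissuecut_config_error")
  }
}

#' Run a cutting session
#'
#' Executes the per-pose pipeline (plane update, classification, path
#' extraction, incision construction, virtual-point regeneration, coupled
#' solver steps, feedback-force record) over the whole scalpel trajectory.
#' Poses with no affected points are no-ops. When `output_dir` is set, the
#' cut mesh (OBJ), point trajectories (CSV), force series (CSV) and a JSON
#' run summary are written there.
#'
#' @param config a [sim_config].
#' @return Object of class `cutting_session`: final `points`, `mesh` (cut
#'   surface), last `curves`, `force_series` and `pose_log` data frames, and
#'   the `config`.
#' @export
run_cutting <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mdl <- build_model(config$model)
  mesh0 <- mdl$mesh
  points <- mdl$points
  params <- config$material
  if (is.null(params)) {
    sp <- mdl$spacing
    if (!is_number(sp)) stopf("material or model spacing must be given",
                              class = "tissuecut_config_error")
    params <- material_params(h = 2.2 * sp)
  }
  time <- 0
  cut_mesh <- mesh0
  curves <- NULL
  last_path <- integer()
  vp <- generate_virtual_points(mesh0, NULL)
  nb <- NULL
  force_rows <- list(); pose_rows <- list()
  for (k in seq_along(config$trajectory)) {
    pose <- config$trajectory[[k]]
    sc <- scalpel(pose$tip, pose$handle, pose$vertical %||% c(0, 0, 1))
    planes <- planes_from_scalpel(sc, pose$depth %||% 0)
    labels <- classify(points, planes)
    points <- apply_labels(points, labels)
    n_aff <- sum(startsWith(labels$label, "affected"))
    path <- extract_cut_path(mesh0, planes)
    if (length(path) >= 2L && !identical(path, last_path)) {
      curves <- build_incision(mesh0, path, config$samples_per_curve)
      cut_mesh <- remesh_incision(mesh0, curves)
      vp <- generate_virtual_points(mesh0, curves, config$per_edge)
      vp <- prescribe_displacements(vp, curves, config$opening_scale)
      nb <- NULL                              # cloud changed
      last_path <- path
    }
    evals <- 0L
    if (n_aff > 0L) {
      if (is.null(nb))
        nb <- build_neighborhoods(coupling_cloud(points, vp), params, quiet = TRUE)
      nb_pose <- sever_cut_pairs(nb, cloud_sides(points, vp))
      for (s in seq_len(config$steps_per_pose)) {
        st <- coupled_step(points, vp, nb_pose, params)
        points <- st$points
        evals <- evals + st$gradient_evals
        time <- time + params$dt
        nr <- n_points(points)
        vrows <- if (n_virtual(vp) > 0L) st$forces[-seq_len(nr), , drop = FALSE]
                 else matrix(0, 0L, 3L)
        raw_vec <- if (nrow(vrows) > 0L) colSums(vrows) else c(0, 0, 0)
        raw_mag <- if (nrow(vrows) > 0L) sum(row_norms(vrows)) else 0
        g <- oscillation(time, pose$depth %||% 0, config$oscillation)
        fb <- feedback_force(raw_vec, g)
        force_rows[[length(force_rows) + 1L]] <- data.frame(
          t = time, depth = pose$depth %||% 0,
          fx = fb[1L], fy = fb[2L], fz = fb[3L],
          fmag = abs(g) * raw_mag, modulated = g * raw_mag, raw = raw_mag)
      }
    } else {
      time <- time + params$dt * config$steps_per_pose
    }
    pose_rows[[length(pose_rows) + 1L]] <- data.frame(
      pose = k, affected = n_aff,
      unaffected = sum(labels$label == "unaffected"),
      path_len = length(path), gradient_evals = evals,
      max_disp = max(row_norms(points$displacements)))
  }
  session <- structure(list(points = points, mesh = cut_mesh, curves = curves,
                            virtual_points = vp,
                            force_series = if (length(force_rows)) do.call(rbind, force_rows)
                                           else data.frame(),
                            pose_log = do.call(rbind, pose_rows),
                            config = config),
                       class = "cutting_session")
  if (!is.null(config$output_dir)) write_session(session, config$output_dir)
  session
}

write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(session$mesh, file.path(dir, "cut_mesh.obj"))
  pts <- session$points
  df <- data.frame(x = pts$positions[, 1L], y = pts$positions[, 2L],
                   z = pts$positions[, 3L],
                   ux = pts$displacements[, 1L], uy = pts$displacements[, 2L],
                   uz = pts$displacements[, 3L], label = pts$labels)
  utils::write.csv(df, file.path(dir, "points.csv"), row.names = FALSE)
  utils::write.csv(session$force_series, file.path(dir, "force_series.csv"),
                   row.names = FALSE)
  summ <- list(poses = nrow(session$pose_log),
               points = n_points(pts),
               affected_final = sum(startsWith(pts$labels, "affected")),
               max_displacement = max(row_norms(pts$displacements)),
               seed = session$config$seed)
  jsonlite::write_json(summ, file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @export
print.cutting_session <- function(x, ...) {
  cat(sprintf("cutting_session: %d poses, %d point elements\n",
              nrow(x$pose_log), n_points(x$points)))
  cat(sprintf("  final affected: %d, max displacement %.4g mm\n",
              sum(startsWith(x$points$labels, "affected")),
              max(row_norms(x$points$displacements))))
  invisible(x)
}

#' @export
summary.cutting_session <- function(object, ...) {
  cat("Per-pose log:\n")
  print(object$pose_log, row.names = FALSE)
  if (nrow(object$force_series) > 0L)
    cat(sprintf("Feedback force: %d samples, peak |modulated| %.4g\n",
                nrow(object$force_series), max(abs(object$force_series$modulated))))
  invisible(object$pose_log)
}
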