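## Plain-text I/O for meshes (OBJ, OFF, ASCII PLY) and point elements
## (CSV with header x,y,z,mass,volume, or bare XYZ). Round trips are exact to
## the printed precision (%.9g, i.e. well under 1e-6 mm for model-scale
## coordinates).

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

#' Read a surface mesh from OBJ, OFF or ASCII PLY
#'
#' @param path file path; format inferred from the extension.
#' @return A [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  switch(file_ext(path),
         obj = read_obj(path),
         off = read_off(path),
         ply = read_ply(path),
         stopf("unknown mesh extension '.%s' (expected obj/off/ply)", file_ext(path),
               class = "tissuecut_format_error"))
}

#' Write a surface mesh to OBJ, OFF or ASCII PLY
#'
#' @param mesh a [surface_mesh].
#' @param path output path; format inferred from the extension.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  fmt <- function(x) sprintf("%.9g", x)
  lines <- switch(file_ext(path),
    obj = c(paste("v", fmt(v[, 1L]), fmt(v[, 2L]), fmt(v[, 3L])),
            paste("f", tr[, 1L], tr[, 2L], tr[, 3L])),
    off = c("OFF",
            paste(nrow(v), nrow(tr), 0L),
            paste(fmt(v[, 1L]), fmt(v[, 2L]), fmt(v[, 3L])),
            paste(3L, tr[, 1L] - 1L, tr[, 2L] - 1L, tr[, 3L] - 1L)),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(v)),
            "property float x", "property float y", "property float z",
            paste("element face", nrow(tr)),
            "property list uchar int vertex_indices", "end_header",
            paste(fmt(v[, 1L]), fmt(v[, 2L]), fmt(v[, 3L])),
            paste(3L, tr[, 1L] - 1L, tr[, 2L] - 1L, tr[, 3L] - 1L)),
    stopf("unknown mesh extension '.%s' (expected obj/off/ply)", file_ext(path),
          class = "tissuecut_format_error"))
  writeLines(lines, path)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vs <- list(); ts <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (tok[1L] == "v") {
      if (length(tok) < 4L) stopf("malformed OBJ vertex at line %d", k,
                                  class = "tissuecut_format_error")
      vs[[length(vs) + 1L]] <- as.numeric(tok[2:4])
    } else if (tok[1L] == "f") {
      if (length(tok) < 4L) stopf("malformed OBJ face at line %d", k,
                                  class = "tissuecut_format_error")
      idx <- as.integer(sub("/.*", "", tok[-1L]))
      if (any(is.na(idx))) stopf("malformed OBJ face at line %d", k,
                                 class = "tissuecut_format_error")
      for (i in seq_len(length(idx) - 2L))  # fan-triangulate polygons
        ts[[length(ts) + 1L]] <- idx[c(1L, i + 1L, i + 2L)]
    }
  }
  surface_mesh(do.call(rbind, vs), do.call(rbind, ts))
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (toupper(lines[1L]) != "OFF") stopf("not an OFF file (line 1)",
                                         class = "tissuecut_format_error")
  hdr <- as.integer(strsplit(lines[2L], "[[:space:]]+")[[1L]])
  nv <- hdr[1L]; nf <- hdr[2L]
  v <- t(vapply(lines[3:(2L + nv)],
                function(s) as.numeric(strsplit(s, "[[:space:]]+")[[1L]][1:3]),
                numeric(3L)))
  ts <- list()
  for (k in seq_len(nf)) {
    tok <- as.integer(strsplit(lines[2L + nv + k], "[[:space:]]+")[[1L]])
    if (any(is.na(tok)) || tok[1L] < 3L)
      stopf("malformed OFF face at line %d", 2L + nv + k,
            class = "tissuecut_format_error")
    idx <- tok[2:(1L + tok[1L])] + 1L
    for (i in seq_len(length(idx) - 2L))
      ts[[length(ts) + 1L]] <- idx[c(1L, i + 1L, i + 2L)]
  }
  surface_mesh(v, do.call(rbind, ts))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (trimws(lines[1L]) != "ply") stopf("not a PLY file (line 1)",
                                        class = "tissuecut_format_error")
  nv <- nf <- NA_integer_; body <- NA_integer_
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (grepl("^format", ln) && !grepl("ascii", ln))
      stopf("only ASCII PLY supported (line %d)", k, class = "tissuecut_format_error")
    if (grepl("^element vertex", ln)) nv <- as.integer(strsplit(ln, " ")[[1L]][3L])
    if (grepl("^element face", ln)) nf <- as.integer(strsplit(ln, " ")[[1L]][3L])
    if (ln == "end_header") { body <- k; break }
  }
  if (is.na(body) || is.na(nv) || is.na(nf))
    stopf("malformed PLY header", class = "tissuecut_format_error")
  v <- t(vapply(lines[(body + 1L):(body + nv)],
                function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1L]][1:3]),
                numeric(3L)))
  ts <- list()
  for (k in seq_len(nf)) {
    tok <- as.integer(strsplit(trimws(lines[body + nv + k]), "[[:space:]]+")[[1L]])
    idx <- tok[2:(1L + tok[1L])] + 1L
    for (i in seq_len(length(idx) - 2L))
      ts[[length(ts) + 1L]] <- idx[c(1L, i + 1L, i + 2L)]
  }
  surface_mesh(v, do.call(rbind, ts))
}

#' Read point elements from CSV or XYZ
#'
#' CSV files need a header with columns `x,y,z,mass,volume`; bare `.xyz`
#' files carry coordinates only (unit mass/volume assigned).
#' @param path file path.
#' @return A [point_element_set].
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- file_ext(path)
  if (ext == "csv") {
    df <- utils::read.csv(path)
    need <- c("x", "y", "z", "mass", "volume")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L)
      stopf("point CSV missing column(s): %s (header line)", paste(miss, collapse = ", "),
            class = "tissuecut_format_error")
    point_element_set(as.matrix(df[, c("x", "y", "z")]),
                      masses = df$mass, volumes = df$volume)
  } else if (ext == "xyz") {
    m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
    point_element_set(m)
  } else {
    stopf("unknown point extension '.%s' (expected csv/xyz)", ext,
          class = "tissuecut_format_error")
  }
}

#' Write point elements to CSV or XYZ
#'
#' @param points a [point_element_set].
#' @param path output path; `.csv` keeps mass and volume, `.xyz` positions only.
#' @return Invisibly, `path`.
#' @export
write_points <- function(points, path) {
  stopifnot(inherits(points, "point_element_set"))
  ext <- file_ext(path)
  p <- points$positions
  if (ext == "csv") {
    df <- data.frame(x = p[, 1L], y = p[, 2L], z = p[, 3L],
                     mass = points$masses, volume = points$volumes)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "xyz") {
    utils::write.table(p, path, row.names = FALSE, col.names = FALSE)
  } else {
    stopf("unknown point extension '.%s' (expected csv/xyz)", ext,
          class = "tissuecut_format_error")
  }
  invisible(path)
}
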