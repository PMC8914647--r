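landmark_vertex <- function(mesh, registry, landmark_index) {
  row <- lookup_landmark(registry, landmark_index)
  vi <- row$vertex_index + 1L  # registry is 0-based
  if (vi > nrow(mesh$vertices))
    stop("landmark '", row$name, "' addresses vertex ", row$vertex_index,
         " but the mesh has only ", nrow(mesh$vertices), " vertices")
  mesh$vertices[vi, ]
}

plane_normal_for <- function(orientation, up_axis, lr_axis) {
  ax <- switch(orientation, horizontal = up_axis, vertical = lr_axis,
               stop("circumference definition needs a plane orientation"))
  n <- c(0, 0, 0)
  n[axis_index(ax)] <- 1
  n
}

#' Extract a single body measurement from a mesh
#'
#' Lengths are the Euclidean distance between the definition's two
#' landmark vertices. Circumferences slice the mesh with a plane through
#' the landmark vertex (normal set by the plane orientation) and sum the
#' segment lengths of the closed intersection loop nearest that landmark.
#'
#' @param mesh an [anthro_mesh()].
#' @param definition one row of [measurement_definitions()] (or any
#'   data.frame with the same columns).
#' @param registry a [landmark_registry()] compatible with the mesh.
#' @param lr_axis the body's left-right axis, used as the normal of
#'   vertical slicing planes.
#' @param convex passed to [slice_circumference()].
#' @return the measurement value in mm.
#' @export
extract_measurement <- function(mesh, definition, registry,
                                lr_axis = "x", convex = FALSE) {
  stopifnot(nrow(definition) == 1L)
  res <- tryCatch({
    if (definition$kind == "length") {
      p1 <- landmark_vertex(mesh, registry, definition$landmark1)
      p2 <- landmark_vertex(mesh, registry, definition$landmark2)
      point_distance(p1, p2)
    } else {
      p <- landmark_vertex(mesh, registry, definition$landmark1)
      n <- plane_normal_for(definition$plane_orientation, mesh$up_axis,
                            lr_axis)
      slice_circumference(mesh, p, n, anchor = p, convex = convex)
    }
  }, error = function(e) {
    stop("measurement ", definition$code, " (", definition$name, "): ",
         conditionMessage(e), call. = FALSE)
  })
  res
}

#' Extract all body measurements from a mesh
#'
#' Runs the full measurement protocol: every definition in the table,
#' plus stature via [mesh_height()] and body volume via [mesh_volume()].
#' Per-measurement failures do not abort the run; the failing codes are
#' reported in a single warning and returned as `NA`.
#'
#' @inheritParams extract_measurement
#' @param definitions a [measurement_definitions()] table.
#' @param include_additional convenience switch: when `definitions` is
#'   missing, selects the 15-standard or 18-measurement canonical set.
#' @param subject_id,sex metadata carried into the result.
#' @param volume compute mesh volume (requires watertightness).
#' @return a list of class `"measurement_vector"` with `subject_id`,
#'   `sex`, `values` (named numeric, mm), `height_cm`, `volume_L`.
#' @export
extract_all <- function(mesh, registry = landmark_registry(),
                        definitions = NULL, include_additional = FALSE,
                        subject_id = "subject", sex = "unspecified",
                        lr_axis = "x", convex = FALSE, volume = TRUE) {
  if (is.null(definitions))
    definitions <- measurement_definitions(include_additional)
  vals <- stats::setNames(rep(NA_real_, nrow(definitions)), definitions$code)
  failed <- character(0)
  for (i in seq_len(nrow(definitions))) {
    v <- tryCatch(
      extract_measurement(mesh, definitions[i, , drop = FALSE], registry,
                          lr_axis = lr_axis, convex = convex),
      error = function(e) { failed <<- c(failed, conditionMessage(e)); NA_real_ })
    vals[i] <- v
  }
  if (length(failed))
    warning("measurement failure(s): ", paste(failed, collapse = "; "))
  structure(list(
    subject_id = subject_id,
    sex = match.arg(sex, c("male", "female", "unspecified")),
    values = vals,
    height_cm = mesh_height(mesh),
    volume_L = if (volume) mesh_volume(mesh) else NA_real_
  ), class = "measurement_vector")
}

#' @export
print.measurement_vector <- function(x, ...) {
  cat(sprintf("measurement_vector '%s' (%s): height %.1f cm, volume %s L\n",
              x$subject_id, x$sex, x$height_cm,
              if (is.na(x$volume_L)) "NA" else sprintf("%.1f", x$volume_L)))
  print(round(x$values, 1))
  invisible(x)
}

#' Write / read measurement vectors as CSV
#'
#' One row per subject; columns `subject_id`, `sex`, `height_cm`,
#' `volume_L`, then one column per measurement code. Missing values are
#' empty cells, never 0 or a sentinel. The pair round-trips losslessly.
#'
#' @param vectors a list of `measurement_vector` objects (or a single one).
#' @param path CSV path.
#' @return `write_measurements()`: `path` invisibly;
#'   `read_measurements()`: a data.frame.
#' @export
write_measurements <- function(vectors, path) {
  if (inherits(vectors, "measurement_vector")) vectors <- list(vectors)
  codes <- unique(unlist(lapply(vectors, function(v) names(v$values))))
  rows <- lapply(vectors, function(v) {
    vals <- stats::setNames(rep(NA_real_, length(codes)), codes)
    vals[names(v$values)] <- v$values
    cbind(data.frame(subject_id = v$subject_id, sex = v$sex,
                     height_cm = v$height_cm, volume_L = v$volume_L,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), sex = character(0),
               height_cm = numeric(0), volume_L = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
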