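#' Canonical SMPL landmark registry
#'
#' The 20 anatomical landmarks used by the measurement protocol, each a
#' fixed vertex index on the SMPL template mesh (6890 vertices). Because
#' the template topology shares vertex semantics across all bodies, a
#' landmark is fully specified by its vertex index. `vertex_index` is a
#' 0-based offset into the vertex array, the convention of the SMPL
#' ecosystem; R code indexing mesh vertices must add 1.
#'
#' @param landmarks optional data.frame with columns `index`, `name`,
#'   `vertex_index` for non-SMPL topologies; defaults to the canonical
#'   SMPL table.
#' @param n_vertices vertex count the registry addresses (6890 for SMPL).
#' @return a data.frame of class `"landmark_registry"`.
#' @export
landmark_registry <- function(landmarks = smpl_landmark_table(),
                              n_vertices = 6890L) {
  stopifnot(all(c("index", "name", "vertex_index") %in% names(landmarks)))
  if (any(landmarks$vertex_index < 0L | landmarks$vertex_index >= n_vertices))
    stop("vertex_index out of range [0, ", n_vertices, ")")
  if (anyDuplicated(landmarks$index)) stop("duplicate landmark indices")
  reg <- as.data.frame(landmarks)
  attr(reg, "n_vertices") <- as.integer(n_vertices)
  class(reg) <- c("landmark_registry", "data.frame")
  reg
}

#' @rdname landmark_registry
#' @export
smpl_landmark_table <- function() {
  data.frame(
    index = 1:20,
    name = c("Inseam point", "Left shoulder", "Right shoulder", "Left chest",
             "Left hip", "Right hip", "Left mid finger", "Right mid finger",
             "Left wrist", "Shoulder top", "Low left hip", "Left ankle",
             "Lower belly point", "Forehead point", "Right forearm point",
             "Right thigh point", "Right calf point", "Right ankle point",
             "Mid hip point", "Right bicep point"),
    vertex_index = c(3149L, 3011L, 6470L, 1423L, 1229L, 4949L, 2445L, 5906L,
                     2241L, 3068L, 3134L, 3334L, 1769L, 335L, 5084L, 4971L,
                     4589L, 6723L, 3145L, 6281L),
    stringsAsFactors = FALSE
  )
}

#' Look up a landmark by name or index
#'
#' @param registry a [landmark_registry()].
#' @param name_or_index a landmark name (case-insensitive) or its 1-20
#'   landmark index.
#' @return a one-row data.frame with `index`, `name`, `vertex_index`.
#' @export
lookup_landmark <- function(registry, name_or_index) {
  stopifnot(inherits(registry, "landmark_registry"))
  if (is.numeric(name_or_index)) {
    hit <- which(registry$index == as.integer(name_or_index))
  } else {
    hit <- which(tolower(registry$name) == tolower(as.character(name_or_index)))
  }
  if (length(hit) != 1L)
    stop("unknown landmark '", name_or_index, "'; valid names: ",
         paste(registry$name, collapse = ", "))
  as.data.frame(registry)[hit, , drop = FALSE]
}

#' Canonical measurement definitions
#'
#' The 15 standard body measurements (codes A-O) plus three additional
#' ones (arm span, inseam height, hip width). Lengths are Euclidean
#' distances between two landmarks; circumferences are plane slices
#' through a single landmark. Default plane orientations are a documented
#' inference, not a published table: horizontal (normal along the up
#' axis) for torso, head, neck and leg girths (A, B, D, E, F, L, M, N)
#' and vertical with normal along the body's left-right axis for the arm
#' girths (G, H, I), since A-pose arms run roughly along that axis. Both
#' are overridable per measurement.
#'
#' @param include_additional include the three extra length measurements.
#' @return a data.frame of class `"measurement_definitions"` with columns
#'   `code`, `name`, `kind`, `landmark1`, `landmark2` (NA for
#'   circumferences), `plane_orientation` (`"horizontal"`, `"vertical"`,
#'   or `"none"`).
#' @export
measurement_definitions <- function(include_additional = FALSE) {
  def <- data.frame(
    code = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
             "M", "N", "O"),
    name = c("Head circumference", "Neck circumference", "Shoulder to crotch",
             "Chest circumference", "Waist circumference", "Hip circumference",
             "Wrist circumference", "Bicep circumference",
             "Forearm circumference", "Arm length", "Inside leg length",
             "Thigh circumference", "Calf circumference", "Ankle circumference",
             "Shoulder breadth"),
    kind = c("circumference", "circumference", "length", "circumference",
             "circumference", "circumference", "circumference",
             "circumference", "circumference", "length", "length",
             "circumference", "circumference", "circumference", "length"),
    landmark1 = c(14L, 10L, 1L, 4L, 13L, 19L, 9L, 20L, 15L, 2L, 11L, 16L,
                  17L, 18L, 2L),
    landmark2 = c(NA, NA, 10L, NA, NA, NA, NA, NA, NA, 9L, 12L, NA, NA, NA,
                  3L),
    plane_orientation = c("horizontal", "horizontal", "none", "horizontal",
                          "horizontal", "horizontal", "vertical", "vertical",
                          "vertical", "none", "none", "horizontal",
                          "horizontal", "horizontal", "none"),
    stringsAsFactors = FALSE
  )
  if (include_additional) {
    def <- rbind(def, data.frame(
      code = c("arm_span", "inseam_height", "hip_width"),
      name = c("Arm span", "Inseam height", "Hip width"),
      kind = "length",
      landmark1 = c(7L, 2L, 5L),
      landmark2 = c(8L, 19L, 6L),
      plane_orientation = "none",
      stringsAsFactors = FALSE
    ))
  }
  bad <- (def$kind == "length") != !is.na(def$landmark2)
  if (any(bad)) stop("inconsistent measurement definition")
  class(def) <- c("measurement_definitions", "data.frame")
  def
}

#' Write or read the registry + definitions as a YAML config
#'
#' The shipped copy under `inst/extdata/smpl_protocol.yaml` mirrors the
#' canonical tables entry for entry; a golden-file test keeps them in
#' sync. User-supplied configs with the same structure support non-SMPL
#' topologies.
#'
#' @param path YAML file path.
#' @param registry a [landmark_registry()].
#' @param definitions a [measurement_definitions()] table (use
#'   `include_additional = TRUE` to ship all 18).
#' @return `write_protocol_config()`: `path` invisibly;
#'   `read_protocol_config()`: a list with `registry` and `definitions`.
#' @export
write_protocol_config <- function(path,
                                  registry = landmark_registry(),
                                  definitions = measurement_definitions(TRUE)) {
  cfg <- list(
    n_vertices = attr(registry, "n_vertices"),
    landmarks = lapply(seq_len(nrow(registry)), function(i) list(
      index = registry$index[i], name = registry$name[i],
      vertex_index = registry$vertex_index[i])),
    measurements = lapply(seq_len(nrow(definitions)), function(i) list(
      code = definitions$code[i], name = definitions$name[i],
      kind = definitions$kind[i],
      landmarks = as.integer(stats::na.omit(
        c(definitions$landmark1[i], definitions$landmark2[i]))),
      plane_orientation = definitions$plane_orientation[i]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  reg <- do.call(rbind, lapply(cfg$landmarks, function(l)
    data.frame(index = as.integer(l$index), name = l$name,
               vertex_index = as.integer(l$vertex_index),
               stringsAsFactors = FALSE)))
  defs <- do.call(rbind, lapply(cfg$measurements, function(m)
    data.frame(code = m$code, name = m$name, kind = m$kind,
               landmark1 = as.integer(m$landmarks[1]),
               landmark2 = if (length(m$landmarks) > 1L)
                 as.integer(m$landmarks[2]) else NA_integer_,
               plane_orientation = m$plane_orientation,
               stringsAsFactors = FALSE)))
  class(defs) <- c("measurement_definitions", "data.frame")
  list(registry = landmark_registry(reg, cfg$n_vertices),
       definitions = defs)
}
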