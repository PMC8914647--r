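#' Triangle mesh constructor
#'
#' A minimal triangle-mesh container: an `n x 3` numeric vertex matrix in
#' metres and an `m x 3` integer face matrix of 1-based vertex indices.
#' Vertex order is preserved exactly as supplied, because landmark lookups
#' address vertices by index.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z), in metres.
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param up_axis which axis is "up" for height and horizontal slicing;
#'   one of `"x"`, `"y"`, `"z"`. Template meshes are y-up by convention.
#' @return an object of class `"anthro_mesh"`.
#' @export
anthro_mesh <- function(vertices, faces, up_axis = "y") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, vertex count]")
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen))
      stop(sum(degen), " degenerate face(s) with repeated vertex indices")
  }
  up_axis <- match.arg(up_axis, c("x", "y", "z"))
  structure(list(vertices = vertices, faces = faces, up_axis = up_axis),
            class = "anthro_mesh")
}

#' @export
print.anthro_mesh <- function(x, ...) {
  cat(sprintf("anthro_mesh: %d vertices, %d faces, up axis '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$up_axis))
  invisible(x)
}

axis_index <- function(up_axis) match(up_axis, c("x", "y", "z"))

#' Read a triangle mesh from OBJ or PLY
#'
#' Reads Wavefront OBJ (ASCII) or PLY (ASCII or binary little-endian)
#' files. Vertex coordinates are taken to be metres and vertex order is
#' preserved exactly as stored in the file. Polygonal OBJ faces with more
#' than three vertices are fan-triangulated with a warning; vertex order
#' is never altered.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"`, or `"auto"` (from the file extension).
#' @inheritParams anthro_mesh
#' @return an [anthro_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply"), up_axis = "y") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply"))
      stop("cannot infer mesh format from extension '", ext, "'")
    format <- ext
  }
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "obj") read_obj(path, up_axis) else read_ply(path, up_axis)
}

read_obj <- function(path, up_axis = "y") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop("OBJ file contains no vertices: ", path)
  verts <- t(vapply(strsplit(sub("^v\\s+", "", vlines), "\\s+"),
                    function(tok) as.numeric(tok[1:3]), numeric(3)))
  if (anyNA(verts)) stop("unparseable vertex line in ", path)
  fan_warned <- FALSE
  faces <- list()
  for (fl in flines) {
    tok <- strsplit(sub("^f\\s+", "", fl), "\\s+")[[1]]
    # a token may be v, v/vt, v//vn or v/vt/vn; keep the vertex index only
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, character(1), 1L))
    if (anyNA(idx)) stop("unparseable face line in ", path)
    idx <- ifelse(idx < 0L, nrow(verts) + idx + 1L, idx)
    if (length(idx) < 3L) stop("face with fewer than 3 vertices in ", path)
    if (length(idx) > 3L && !fan_warned) {
      warning("non-triangular face(s) fan-triangulated in ", path)
      fan_warned <- TRUE
    }
    for (k in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
  }
  fmat <- if (length(faces)) do.call(rbind, faces) else
    matrix(integer(0), 0, 3)
  anthro_mesh(verts, fmat, up_axis)
}

read_ply <- function(path, up_axis = "y") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  repeat {
    ln <- trimws(readLines(con, n = 1L))
    if (length(ln) == 0L) stop("unterminated PLY header in ", path)
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt)) stop("PLY header missing format line")
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  if (!all(c("vertex", "face") %in% names(elements)))
    stop("PLY file must contain vertex and face elements")

  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    nv <- elements$vertex$count
    vprops <- vapply(elements$vertex$props, `[[`, character(1), "name")
    vtok <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    vmat <- t(vapply(vtok, function(s) as.numeric(s), numeric(length(vprops))))
    colnames(vmat) <- vprops
    verts <- vmat[, c("x", "y", "z"), drop = FALSE]
    nf <- elements$face$count
    faces <- lapply(strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+"),
                    function(s) {
                      n <- as.integer(s[1])
                      as.integer(s[1 + seq_len(n)]) + 1L
                    })
  } else {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    read_scalar <- function(type) {
      sz <- sizes[[type]]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(con, "double", 1L, size = sz, endian = "little")
      else
        readBin(con, "integer", 1L, size = sz, endian = "little",
                signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    nv <- elements$vertex$count
    vprops <- elements$vertex$props
    vmat <- matrix(NA_real_, nv, length(vprops))
    colnames(vmat) <- vapply(vprops, `[[`, character(1), "name")
    for (i in seq_len(nv))
      for (j in seq_along(vprops))
        vmat[i, j] <- read_scalar(vprops[[j]]$type)
    verts <- vmat[, c("x", "y", "z"), drop = FALSE]
    nf <- elements$face$count
    fprop <- Filter(function(p) p$list, elements$face$props)[[1]]
    faces <- vector("list", nf)
    for (i in seq_len(nf)) {
      n <- read_scalar(fprop$count_type)
      faces[[i]] <- vapply(seq_len(n), function(k)
        read_scalar(fprop$type), numeric(1)) + 1L
    }
  }
  tri <- list()
  for (idx in faces)
    for (k in seq_len(length(idx) - 2L))
      tri[[length(tri) + 1L]] <- as.integer(c(idx[1L], idx[k + 1L], idx[k + 2L]))
  anthro_mesh(verts, do.call(rbind, tri), up_axis)
}

#' Write a mesh as Wavefront OBJ
#'
#' Vertex order is written exactly as stored, so landmark indices survive a
#' write/read round trip. Coordinates are printed with 9 significant
#' decimals (sub-micrometre at human scale).
#'
#' @param mesh an [anthro_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "anthro_mesh"))
  v <- sprintf("v %.9f %.9f %.9f",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d",
               mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c("# anthrofit mesh", v, f), path)
  invisible(path)
}
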