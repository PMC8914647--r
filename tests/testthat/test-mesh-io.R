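test_that("OBJ write/read round-trips vertices, faces and order", {
  m <- prism_mesh("y", c(0, 0.5), 0.1, 16L)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, path)
  m2 <- read_mesh(path)
  expect_identical(m2$faces, m$faces)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
})

test_that("OBJ reader parses a unit cube and preserves vertex order", {
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(cube_mesh(), path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)
  expect_equal(m$vertices, cube_mesh()$vertices, tolerance = 1e-9)
})

test_that("quad OBJ faces are fan-triangulated with a warning", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"),
             path)
  expect_warning(m <- read_mesh(path), "fan-triangulated")
  expect_equal(nrow(m$faces), 2L)
  expect_equal(m$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
})

test_that("OBJ reader handles v/vt/vn face tokens and comments", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("# comment", "v 0 0 0", "v 1 0 0", "v 0 1 0",
               "f 1/1/1 2/2/2 3/3/3"), path)
  m <- read_mesh(path)
  expect_equal(m$faces, rbind(c(1L, 2L, 3L)))
})

test_that("ASCII and binary PLY read back the same mesh", {
  m <- prism_mesh("y", c(0, 0.3), 0.08, 8L)
  ascii <- withr::local_tempfile(fileext = ".ply")
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(m$vertices)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(m$faces)),
              "property list uchar int vertex_indices", "end_header")
  vtx <- apply(m$vertices, 1, function(p) paste(p, collapse = " "))
  fcs <- apply(m$faces - 1L, 1, function(f) paste(c(3, f), collapse = " "))
  writeLines(c(header, vtx, fcs), ascii)
  ma <- read_mesh(ascii)
  expect_equal(ma$vertices, unname(m$vertices), tolerance = 1e-9)
  expect_identical(ma$faces, m$faces)

  bin <- withr::local_tempfile(fileext = ".ply")
  con <- file(bin, "wb")
  writeLines(sub("ascii", "binary_little_endian", header), con)
  for (i in seq_len(nrow(m$vertices)))
    writeBin(as.double(m$vertices[i, ]), con, size = 8, endian = "little")
  # header above says float; rewrite for double properties
  close(con)
  con <- file(bin, "wb")
  header_d <- gsub("float", "double", header)
  header_d[2] <- "format binary_little_endian 1.0"
  writeLines(header_d, con)
  for (i in seq_len(nrow(m$vertices)))
    writeBin(as.double(m$vertices[i, ]), con, size = 8, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
  close(con)
  mb <- read_mesh(bin)
  expect_equal(mb$vertices, unname(m$vertices), tolerance = 1e-12)
  expect_identical(mb$faces, m$faces)
})

test_that("mesh constructor rejects malformed input", {
  expect_error(anthro_mesh(matrix(0, 3, 3), rbind(c(1, 2, 4))), "out of range")
  expect_error(anthro_mesh(matrix(0, 3, 3), rbind(c(1, 2, 2))), "degenerate")
  expect_error(read_mesh(tempfile(fileext = ".obj")), "not found")
})
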