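fx <- make_fixture_body()

test_that("fixture measurements match their closed-form truths", {
  mv <- extract_all(fx$mesh, fx$registry, include_additional = TRUE)
  expect_named(mv$values, names(fx$truth$values))
  for (cd in names(fx$truth$values))
    expect_equal(mv$values[[cd]], fx$truth$values[[cd]],
                 tolerance = 1e-6, label = paste("code", cd))
  expect_equal(mv$height_cm, 175)
  expect_equal(mv$volume_L, fx$truth$volume_L, tolerance = 1e-9)
})

test_that("extract_all returns 15 standard or 18 total measurements", {
  m15 <- extract_all(fx$mesh, fx$registry, include_additional = FALSE,
                     volume = FALSE)
  m18 <- extract_all(fx$mesh, fx$registry, include_additional = TRUE,
                     volume = FALSE)
  expect_length(m15$values, 15L)
  expect_length(m18$values, 18L)
  expect_setequal(names(m15$values), LETTERS[1:15])
})

test_that("empty definitions yield height and volume only", {
  defs <- measurement_definitions()[0, ]
  mv <- extract_all(fx$mesh, fx$registry, definitions = defs)
  expect_length(mv$values, 0L)
  expect_equal(mv$height_cm, 175)
  expect_gt(mv$volume_L, 0)
})

test_that("a length defined on a single repeated landmark is zero", {
  defs <- measurement_definitions()
  d <- defs[defs$code == "O", ]
  d$landmark2 <- d$landmark1
  expect_equal(extract_measurement(fx$mesh, d, fx$registry), 0)
})

test_that("extraction is deterministic and scales linearly with the mesh", {
  a <- extract_all(fx$mesh, fx$registry, include_additional = TRUE)
  b <- extract_all(fx$mesh, fx$registry, include_additional = TRUE)
  expect_identical(a$values, b$values)
  s <- 1.17
  scaled <- anthro_mesh(fx$mesh$vertices * s, fx$mesh$faces,
                        fx$mesh$up_axis)
  mv_s <- extract_all(scaled, fx$registry, include_additional = TRUE)
  expect_equal(mv_s$values, a$values * s, tolerance = 1e-9)
  expect_equal(mv_s$height_cm, a$height_cm * s, tolerance = 1e-9)
  expect_equal(mv_s$volume_L, a$volume_L * s^3, tolerance = 1e-9)
})

test_that("per-measurement failures are annotated with the code", {
  nv <- nrow(fx$mesh$vertices)
  bad_reg <- landmark_registry(
    within(as.data.frame(fx$registry), vertex_index[index == 14] <- nv),
    n_vertices = nv + 1L)  # addresses a vertex the mesh does not have
  defs <- measurement_definitions()
  expect_error(
    extract_measurement(fx$mesh, defs[defs$code == "A", ], bad_reg),
    "measurement A")
})

test_that("measurement CSV round-trips values and missing cells", {
  mv1 <- extract_all(fx$mesh, fx$registry, subject_id = "s1", sex = "male")
  mv2 <- mv1; mv2$subject_id <- "s2"; mv2$values[["E"]] <- NA_real_
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(list(mv1, mv2), path)
  df <- read_measurements(path)
  expect_equal(nrow(df), 2L)
  expect_equal(df$A, rep(mv1$values[["A"]], 2), tolerance = 1e-9)
  expect_true(is.na(df$E[2]))
  expect_equal(df$E[1], mv1$values[["E"]], tolerance = 1e-9)
  # empty input writes a header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(list(), path2)
  expect_equal(nrow(read_measurements(path2)), 0L)
})
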