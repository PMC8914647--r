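test_that("humanoid fixture is watertight and matches its closed forms", {
  fx <- make_fixture_body()
  wt <- mesh_watertight(fx$mesh)
  expect_true(wt$watertight)
  expect_true(wt$consistent_winding)
  expect_equal(mesh_height(fx$mesh), 175)
  expect_equal(mesh_volume(fx$mesh), fx$truth$volume_L, tolerance = 1e-9)
  # spec'd examples: waist ring and shoulder breadth by construction
  expect_equal(fx$truth$values[["E"]], ngon_perimeter(64, 0.14) * 1000)
  expect_equal(fx$truth$values[["O"]], 400)
})

test_that("fixture stature scales geometry linearly and volume cubically", {
  base <- make_fixture_body(fixture_body_spec(stature = 1.75))
  tall <- make_fixture_body(fixture_body_spec(stature = 1.90))
  s <- 1.90 / 1.75
  expect_equal(mesh_height(tall$mesh), 190)
  expect_equal(tall$truth$values, base$truth$values * s, tolerance = 1e-9)
  expect_equal(tall$truth$volume_L, base$truth$volume_L * s^3,
               tolerance = 1e-9)
})

test_that("self-intersecting parameter combinations are rejected", {
  expect_error(fixture_body_spec(r_leg = 0.12), "legs")
  expect_error(fixture_body_spec(r_arm = 0.12), "chest")
  expect_error(fixture_body_spec(n = 63), "even")
})

test_that("circumference truth converges O(1/n^2) while lengths are exact", {
  per <- function(n) ngon_perimeter(n, 0.1)
  smooth <- 2 * pi * 0.1
  err <- smooth - c(per(32), per(64), per(128))
  expect_equal(err[1] / err[2], 4, tolerance = 0.01)
  expect_equal(err[2] / err[3], 4, tolerance = 0.01)
  lo <- make_fixture_body(fixture_body_spec(n = 16))
  hi <- make_fixture_body(fixture_body_spec(n = 64))
  expect_equal(lo$truth$values[["O"]], hi$truth$values[["O"]])
  expect_equal(lo$truth$values[["K"]], hi$truth$values[["K"]])
})

test_that("population generation is seed-deterministic", {
  s <- population_spec(n = 100, seed = 2021)
  expect_identical(make_population(s), make_population(s))
  other <- make_population(population_spec(n = 100, seed = 2022))
  expect_false(identical(make_population(s)$height_cm, other$height_cm))
})

test_that("noiseless populations are recovered exactly by the fit", {
  pop <- make_population(population_spec(n = 200, seed = 6, noise_sd = 0))
  fit <- anthro_fit(pop)
  truth <- attr(pop, "true_coefficients")
  expect_equal(coef(fit, "male"), truth, tolerance = 1e-8)
  expect_equal(coef(fit, "female"), truth, tolerance = 1e-8)
})

test_that("heights respect the plausibility windows", {
  pop <- make_population(population_spec(n = 2000, seed = 44))
  m <- pop$height_cm[pop$sex == "male"]
  f <- pop$height_cm[pop$sex == "female"]
  expect_true(all(m >= 145 & m <= 196))
  expect_true(all(f >= 135 & f <= 190))
})

test_that("undersized populations are refused for fitting specs", {
  expect_error(population_spec(n = 3), "smaller than")
})

test_that("held-out MRE stays below 5% at default noise levels", {
  pop <- make_population(population_spec(n = 1000, seed = 55))
  test_idx <- seq(1, nrow(pop), by = 5)
  fit <- anthro_fit(pop[-test_idx, ])
  pred <- predict(fit, pop[test_idx, ])
  rep <- evaluate_measurements(pred, pop[test_idx, ])
  expect_true(all(rep$per_measurement$mre_pct < 5))
})

test_that("fixture suite regenerates deterministically and self-consistently", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixture_suite(d1, statures = 1.75)
  make_fixture_suite(d2, statures = 1.75)
  for (f in basename(f1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6),
                     label = paste("bytes of", f))
  }
  # every suite mesh is watertight; humanoid truths reproduce end to end
  for (obj in list.files(d1, pattern = "\\.obj$", full.names = TRUE)) {
    m <- suppressWarnings(read_mesh(obj))
    expect_true(mesh_watertight(m)$watertight, label = obj)
  }
  cfg <- read_protocol_config(file.path(d1, "humanoid_registry.yaml"))
  hum <- read_mesh(file.path(d1, "humanoid_175.obj"))
  truth <- read_measurements(file.path(d1, "truth.csv"))
  mv <- extract_all(hum, cfg$registry, include_additional = TRUE)
  for (cd in LETTERS[1:15])
    expect_equal(mv$values[[cd]], truth[[cd]][1], tolerance = 1e-6,
                 label = paste("suite truth", cd))
})
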