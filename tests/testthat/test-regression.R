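test_that("design matrix has a column of ones and documented term units", {
  X0 <- build_design_matrix(180, 81, design_spec(0))
  expect_equal(unname(X0[1, ]), c(1, 180, 81))
  X2 <- build_design_matrix(180, 81, design_spec(2))
  expect_equal(unname(X2[1, ]), c(1, 180, 81, 81 / 1.80^2, 81 / 1.80))
  X4 <- build_design_matrix(180, 81, design_spec(4))
  expect_equal(unname(X4[1, ]), c(1, 180, 81, 25, 45, 6561, 3.24))
  expect_equal(colnames(X4),
               c("intercept", "h", "w", "bmi", "w_over_h", "w_sq", "h_sq"))
  expect_error(design_spec(3), "0, 2 or 4")
  expect_error(build_design_matrix(c(-1, 170), c(70, 70)), "non-positive")
})

test_that("noiseless linear data is recovered exactly", {
  set.seed(42)
  h <- runif(10, 150, 200); w <- runif(10, 50, 110)
  X <- build_design_matrix(h, w)
  y <- 2 + 0.5 * h + 0.3 * w
  expect_equal(unname(fit_ols(X, y)), c(2, 0.5, 0.3), tolerance = 1e-10)
})

test_that("fit_ols matches the pseudoinverse normal-equations oracle", {
  skip_if_not_installed("MASS")
  set.seed(2021)
  for (rep in 1:100) {
    X <- cbind(1, matrix(rnorm(50 * 4), 50, 4))
    colnames(X) <- c("intercept", paste0("x", 1:4))
    y <- rnorm(50)
    expect_equal(unname(fit_ols(X, y)), ols_pinv_oracle(X, y),
                 tolerance = 1e-8)
  }
})

test_that("rank deficiency is reported with the collinear column named", {
  h <- runif(20, 150, 200); w <- runif(20, 50, 100)
  X <- build_design_matrix(h, w)
  X2 <- cbind(X, h_dup = X[, "h"])
  expect_error(fit_ols(X2, rnorm(20)), "collinear.*h_dup")
  expect_error(fit_ols(X[1:3, ], rnorm(3)), "more observations")
})

test_that("fit_ols is invariant to row permutation", {
  set.seed(8)
  X <- cbind(1, matrix(rnorm(120), 40, 3)); y <- rnorm(40)
  perm <- sample(40)
  expect_equal(unname(fit_ols(X, y)), unname(fit_ols(X[perm, ], y[perm])),
               tolerance = 1e-10)
})

test_that("per-sex fits recover an identical generating model for both sexes", {
  pop <- make_population(population_spec(n = 1500, seed = 31))
  fit <- anthro_fit(pop)
  truth <- attr(pop, "true_coefficients")
  for (sx in c("male", "female")) {
    co <- coef(fit, sx)
    se <- vapply(fit$models[[sx]]$diagnostics, `[[`,
                 numeric(length(fit$spec$terms)), "std_errors")
    expect_true(all(abs(co - truth) <= 3.5 * se),
                label = paste(sx, "coefficients near truth"))
  }
  # and the two sex models agree within joint uncertainty
  expect_lt(max(abs(coef(fit, "male") - coef(fit, "female")) /
                  truth["intercept", "A"]), 1)
})

test_that("a single-sex table yields only that model, with a warning", {
  pop <- make_population(population_spec(n = 300, seed = 5))
  males <- pop[pop$sex == "male", ]
  expect_warning(fit <- anthro_fit(males), "female.*skipped")
  expect_named(fit$models, "male")
  expect_equal(ncol(coef(fit, "male")), 15L)
})

test_that("prediction satisfies exact-fit, centroid, and affine properties", {
  set.seed(9)
  n <- 60
  pop <- data.frame(sex = "male",
                    height_cm = runif(n, 150, 200),
                    weight_kg = runif(n, 50, 110))
  pop$E <- 3 + 2 * pop$height_cm + 4 * pop$weight_kg  # noiseless
  fit <- suppressWarnings(anthro_fit(pop, measurements = "E"))
  pr <- predict(fit, pop)
  expect_equal(pr$E, pop$E, tolerance = 1e-8)
  # centroid property with noisy data
  pop$E <- pop$E + rnorm(n, 0, 5)
  fit2 <- suppressWarnings(anthro_fit(pop, measurements = "E"))
  centroid <- data.frame(sex = "male", height_cm = mean(pop$height_cm),
                         weight_kg = mean(pop$weight_kg))
  expect_equal(predict(fit2, centroid)$E, mean(pop$E), tolerance = 1e-8)
  # shifting the response shifts only the intercept
  pop3 <- pop; pop3$E <- pop$E + 100
  fit3 <- suppressWarnings(anthro_fit(pop3, measurements = "E"))
  expect_equal(coef(fit3, "male")["intercept", "E"],
               coef(fit2, "male")["intercept", "E"] + 100, tolerance = 1e-8)
  expect_equal(coef(fit3, "male")[-1, "E"], coef(fit2, "male")[-1, "E"],
               tolerance = 1e-8)
  expect_equal(predict(fit3, pop)$E, predict(fit2, pop)$E + 100,
               tolerance = 1e-8)
})

test_that("model JSON serialisation round-trips predictions", {
  pop <- make_population(population_spec(n = 200, seed = 13))
  fit <- anthro_fit(pop, interactions = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  fit2 <- read_model(path)
  nd <- data.frame(sex = c("male", "female"), height_cm = c(180, 165),
                   weight_kg = c(80, 60))
  expect_equal(predict(fit2, nd), predict(fit, nd), tolerance = 1e-12)
})

test_that("simulate() reproduces the fitted noise level", {
  pop <- make_population(population_spec(n = 1000, seed = 17))
  fit <- anthro_fit(pop)
  sim <- simulate(fit, nsim = 1, seed = 1)
  base <- predict(fit, sim[, c("sex", "height_cm", "weight_kg")])
  resid_sd <- sd(sim$E - base$E)
  expect_equal(resid_sd, fit$models$male$diagnostics$E$sigma,
               tolerance = 0.1)
})
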