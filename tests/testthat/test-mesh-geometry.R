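test_that("cube volume, height and mid-plane slice match closed forms", {
  cb <- cube_mesh()
  expect_equal(mesh_volume(cb), 1000)
  expect_equal(mesh_height(cb), 100)
  expect_equal(slice_circumference(cb, c(0.5, 0.5, 0.5), c(0, 1, 0),
                                   anchor = c(0, 0.5, 0.5)), 4000)
})

test_that("volume and height are translation invariant", {
  cb <- cube_mesh()
  moved <- translate_mesh(cb, c(5, 5, 5))
  expect_equal(mesh_volume(moved), 1000)
  expect_equal(mesh_height(moved), 100)
})

test_that("icosphere-like prism volume approximates the smooth solid", {
  # high-resolution prism converges to the cylinder volume as O(1/n^2)
  r <- 0.2; h <- 0.4
  v64 <- mesh_volume(prism_mesh("y", c(0, h), r, 64L))
  expect_equal(v64, ngon_area(64, r) * h * 1000, tolerance = 1e-12)
  expect_lt(abs(v64 - pi * r^2 * h * 1000) / (pi * r^2 * h * 1000), 0.005)
})

test_that("64-gon prism cross-section equals the polygon perimeter", {
  pr <- prism_mesh("y", c(0, 0.5), 0.1, 64L)
  got <- slice_circumference(pr, c(0, 0.25, 0), c(0, 1, 0),
                             anchor = c(0.1, 0.25, 0))
  expect_equal(got, ngon_perimeter(64, 0.1) * 1000, tolerance = 1e-9)
})

test_that("slicing exactly at a vertex ring is handled (degenerate plane)", {
  pr <- prism_mesh("y", c(0, 0.2, 0.5), 0.1, 64L)
  got <- slice_circumference(pr, c(0, 0.2, 0), c(0, 1, 0),
                             anchor = c(0.1, 0.2, 0))
  expect_equal(got, ngon_perimeter(64, 0.1) * 1000, tolerance = 1e-9)
})

test_that("volume and slice are invariant under rigid motion", {
  pr <- prism_mesh("y", c(0, 0.5), 0.1, 64L)
  ref_v <- mesh_volume(pr)
  ref_c <- slice_circumference(pr, c(0, 0.25, 0), c(0, 1, 0),
                               c(0.1, 0.25, 0))
  for (ang in c(0.3, 1.2)) {
    m <- translate_mesh(rotate_about_y(pr, ang), c(1, -2, 3))
    expect_equal(mesh_volume(m), ref_v, tolerance = 1e-6)
    anchor <- c(1 + 0.1 * cos(ang), -2 + 0.25, 3 - 0.1 * sin(ang))
    got <- slice_circumference(m, c(1, -1.75, 3), c(0, 1, 0), anchor)
    expect_equal(got, ref_c, tolerance = 1e-6 * ref_c)
  }
})

test_that("anchor selects the correct loop in a multi-part slice", {
  two <- fixture_two_prisms()
  plane <- c(0, 0.25, 0)
  big <- slice_circumference(two, plane, c(0, 1, 0),
                             anchor = c(0.5 + 0.1, 0.25, 0))
  small <- slice_circumference(two, plane, c(0, 1, 0),
                               anchor = c(-0.5 + 0.05, 0.25, 0))
  expect_equal(big, ngon_perimeter(32, 0.1) * 1000, tolerance = 1e-9)
  expect_equal(small, ngon_perimeter(32, 0.05) * 1000, tolerance = 1e-9)
})

test_that("disjoint-union volume is the sum of component volumes", {
  two <- fixture_two_prisms()
  expect_equal(mesh_volume(two),
               (ngon_area(32, 0.1) + ngon_area(32, 0.05)) * 0.5 * 1000,
               tolerance = 1e-12)
})

test_that("convex slice equals raw slice on a convex cross-section", {
  pr <- prism_mesh("y", c(0, 0.5), 0.1, 32L)
  raw <- slice_circumference(pr, c(0, 0.25, 0), c(0, 1, 0), c(0.1, 0.25, 0))
  cvx <- slice_circumference(pr, c(0, 0.25, 0), c(0, 1, 0), c(0.1, 0.25, 0),
                             convex = TRUE)
  expect_equal(cvx, raw, tolerance = 1e-9)
})

test_that("non-watertight meshes are refused for volume with open-edge count", {
  cb <- cube_mesh()
  holed <- anthro_mesh(cb$vertices, cb$faces[-1, ])
  expect_error(mesh_volume(holed), "not watertight.*3 edge")
  expect_false(mesh_watertight(holed)$watertight)
})

test_that("a plane missing the mesh is an error", {
  expect_error(slice_mesh(cube_mesh(), c(0, 5, 0), c(0, 1, 0)),
               "does not intersect")
})

test_that("point_distance is a symmetric Euclidean norm in mm", {
  expect_equal(point_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(point_distance(c(0, 0, 0), c(0.3, 0.4, 0)), 500)
  set.seed(11)
  for (i in 1:5) {
    p <- rnorm(3); q <- rnorm(3)
    expect_equal(point_distance(p, q), point_distance(q, p))
  }
})
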