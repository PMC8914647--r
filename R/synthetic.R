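#' Primitive fixture meshes with closed-form geometry
#'
#' `cube_mesh()` builds an axis-aligned cube; `prism_mesh()` builds a
#' capped right prism over a regular n-gon, optionally with extra vertex
#' rings at interior positions along its axis. Prisms are the workhorse
#' of the synthetic fixtures because their cross-section perimeter
#' \eqn{2 n r \sin(\pi/n)}, area \eqn{\tfrac{1}{2} n r^2 \sin(2\pi/n)}
#' and volume are exact closed forms, unlike a smooth cylinder's. All
#' primitives are watertight and consistently outward-wound.
#'
#' @param edge cube edge length, metres.
#' @param origin cube corner (minimum coordinates).
#' @param axis prism axis, `"x"`, `"y"` or `"z"`.
#' @param positions increasing axis coordinates of the vertex rings
#'   (first and last are the capped ends), metres.
#' @param radius circumradius of the polygon cross-section, metres.
#' @param n polygon resolution (number of cross-section vertices).
#' @param center 3-vector; the two off-axis components locate the prism
#'   axis (the axis component is ignored).
#' @inheritParams anthro_mesh
#' @return an [anthro_mesh()]. For `prism_mesh()` the attribute
#'   `"ring_index"` is a function(ring, k) giving the vertex index of
#'   polygon vertex k on ring `ring`, and `"cap_centers"` the indices of
#'   the two cap-centre vertices (low end first).
#' @export
cube_mesh <- function(edge = 1, origin = c(0, 0, 0), up_axis = "y") {
  o <- as.numeric(origin); e <- edge
  v <- rbind(o + c(0, 0, 0), o + c(e, 0, 0), o + c(e, e, 0), o + c(0, e, 0),
             o + c(0, 0, e), o + c(e, 0, e), o + c(e, e, e), o + c(0, e, e))
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(3, 4, 8), c(3, 8, 7),
             c(1, 5, 8), c(1, 8, 4), c(2, 3, 7), c(2, 7, 6))
  anthro_mesh(v, f, up_axis)
}

#' @rdname cube_mesh
#' @export
prism_mesh <- function(axis = "y", positions = c(0, 1), radius = 0.1,
                       n = 64L, center = c(0, 0, 0), up_axis = "y") {
  stopifnot(length(positions) >= 2L, all(diff(positions) > 0), radius > 0,
            n >= 3L)
  # right-handed in-plane basis (e1, e2) with e1 x e2 = axis direction
  basis <- switch(axis,
    x = list(ea = c(1, 0, 0), e1 = c(0, 1, 0), e2 = c(0, 0, 1)),
    y = list(ea = c(0, 1, 0), e1 = c(0, 0, 1), e2 = c(1, 0, 0)),
    z = list(ea = c(0, 0, 1), e1 = c(1, 0, 0), e2 = c(0, 1, 0)))
  cvec <- as.numeric(center)
  cvec[axis_index(axis)] <- 0
  theta <- 2 * pi * (seq_len(n) - 1) / n
  ring <- outer(cos(theta), basis$e1) + outer(sin(theta), basis$e2)
  R <- length(positions)
  verts <- do.call(rbind, lapply(positions, function(s)
    matrix(cvec, n, 3, byrow = TRUE) + radius * ring +
      outer(rep(s, n), basis$ea)))
  cap_lo <- cvec + positions[1] * basis$ea
  cap_hi <- cvec + positions[R] * basis$ea
  verts <- rbind(verts, cap_lo, cap_hi)
  vid <- function(r, k) (r - 1L) * n + ((k - 1L) %% n) + 1L
  faces <- list()
  for (r in seq_len(R - 1L)) for (k in seq_len(n)) {
    a <- vid(r, k); b <- vid(r, k + 1L)
    c2 <- vid(r + 1L, k + 1L); d <- vid(r + 1L, k)
    faces[[length(faces) + 1L]] <- c(a, b, c2)
    faces[[length(faces) + 1L]] <- c(a, c2, d)
  }
  ic_lo <- R * n + 1L; ic_hi <- R * n + 2L
  for (k in seq_len(n)) {
    faces[[length(faces) + 1L]] <- c(ic_lo, vid(1L, k + 1L), vid(1L, k))
    faces[[length(faces) + 1L]] <- c(ic_hi, vid(R, k), vid(R, k + 1L))
  }
  m <- anthro_mesh(verts, do.call(rbind, faces), up_axis)
  attr(m, "ring_index") <- vid
  attr(m, "cap_centers") <- c(ic_lo, ic_hi)
  m
}

#' Closed-form regular-polygon quantities
#'
#' Perimeter \eqn{2 n r \sin(\pi/n)} and area
#' \eqn{\tfrac{1}{2} n r^2 \sin(2\pi/n)} of a regular n-gon of
#' circumradius r — the exact ground truths of the prism fixtures.
#'
#' @param n polygon resolution.
#' @param radius circumradius, metres.
#' @return metres (perimeter) or square metres (area).
#' @export
ngon_perimeter <- function(n, radius) 2 * n * radius * sin(pi / n)

#' @rdname ngon_perimeter
#' @export
ngon_area <- function(n, radius) 0.5 * n * radius^2 * sin(2 * pi / n)

merge_meshes <- function(meshes, up_axis = "y") {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                              integer(1))))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  faces <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$faces + offs[i]))
  list(mesh = anthro_mesh(verts, faces, up_axis), offsets = offs)
}

#' Specification of the procedural humanoid fixture
#'
#' A synthetic stand-in for a template body mesh: a disjoint union of
#' capped regular-polygon prisms (two legs, torso, neck, head, two
#' horizontal arms in an exaggerated A-pose), with vertex rings placed
#' exactly at every slicing height so that all 18 protocol measurements
#' have closed-form ground truth. Radii are constrained so no two
#' primitives intersect and no slicing plane crosses an unintended part
#' except the contralateral limb (which exercises the anchor-nearest
#' loop rule).
#'
#' @param stature total height, metres; the whole body is scaled
#'   uniformly by `stature / 1.75` from the reference proportions.
#' @param n polygon resolution (even, so diametrically opposite vertices
#'   exist for width measurements).
#' @param r_torso,r_leg,r_arm,r_neck,r_head component circumradii at
#'   reference stature, metres.
#' @return a list of class `"fixture_body_spec"`.
#' @export
fixture_body_spec <- function(stature = 1.75, n = 64L, r_torso = 0.14,
                              r_leg = 0.07, r_arm = 0.04, r_neck = 0.06,
                              r_head = 0.10) {
  n <- as.integer(n)
  if (n < 8L || n %% 2L != 0L) stop("n must be an even integer >= 8")
  if (r_leg >= 0.10) stop("r_leg >= 0.10 m: legs would intersect")
  if (r_torso >= 0.20) stop("r_torso >= 0.20 m: torso would reach the arms")
  if (r_arm >= 0.10)
    stop("r_arm >= 0.10 m: arms would cross the chest slicing plane")
  if (r_neck <= 0 || r_head <= 0 || stature <= 0) stop("invalid dimensions")
  structure(list(stature = stature, n = n, r_torso = r_torso,
                 r_leg = r_leg, r_arm = r_arm, r_neck = r_neck,
                 r_head = r_head),
            class = "fixture_body_spec")
}

#' Build the humanoid fixture with closed-form ground truth
#'
#' @param spec a [fixture_body_spec()].
#' @return a list: `mesh` (an [anthro_mesh()]), `truth` (a
#'   `measurement_vector` of the 18 closed-form values, mm, plus exact
#'   height and summed-primitive volume), `registry` (a
#'   [landmark_registry()] mapping the 20 landmark roles onto generated
#'   vertices, 0-based as in the canonical registry).
#' @export
make_fixture_body <- function(spec = fixture_body_spec()) {
  stopifnot(inherits(spec, "fixture_body_spec"))
  s <- spec$stature / 1.75
  n <- spec$n
  rT <- spec$r_torso * s; rL <- spec$r_leg * s; rA <- spec$r_arm * s
  rN <- spec$r_neck * s; rH <- spec$r_head * s
  y <- function(v) v * s  # reference heights scale with stature

  legs_y <- y(c(0, 0.10, 0.35, 0.60, 0.84))
  torso_y <- y(c(0.85, 0.90, 0.95, 1.00, 1.30, 1.45))
  neck_y <- y(c(1.46, 1.50, 1.55))
  head_y <- y(c(1.56, 1.65, 1.75))
  armL_x <- y(c(0.20, 0.80, 0.85))
  armR_x <- y(c(-0.85, -0.60, -0.30, -0.20))

  comp <- list(
    leg_l = prism_mesh("y", legs_y, rL, n, center = c(y(0.10), 0, 0)),
    leg_r = prism_mesh("y", legs_y, rL, n, center = c(-y(0.10), 0, 0)),
    torso = prism_mesh("y", torso_y, rT, n),
    neck = prism_mesh("y", neck_y, rN, n),
    head = prism_mesh("y", head_y, rH, n),
    arm_l = prism_mesh("x", armL_x, rA, n, center = c(0, y(1.40), 0)),
    arm_r = prism_mesh("x", armR_x, rA, n, center = c(0, y(1.40), 0))
  )
  mg <- merge_meshes(comp)
  off <- stats::setNames(mg$offsets[seq_along(comp)], names(comp))
  gvid <- function(part, ring, k = 1L) {
    off[[part]] + attr(comp[[part]], "ring_index")(ring, k)
  }
  gcap <- function(part, which) off[[part]] + attr(comp[[part]],
                                                   "cap_centers")[which]
  kq <- n / 4L + 1L   # polygon vertex a quarter turn round (+x for y-prisms)
  k3q <- 3L * n / 4L + 1L

  # 1-based vertex indices of the 20 landmark roles on the generated mesh
  lm <- c(
    gcap("torso", 1L),            # 1  inseam point: torso bottom centre
    gcap("arm_l", 1L),            # 2  left shoulder: inner arm cap
    gcap("arm_r", 2L),            # 3  right shoulder: inner arm cap
    gvid("torso", 5L, kq),        # 4  left chest (y = 1.30)
    gvid("torso", 3L, kq),        # 5  left hip (y = 0.95)
    gvid("torso", 3L, k3q),       # 6  right hip
    gcap("arm_l", 2L),            # 7  left mid finger: outer arm cap
    gcap("arm_r", 1L),            # 8  right mid finger
    gvid("arm_l", 2L),            # 9  left wrist (x = 0.80)
    gvid("neck", 2L),             # 10 shoulder top (y = 1.50)
    gvid("leg_l", 5L),            # 11 low left hip (y = 0.84)
    gvid("leg_l", 2L),            # 12 left ankle (y = 0.10)
    gvid("torso", 4L),            # 13 lower belly point (y = 1.00)
    gvid("head", 2L),             # 14 forehead point (y = 1.65)
    gvid("arm_r", 2L),            # 15 right forearm point (x = -0.60)
    gvid("leg_r", 4L),            # 16 right thigh point (y = 0.60)
    gvid("leg_r", 3L),            # 17 right calf point (y = 0.35)
    gvid("leg_r", 2L),            # 18 right ankle point (y = 0.10)
    gvid("torso", 2L),            # 19 mid hip point (y = 0.90)
    gvid("arm_r", 3L)             # 20 right bicep point (x = -0.30)
  )
  registry <- landmark_registry(
    data.frame(index = 1:20, name = smpl_landmark_table()$name,
               vertex_index = as.integer(lm - 1L)),
    n_vertices = nrow(mg$mesh$vertices))

  pos <- function(i) mg$mesh$vertices[lm[i], ]
  dist_mm <- function(i, j) point_distance(pos(i), pos(j))
  per_mm <- function(r) ngon_perimeter(n, r) * 1000
  truth_vals <- c(
    A = per_mm(rH), B = per_mm(rN), C = dist_mm(1, 10), D = per_mm(rT),
    E = per_mm(rT), F = per_mm(rT), G = per_mm(rA), H = per_mm(rA),
    I = per_mm(rA), J = dist_mm(2, 9), K = dist_mm(11, 12), L = per_mm(rL),
    M = per_mm(rL), N = per_mm(rL), O = dist_mm(2, 3),
    arm_span = dist_mm(7, 8), inseam_height = dist_mm(2, 19),
    hip_width = dist_mm(5, 6))

  len <- function(p) diff(range(p))
  vol_L <- 1000 * (
    2 * ngon_area(n, rL) * len(legs_y) +
      ngon_area(n, rT) * len(torso_y) +
      ngon_area(n, rN) * len(neck_y) +
      ngon_area(n, rH) * len(head_y) +
      ngon_area(n, rA) * (len(armL_x) + len(armR_x)))

  truth <- structure(list(subject_id = "fixture", sex = "unspecified",
                          values = truth_vals,
                          height_cm = spec$stature * 100,
                          volume_L = vol_L),
                     class = "measurement_vector")
  list(mesh = mg$mesh, truth = truth, registry = registry, spec = spec)
}

#' Specification of a synthetic per-sex population
#'
#' Defines a cohort in which every measurement is a known linear
#' function of the height-weight design row plus independent Gaussian
#' noise, so regression fits can be checked against the generating
#' truth. Heights are truncated-normal within a plausibility window;
#' weight is linear in height with Gaussian residual.
#'
#' @param n subjects per sex.
#' @param seed RNG seed.
#' @param n_interactions design of the generating model (0, 2 or 4).
#' @param height_model per-sex list of `c(mean, sd, min, max)` in cm.
#' @param weight_model per-sex list of `c(intercept, slope, sd)`:
#'   weight_kg = intercept + slope * height_cm + N(0, sd).
#' @param coefficients true coefficient matrix, terms x measurements
#'   (mm); defaults to a plausible anthropometric set for the 15
#'   standard codes under `n_interactions = 0`.
#' @param noise_sd measurement noise SD, mm (scalar or per-measurement).
#' @return a list of class `"population_spec"`.
#' @export
population_spec <- function(n = 2000L, seed = 2021L, n_interactions = 0L,
                            height_model = list(
                              male = c(mean = 175, sd = 7, min = 145,
                                       max = 196),
                              female = c(mean = 162, sd = 6.5, min = 135,
                                         max = 190)),
                            weight_model = list(
                              male = c(intercept = -100, slope = 1.0,
                                       sd = 8),
                              female = c(intercept = -90, slope = 0.9,
                                         sd = 7)),
                            coefficients = NULL,
                            noise_sd = 5) {
  spec <- design_spec(n_interactions)
  if (is.null(coefficients)) {
    if (n_interactions != 0L)
      stop("supply `coefficients` when n_interactions > 0")
    coefficients <- default_true_coefficients()
  }
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != length(spec$terms))
    stop("coefficients must have one row per design term (",
         length(spec$terms), ")")
  rownames(coefficients) <- spec$terms
  m <- ncol(coefficients)
  if (length(noise_sd) == 1L)
    noise_sd <- stats::setNames(rep(noise_sd, m), colnames(coefficients))
  if (n < length(spec$terms) + 1L)
    stop("n is smaller than the design column count + 1; unusable for fitting")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 design = spec, height_model = height_model,
                 weight_model = weight_model, coefficients = coefficients,
                 noise_sd = noise_sd),
            class = "population_spec")
}

default_true_coefficients <- function() {
  # intercept (mm), per-cm and per-kg slopes; plausible adult magnitudes
  m <- rbind(
    intercept = c(350, 80, -40, 150, -100, 200, 40, 60, 80, -80, -150, 100,
                  90, 90, 50),
    h = c(0.8, 1.0, 3.5, 1.5, 1.0, 1.5, 0.5, 0.5, 0.5, 3.5, 5.0, 0.5, 0.5,
          0.5, 1.5),
    w = c(0.5, 1.5, 0.5, 6.0, 9.0, 6.0, 0.5, 2.0, 1.5, 0.3, 0.2, 5.0, 2.5,
          1.0, 0.8))
  colnames(m) <- LETTERS[1:15]
  m
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic cohort with known linear structure
#'
#' Seeded and reproducible: the same spec yields the same table
#' bitwise. The generating coefficient matrix and noise SDs are attached
#' as attributes `"true_coefficients"` and `"noise_sd"` for recovery
#' tests.
#'
#' @param spec a [population_spec()].
#' @return data.frame with `subject_id`, `sex`, `height_cm`,
#'   `weight_kg` and one column per measurement (mm).
#' @export
make_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  rows <- lapply(names(spec$height_model), function(sx) {
    hm <- spec$height_model[[sx]]
    wm <- spec$weight_model[[sx]]
    h <- rnorm_trunc(spec$n, hm[["mean"]], hm[["sd"]], hm[["min"]],
                     hm[["max"]])
    w <- wm[["intercept"]] + wm[["slope"]] * h +
      stats::rnorm(spec$n, 0, wm[["sd"]])
    w <- pmax(w, 30)  # keep weights physically plausible
    X <- build_design_matrix(h, w, spec$design)
    Y <- X %*% spec$coefficients
    for (j in seq_len(ncol(Y)))
      Y[, j] <- Y[, j] + stats::rnorm(spec$n, 0, spec$noise_sd[[j]])
    cbind(data.frame(subject_id = paste0(sx, "_", seq_len(spec$n)),
                     sex = sx, height_cm = h, weight_kg = w,
                     stringsAsFactors = FALSE),
          as.data.frame(Y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_coefficients") <- spec$coefficients
  attr(out, "noise_sd") <- spec$noise_sd
  attr(out, "population_spec") <- spec
  out
}

#' Write the versioned fixture suite to a directory
#'
#' A small set of golden inputs: unit cube, a 64-gon prism, a
#' two-component mesh (disjoint prisms, for loop-selection tests), and
#' three humanoid fixtures at different statures, together with a CSV of
#' their closed-form truths and the humanoid landmark registry as YAML.
#' Generation is deterministic, so regeneration reproduces the suite
#' byte for byte.
#'
#' @param out_dir output directory (created if missing).
#' @param statures humanoid fixture statures, metres.
#' @return invisibly, the list of files written.
#' @export
make_fixture_suite <- function(out_dir, statures = c(1.60, 1.75, 1.90)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(mesh, name) {
    p <- file.path(out_dir, name)
    write_obj(mesh, p)
    files <<- c(files, p)
  }
  wr(cube_mesh(), "cube.obj")
  wr(prism_mesh("y", c(0, 0.5), 0.1, 64L), "prism64.obj")
  two <- merge_meshes(list(prism_mesh("y", c(0, 0.5), 0.1, 32L,
                                      center = c(0.5, 0, 0)),
                           prism_mesh("y", c(0, 0.5), 0.05, 32L,
                                      center = c(-0.5, 0, 0))))$mesh
  wr(two, "two_prisms.obj")
  truths <- list()
  for (st in statures) {
    fx <- make_fixture_body(fixture_body_spec(stature = st))
    nm <- sprintf("humanoid_%03.0f.obj", st * 100)
    wr(fx$mesh, nm)
    fx$truth$subject_id <- sub("\\.obj$", "", nm)
    truths[[length(truths) + 1L]] <- fx$truth
    if (st == statures[1]) {
      rp <- file.path(out_dir, "humanoid_registry.yaml")
      write_protocol_config(rp, fx$registry)
      files <- c(files, rp)
    }
  }
  tp <- file.path(out_dir, "truth.csv")
  write_measurements(truths, tp)
  files <- c(files, tp)
  invisible(files)
}
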