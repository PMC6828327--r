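# Projection model, distortion correction and triangulation.

test_that("pinhole projection matches the textbook formulas", {
  cam <- camera_model(1, fx = 1, fy = 1, cx = 0, cy = 0,
                      image_size = c(10, 10))
  expect_equal(as.numeric(project(cam, c(0, 0, 5))), c(0, 0))
  expect_equal(as.numeric(project(cam, c(1, 2, 2))), c(0.5, 1))
  expect_error(project(cam, c(0, 0, 0)), "behind")
  expect_error(project(cam, c(0, 0, -1)), "behind")
  expect_true(all(is.na(project(cam, c(0, 0, -1), behind = "na"))))
})

test_that("axis-angle conversion round-trips, including edge angles", {
  for (r in list(c(0, 0, 0), c(1e-10, 0, 0), c(0.3, -0.2, 0.9),
                 c(pi - 1e-7, 0, 0), c(pi, 0, 0), c(0, 2, 2))) {
    R <- rotvec_to_matrix(r)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(rotvec_to_matrix(matrix_to_rotvec(R)), R, tolerance = 1e-8)
  }
})

test_that("projection with distortion matches an independent composed oracle", {
  for (seed in 1:25) {
    cam <- random_camera(seed)
    set.seed(seed + 1000)
    X <- c(runif(2, -3, 3), runif(1, 25, 50))
    expect_equal(as.numeric(project(cam, X)), oracle_project(cam, X),
                 tolerance = 1e-9)
  }
})

test_that("to_pinhole applies the radial correction and has the right fixed points", {
  cam <- random_camera(3)
  set.seed(99)
  uv <- cbind(runif(5, 0, 499), runif(5, 0, 499))
  cam0 <- cam; cam0$distortion <- rep(0, 4)
  expect_equal(to_pinhole(cam0, uv), uv, ignore_attr = TRUE)
  # principal point is a fixed point for any coefficients
  expect_equal(as.numeric(to_pinhole(cam, c(cam$cx, cam$cy))),
               c(cam$cx, cam$cy))
  # unit normalized coordinate with k1 = 0.1 is corrected by exactly 1.1
  camn <- camera_model(1, fx = 1, fy = 1, cx = 0, cy = 0,
                       image_size = c(10, 10),
                       distortion = c(0.1, 0, 0, 0))
  expect_equal(suppressWarnings(as.numeric(to_pinhole(camn, c(1, 0)))),
               c(1.1, 0))
  expect_error(to_pinhole(cam, c(NA, 1)), "invalid observation")
})

test_that("to_pinhole inverts the projection's distortion", {
  for (seed in 4:8) {
    cam <- random_camera(seed)
    set.seed(seed)
    X <- cbind(runif(20, -3, 3), runif(20, -3, 3), runif(20, 25, 50))
    uv <- project(cam, X)
    cam0 <- cam; cam0$distortion <- rep(0, 4)
    pinhole <- project(cam0, X)
    expect_equal(suppressWarnings(to_pinhole(cam, uv)), pinhole,
                 tolerance = 1e-9)
  }
})

test_that("triangulation round-trips noiseless projections", {
  rig <- simple_stereo_rig()
  X <- c(0.25, -0.1, 5)
  uv <- rbind(project(rig[[1]], X), project(rig[[2]], X))
  tri <- triangulate(uv, rig)
  expect_true(tri$ok)
  expect_equal(tri$point, X, tolerance = 1e-9)
  expect_lt(tri$error, 1e-12)
  # seven cameras with distortion
  ring <- make_rig(seed = 11, distortion_range = c(-0.3, 0.3))
  Y <- c(0.4, -0.2, 0.15)
  uv7 <- t(vapply(ring, function(cm) as.numeric(project(cm, Y)), numeric(2)))
  tri7 <- triangulate(uv7, ring)
  expect_equal(tri7$point, Y, tolerance = 1e-6)
})

test_that("triangulation requires two visible observations", {
  rig <- simple_stereo_rig()
  uv <- rbind(c(50, 50), c(NA, NA))
  expect_error(triangulate(uv, rig), "untriangulatable")
})

test_that("reprojection error sums squared pixel distances over visible cameras", {
  rig <- simple_stereo_rig()
  X <- c(0.2, 0.3, 4)
  uv <- rbind(project(rig[[1]], X), project(rig[[2]], X))
  expect_lt(reprojection_error(X, uv, rig), 1e-18)
  uv2 <- uv; uv2[1, ] <- uv2[1, ] + c(3, 4)
  expect_equal(reprojection_error(X, uv2, rig), 25)
  # invisible camera contributes nothing
  expect_equal(reprojection_error(X, uv2, rig, visible = c(FALSE, TRUE)), 0)
  # brute-force per-camera sum on a random configuration
  ring <- make_rig(seed = 5, distortion_range = c(-0.1, 0.1))
  set.seed(42)
  Y <- c(0.3, 0.1, -0.2)
  obs <- t(vapply(ring, function(cm) as.numeric(project(cm, Y)), numeric(2))) +
    matrix(rnorm(14), ncol = 2)
  direct <- sum(vapply(seq_along(ring), function(i) {
    sum((as.numeric(project(ring[[i]], Y)) - obs[i, ])^2)
  }, numeric(1)))
  expect_equal(reprojection_error(Y, obs, ring), direct, tolerance = 1e-12)
})

test_that("reprojection error grows monotonically with a single perturbation", {
  rig <- simple_stereo_rig()
  X <- c(0.1, 0.2, 5)
  uv <- rbind(project(rig[[1]], X), project(rig[[2]], X))
  errs <- vapply(seq(0, 10, by = 0.5), function(m) {
    uv2 <- uv; uv2[2, ] <- uv2[2, ] + m * c(0.6, 0.8)
    reprojection_error(X, uv2, rig)
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("projection is invariant to a joint rigid transform of world and rig", {
  rig <- make_rig(seed = 2, distortion_range = c(-0.2, 0.2))
  set.seed(8)
  X <- cbind(runif(10, -1, 1), runif(10, -1, 1), runif(10, -0.5, 0.5))
  rot <- c(0.2, -0.4, 0.7); tr <- c(5, -3, 2)
  R0 <- rotvec_to_matrix(rot)
  Xt <- X %*% t(R0) + rep(tr, each = nrow(X))
  rig_t <- transform_rig(rig, R0, tr)
  for (ci in seq_along(rig)) {
    expect_equal(project(rig_t[[ci]], Xt), project(rig[[ci]], X),
                 tolerance = 1e-8)
  }
})

test_that("round trip holds across random zero-distortion configurations", {
  for (seed in 1:20) {
    cam1 <- random_camera(seed, distortion = FALSE)
    cam2 <- random_camera(seed + 500, distortion = FALSE)
    set.seed(seed)
    X <- c(runif(2, -2, 2), runif(1, 30, 50))
    uv <- rbind(as.numeric(project(cam1, X)), as.numeric(project(cam2, X)))
    tri <- triangulate(uv, list(cam1, cam2))
    if (!tri$ok) next  # accidental degenerate baseline
    expect_equal(tri$point, X, tolerance = 1e-9)
  }
})
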