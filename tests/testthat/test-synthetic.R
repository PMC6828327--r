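# Synthetic rigs, motion, probability maps and corruptions.

test_that("synthetic rigs are deterministic and sit on the configured ring", {
  r1 <- make_rig(seed = 5, position_jitter = 0.5, rotation_jitter = 0.01,
                 distortion_range = c(-0.1, 0.1))
  r2 <- make_rig(seed = 5, position_jitter = 0.5, rotation_jitter = 0.01,
                 distortion_range = c(-0.1, 0.1))
  expect_identical(r1, r2)
  r0 <- make_rig(seed = 1)
  expect_equal(vapply(r0, function(cm) sqrt(sum(camera_center(cm)^2)),
                      numeric(1)), rep(94, 7), tolerance = 1e-9)
  # zero jitter reproduces the calibration initialization layout
  ext <- init_extrinsics(calib_config())
  for (i in 1:7) {
    expect_equal(r0[[i]]$rotation, ext[[i]]$rotation, tolerance = 1e-12)
    expect_equal(r0[[i]]$translation, ext[[i]]$translation, tolerance = 1e-12)
  }
})

test_that("segment lengths are constant across simulated frames", {
  sk <- fly_skeleton()
  motion <- simulate_motion(sk, data.frame(label = "walk", frequency = 12,
                                           amplitude = 0.6, n_frames = 50))
  geo <- fly_geometry()
  lens <- c(geo$segment_lengths, use.names = FALSE)
  for (limb in c("L1", "R3")) {
    ids <- sk$keypoints$id[sk$keypoints$limb == limb]
    for (s in 1:4) {
      d <- motion$poses[, ids[s], ] - motion$poses[, ids[s + 1], ]
      seg <- sqrt(rowSums(d^2))
      expect_equal(seg, rep(geo$segment_lengths[[s]], 50), tolerance = 1e-12)
    }
  }
  # zero amplitude freezes the pose
  still <- simulate_motion(sk, data.frame(label = "rest", frequency = 12,
                                          amplitude = 0, n_frames = 10))
  for (t in 2:10) {
    expect_equal(still$poses[t, , ], still$poses[1, , ], tolerance = 1e-12)
  }
})

test_that("a 10 Hz gait dominates the wavelet spectrum near 10 Hz", {
  sk <- fly_skeleton()
  motion <- simulate_motion(sk, data.frame(label = "walk", frequency = 10,
                                           amplitude = 0.5, n_frames = 400))
  ang <- compute_angles(motion$poses, sk, rate = motion$rate)
  feats <- wavelet_features(ang)
  freqs <- attr(feats, "frequencies")
  # average spectrum of the strongest femur-tibia channel, mid-series
  ch <- which.max(apply(unclass(ang), 2, stats::sd))
  spec <- colMeans(feats[100:300, (ch - 1) * 25 + 1:25])
  expect_lt(abs(freqs[which.max(spec)] - 10) / 10, 0.15)
})

test_that("rendered maps peak at the (grid-quantized) true projections", {
  scene <- make_scene(n_frames = 2, seed = 8)
  st <- render_maps(scene, frame = 1, seed = 8)
  sk <- scene$skeleton
  for (j in c(1, 10, 25, 38)) {
    for (ci in which(sk$visibility[j, ])) {
      m <- st$maps[[ci]][[j]]
      pk <- local_maxima(m, n = 1)
      truth <- scene$projections[1, ci, j, ]
      expect_lt(max(abs(c(pk$u, pk$v) - truth)), max(m$scale) / 2 + 1e-9)
    }
  }
  # determinism
  st2 <- render_maps(scene, frame = 1, seed = 8)
  expect_identical(st$maps[[1]][[1]]$values, st2$maps[[1]][[1]]$values)
})

test_that("false positives are injected per the corruption log", {
  scene <- make_scene(n_frames = 1, seed = 9)
  st <- render_maps(scene, frame = 1, fp_rate = 1, fp_height = 1.3, seed = 9)
  expect_gt(nrow(st$corruption), 0)
  row <- st$corruption[1, ]
  m <- st$maps[[row$camera]][[row$keypoint]]
  pk <- local_maxima(m, n = 2)
  # the injected taller bump is the top peak, far from the true projection
  truth <- scene$projections[1, row$camera, row$keypoint, ]
  expect_gt(max(abs(c(pk$u[1], pk$v[1]) - truth)), 4 * m$scale[1])
})

test_that("observation corruption honors rate and logs originals", {
  scene <- make_scene(n_frames = 3, seed = 10)
  uv <- aperm(scene$projections[1, , , ], c(1, 2, 3))
  obs <- observation_set(uv)
  id <- corrupt_observations(obs, 0, seed = 1)
  expect_identical(id$obs$uv, obs$uv)
  expect_equal(nrow(id$log), 0)
  all_bad <- corrupt_observations(obs, 1, magnitude = 50, seed = 1)
  expect_equal(nrow(all_bad$log), sum(obs$visible))
  half <- corrupt_observations(obs, 0.25, magnitude = 50, seed = 1)
  expect_equal(nrow(half$log), round(0.25 * sum(obs$visible)))
  # shifts have the requested magnitude and originals are recoverable
  d <- sqrt((half$log$u - half$log$u0)^2 + (half$log$v - half$log$v0)^2)
  expect_equal(d, rep(50, nrow(half$log)), tolerance = 1e-9)
})

test_that("scene regeneration with the same seed is bit-identical", {
  s1 <- make_scene(n_frames = 4, seed = 123)
  s2 <- make_scene(n_frames = 4, seed = 123)
  expect_identical(s1$poses, s2$poses)
  expect_identical(s1$projections, s2$projections)
  # behavior labels cover the configured bouts
  s3 <- make_scene(behaviors = data.frame(label = c("walk", "groom"),
                                          frequency = c(10, 25),
                                          amplitude = c(0.5, 0.3),
                                          n_frames = c(6, 4)), seed = 2)
  expect_equal(s3$labels, rep(c("walk", "groom"), c(6, 4)))
})

test_that("every keypoint is visible from at most four cameras", {
  sk <- fly_skeleton()
  expect_true(all(rowSums(sk$visibility) <= 4))
  expect_true(all(rowSums(sk$visibility) >= 2))
})
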