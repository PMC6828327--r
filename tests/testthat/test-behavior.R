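# Angles, wavelet posture dynamics, embedding, behavior map.

test_that("one-euro filter passes constants and the first sample unchanged", {
  x <- rep(3.2, 100)
  expect_equal(one_euro_filter(x), x)
  set.seed(1)
  y <- cumsum(rnorm(100))
  expect_equal(one_euro_filter(y)[1], y[1])
})

test_that("one-euro filter attenuates fast oscillations more than slow ones", {
  t <- seq(0, 2, by = 0.01)  # 100 Hz sampling
  slow <- sin(2 * pi * 1 * t)
  fast <- sin(2 * pi * 45 * t)
  ret_slow <- diff(range(one_euro_filter(slow))) / diff(range(slow))
  ret_fast <- diff(range(one_euro_filter(fast))) / diff(range(fast))
  # a 1 Hz component sits at the default minimum cutoff: most of it passes
  expect_gt(ret_slow, 0.75)
  expect_lt(ret_fast, 0.25)
  expect_lt(ret_fast, ret_slow)
})

test_that("smoothing rejects non-uniform timestamps", {
  poses <- array(rnorm(10 * 38 * 3), c(10, 38, 3))
  expect_error(smooth_poses(poses, timestamps = c(1:9, 20) / 100),
               "non-uniform")
})

test_that("joint angles follow the three-point arccos construction", {
  sk <- fly_skeleton()
  ch <- list(test = list(type = "joint", a = 1, j = 2, b = 3))
  poses <- array(0, c(1, 3, 3))
  poses[1, 1, ] <- c(1, 0, 0)
  poses[1, 2, ] <- c(0, 0, 0)
  poses[1, 3, ] <- c(0, 1, 0)
  ang <- compute_angles(poses, sk, channels = ch)
  expect_equal(as.numeric(ang[1, 1]), pi / 2)
})

test_that("angle series are invariant to similarity transforms of the pose", {
  scene <- make_scene(n_frames = 50, seed = 6)
  ang <- compute_angles(scene$poses, scene$skeleton)
  expect_equal(ncol(ang), 20)
  expect_true(all(ang >= 0 & ang <= pi))
  # scaling
  ang_s <- compute_angles(scene$poses * 10, scene$skeleton)
  expect_equal(unclass(ang_s), unclass(ang), tolerance = 1e-12)
  # rotation + translation
  R0 <- rotvec_to_matrix(c(0.3, -1.1, 0.6))
  poses_t <- scene$poses
  for (t in 1:50) {
    poses_t[t, , ] <- scene$poses[t, , ] %*% t(R0) +
      rep(c(5, -2, 1), each = 38)
  }
  ang_t <- compute_angles(poses_t, scene$skeleton)
  expect_equal(unclass(ang_t), unclass(ang), tolerance = 1e-9)
})

test_that("degenerate zero-length segments carry the previous angle", {
  sk <- fly_skeleton()
  ch <- list(test = list(type = "joint", a = 1, j = 2, b = 3))
  poses <- array(0, c(3, 3, 3))
  poses[, 1, 1] <- 1
  poses[, 3, 2] <- 1
  poses[2, 1, ] <- 0  # frame 2: a coincides with j
  ang <- compute_angles(poses, sk, channels = ch)
  expect_equal(as.numeric(ang[, 1]), rep(pi / 2, 3))
  expect_true(attr(ang, "flagged")[2, 1])
})

test_that("wavelet features have the documented dimension and frequency response", {
  t <- seq(0, 9.99, by = 0.01)
  ang <- matrix(rep(sin(2 * pi * 10 * t), 20), ncol = 20)
  feats <- wavelet_features(ang, rate = 100)
  expect_equal(dim(feats), c(1000, 20 * 25))
  freqs <- attr(feats, "frequencies")
  expect_equal(length(freqs), 25)
  expect_equal(freqs[1], 5)
  expect_equal(freqs[25], 50)
  # log2-uniform spacing
  expect_equal(diff(log2(freqs)), rep(log2(10) / 24, 24), tolerance = 1e-12)
  # the dominant scale of a 10 Hz sinusoid is the one closest to 10 Hz
  mid <- colMeans(feats[300:700, 1:25])
  expect_equal(unname(which.max(mid)), which.min(abs(freqs - 10)))
  # constant channels produce (numerically) zero magnitudes
  feats0 <- wavelet_features(matrix(2, 1000, 2), rate = 100)
  expect_lt(max(feats0), 1e-8)
})

test_that("feature normalization produces row distributions", {
  expect_equal(as.numeric(normalize_features(matrix(c(1, 3), 1, 2))),
               c(0.25, 0.75))
  set.seed(2)
  x <- matrix(runif(200), 20, 10)
  n1 <- normalize_features(x)
  expect_equal(rowSums(n1), rep(1, 20), tolerance = 1e-12)
  expect_equal(unclass(normalize_features(n1)), unclass(n1),
               tolerance = 1e-12)
  withzero <- rbind(x[1:3, ], 0)
  nz <- normalize_features(withzero)
  expect_equal(as.numeric(nz[4, ]), rep(0.1, 10))
  expect_equal(attr(nz, "flagged_rows"), 4L)
})

test_that("the KL dissimilarity matrix matches a direct computation", {
  set.seed(3)
  p <- normalize_features(matrix(runif(40, 0.1, 1), 4, 10))
  D <- kl_divergence_matrix(p)
  kl <- function(a, b) sum(a * log(a / b))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(D[i, j], (kl(p[i, ], p[j, ]) + kl(p[j, ], p[i, ])) / 2,
                 tolerance = 1e-10)
  }
  expect_error(kl_divergence_matrix(matrix(1, 2, 2)), "normalized")
})

test_that("the embedding is deterministic and preserves cluster structure", {
  set.seed(9)
  n <- 60
  # two clusters of distributions concentrated on disjoint channel blocks
  a <- matrix(runif(n / 2 * 10, 0, 0.05), n / 2, 10)
  a[, 1:3] <- a[, 1:3] + 1
  b <- matrix(runif(n / 2 * 10, 0, 0.05), n / 2, 10)
  b[, 8:10] <- b[, 8:10] + 1
  feats <- normalize_features(rbind(a, b))
  y1 <- tsne_embed(feats, perplexity = 10, seed = 4, n_iter = 300)
  y2 <- tsne_embed(feats, perplexity = 10, seed = 4, n_iter = 300)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(n, 2))
  # silhouette of the known labels in the embedding
  lab <- rep(1:2, each = n / 2)
  d <- as.matrix(dist(y1))
  sil <- vapply(seq_len(n), function(i) {
    a_i <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b_i <- mean(d[i, lab != lab[i]])
    (b_i - a_i) / max(a_i, b_i)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("embedding rows needing more than T/3 perplexity error out", {
  feats <- normalize_features(matrix(runif(50), 10, 5))
  expect_error(tsne_embed(feats, perplexity = 35), "perplexity")
})

test_that("behavior map conserves mass and separates distant clouds", {
  set.seed(11)
  emb <- rbind(matrix(rnorm(200, 0, 2), 100, 2),
               matrix(rnorm(200, 30, 2), 100, 2))
  bm <- behavior_map(emb, grid = 300, sigma = 5)
  expect_equal(sum(bm$histogram), 200)
  expect_equal(sum(bm$density), 200, tolerance = 1e-6)
  expect_gte(bm$n_regions, 2)
  lab1 <- bm$assignments$label[1:100]
  lab2 <- bm$assignments$label[101:200]
  m1 <- as.integer(names(which.max(table(lab1[lab1 > 0]))))
  m2 <- as.integer(names(which.max(table(lab2[lab2 > 0]))))
  expect_true(m1 != m2)
  expect_gt(mean(lab1 == m1), 0.9)
  expect_gt(mean(lab2 == m2), 0.9)
  expect_error(behavior_map(matrix(numeric(0), 0, 2)), "empty")
})

test_that("map labels are invariant to frame order (up to the permutation)", {
  set.seed(12)
  n <- 80
  a <- matrix(runif(n / 2 * 8, 0, 0.05), n / 2, 8); a[, 1:2] <- a[, 1:2] + 1
  b <- matrix(runif(n / 2 * 8, 0, 0.05), n / 2, 8); b[, 7:8] <- b[, 7:8] + 1
  feats <- normalize_features(rbind(a, b))
  perm <- sample(n)
  y <- tsne_embed(feats, perplexity = 8, seed = 2, n_iter = 250)
  yp <- tsne_embed(feats[perm, ], perplexity = 8, seed = 2, n_iter = 250)
  expect_equal(yp, y[perm, ], tolerance = 1e-10)
})
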