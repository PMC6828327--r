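# Scores, exact tree inference and prior learning.

test_that("unary log-likelihood reads map intensities at projections", {
  rig <- simple_stereo_rig()
  X <- c(0.1, 0.2, 5)
  maps <- lapply(rig, function(cam) {
    uv <- as.numeric(project(cam, X))
    m <- prob_map(matrix(0, 101, 101), keypoint = 1, camera = cam$id)
    m$values[uv[2] + 1, uv[1] + 1] <- 1
    m
  })
  expect_equal(unary_loglik(X, maps, rig, c(TRUE, TRUE)), 0)
  # an invisible camera contributes exactly the floor constant
  u2 <- unary_loglik(X, maps, rig, c(TRUE, FALSE), eps_p = 1e-6)
  expect_equal(u2, log(1e-6))
  # brute-force product-then-log oracle on random maps
  set.seed(14)
  maps_r <- lapply(rig, function(cam) {
    prob_map(matrix(runif(101 * 101, 0.01, 1), 101, 101),
             keypoint = 1, camera = cam$id)
  })
  direct <- sum(vapply(1:2, function(ci) {
    uv <- round(as.numeric(project(rig[[ci]], X)))
    log(maps_r[[ci]]$values[uv[2] + 1, uv[1] + 1])
  }, numeric(1)))
  expect_equal(unary_loglik(X, maps_r, rig, c(TRUE, TRUE)), direct,
               tolerance = 1e-12)
})

test_that("segment-length log-priors match their closed forms", {
  pr <- segment_prior(1, 2, "gaussian", mu = 2, sigma = 0.3)
  expect_equal(pairwise_logprior(2, pr), log(1 / (0.3 * sqrt(2 * pi))))
  expect_equal(pairwise_logprior(2.3, pr),
               pairwise_logprior(2, pr) - 0.5)
  prb <- segment_prior(1, 2, "beta", alpha = 2, beta = 2, length_scale = 1)
  expect_equal(pairwise_logprior(0.5, prb), log(1.5))
  # outside the Beta support the density is floored, not an error
  expect_equal(pairwise_logprior(1.5, prb, log_floor = -700), -700)
  expect_equal(pairwise_logprior(c(0.5, 2), prb)[2], -745)
})

test_that("reprojection log-term is the log inverse product of squared distances", {
  rig <- simple_stereo_rig()
  X <- c(0.1, 0.2, 5)
  uv0 <- rbind(as.numeric(project(rig[[1]], X)),
               as.numeric(project(rig[[2]], X)))
  # distances exactly at the clamp floor
  eps <- 0.5
  uv <- uv0 + cbind(c(eps, eps), 0)
  expect_equal(reprojection_logterm(X, uv, rig, eps_r = eps),
               2 * (-2 * log(eps)), tolerance = 1e-9)
  # doubling every distance (above the clamp) drops the term by 2 v log 2
  uv2 <- uv0 + cbind(c(2, 2), 0)
  uv4 <- uv0 + cbind(c(4, 4), 0)
  expect_equal(reprojection_logterm(X, uv2, rig) -
                 reprojection_logterm(X, uv4, rig),
               2 * 2 * log(2), tolerance = 1e-9)
  # brute-force oracle on a random configuration
  set.seed(7)
  uvr <- uv0 + matrix(rnorm(4, 0, 5), 2, 2)
  direct <- -sum(vapply(1:2, function(ci) {
    d <- sqrt(sum((as.numeric(project(rig[[ci]], X)) - uvr[ci, ])^2))
    2 * log(max(d, 1))
  }, numeric(1)))
  expect_equal(reprojection_logterm(X, uvr, rig), direct, tolerance = 1e-12)
})

test_that("max-sum inference equals exhaustive enumeration on random trees", {
  for (seed in 1:300) {
    m <- random_tree_model(seed)
    got <- max_sum_tree(m$unary, m$edges, m$pairwise)
    want <- oracle_tree_map(m$unary, m$edges, m$pairwise)
    expect_equal(got$score, want$score, tolerance = 1e-10)
    expect_identical(got$assignment, want$assignment)
  }
})

test_that("a single candidate per node is returned with its summed score", {
  unary <- list(1.5, -0.3, 0.7)
  edges <- data.frame(i = c(1, 2), j = c(2, 3))
  pw <- list(matrix(0.2), matrix(-0.1))
  sol <- max_sum_tree(unary, edges, pw)
  expect_equal(sol$assignment, rep(1L, 3))
  expect_equal(sol$score, 1.5 - 0.3 + 0.7 + 0.2 - 0.1)
})

test_that("raising the winning candidate's unary never changes the MAP", {
  for (seed in 1:20) {
    m <- random_tree_model(seed + 4000)
    base <- max_sum_tree(m$unary, m$edges, m$pairwise)
    v <- sample(length(m$unary), 1)
    m$unary[[v]][base$assignment[v]] <- m$unary[[v]][base$assignment[v]] + 5
    again <- max_sum_tree(m$unary, m$edges, m$pairwise)
    expect_identical(again$assignment, base$assignment)
  }
})

test_that("pictorial correction fixes a taller false positive in one camera", {
  scene <- make_scene(n_frames = 30, seed = 10)
  sk <- scene$skeleton
  st <- render_maps(scene, frame = 1, seed = 10)
  # corrupt the pretarsus map of the first camera that sees it with a
  # false-positive bump taller than the true peak
  j <- sk$keypoints$id[sk$keypoints$name == "L1_pretarsus"]
  ci <- which(sk$visibility[j, ])[1]
  true_uv <- scene$projections[1, ci, j, ] / st$scale
  st$maps[[ci]][[j]] <- add_bump(st$maps[[ci]][[j]],
                                 u_map = (true_uv[1] + 40) %% 120,
                                 v_map = (true_uv[2] + 25) %% 60,
                                 height = 1.4)
  leg <- sk$keypoints$id[sk$keypoints$limb == "L1"]
  cands <- vector("list", max(sk$keypoints$id))
  for (k in leg) {
    maps_k <- lapply(st$maps, function(cm) cm[[k]])
    cands[[k]] <- generate_candidates(maps_k, scene$rig,
                                      visible = sk$visibility[k, ],
                                      n_peaks = 3)
  }
  priors <- learn_segment_priors(scene$poses, sk, sigma_floor = 0.01)
  sol <- map_solve(cands, sk, priors, st$maps, scene$rig)
  err <- sqrt(sum((sol$points[j, ] - scene$poses[1, j, ])^2))
  expect_lt(err, 0.05)
  # without the skeleton context, the corrupted camera's taller peak wins
  pk <- local_maxima(st$maps[[ci]][[j]], n = 1)
  d_fp <- sqrt(sum((c(pk$u, pk$v) - scene$projections[1, ci, j, ])^2))
  expect_gt(d_fp, 50)
})

test_that("pinned observations are honored and occlusions filled in", {
  scene <- make_scene(n_frames = 30, seed = 12)
  sk <- scene$skeleton
  st <- render_maps(scene, frame = 1, seed = 12)
  j <- sk$keypoints$id[sk$keypoints$name == "L2_femur_tibia"]
  ci <- which(sk$visibility[j, ])[2]
  pin <- data.frame(keypoint = j, camera = ci,
                    u = scene$projections[1, ci, j, 1],
                    v = scene$projections[1, ci, j, 2])
  leg <- sk$keypoints$id[sk$keypoints$limb == "L2"]
  cands <- vector("list", max(sk$keypoints$id))
  for (k in leg) {
    maps_k <- lapply(st$maps, function(cm) cm[[k]])
    cands[[k]] <- generate_candidates(maps_k, scene$rig,
                                      visible = sk$visibility[k, ],
                                      n_peaks = 2)
  }
  priors <- learn_segment_priors(scene$poses, sk, sigma_floor = 0.01)
  sol <- map_solve(cands, sk, priors, st$maps, scene$rig, pinned = pin)
  expect_true(sol$resolved[j])
  # the pinned pixel appears as the stored support for that camera
  expect_equal(as.numeric(sol$observations[ci, j, ]), c(pin$u, pin$v),
               tolerance = 1e-9)
  # cameras outside the supporting pair store the reprojection
  sup <- sol$support[[j]]
  other <- setdiff(seq_along(scene$rig), c(sup$cam1, sup$cam2, ci))[1]
  expect_equal(as.numeric(sol$observations[other, j, ]),
               as.numeric(project(scene$rig[[other]], sol$points[j, ])),
               tolerance = 1e-9)
})

test_that("a keypoint without candidates splits the chain and the rest solves", {
  scene <- make_scene(n_frames = 30, seed = 13)
  sk <- scene$skeleton
  st <- render_maps(scene, frame = 1, seed = 13)
  leg <- sk$keypoints$id[sk$keypoints$limb == "L1"]
  cands <- vector("list", max(sk$keypoints$id))
  for (k in leg) {
    maps_k <- lapply(st$maps, function(cm) cm[[k]])
    cands[[k]] <- generate_candidates(maps_k, scene$rig,
                                      visible = sk$visibility[k, ],
                                      n_peaks = 2)
  }
  # knock out the middle of the chain
  mid <- leg[3]
  cands[[mid]]$points <- matrix(numeric(0), 0, 3)
  cands[[mid]]$support <- data.frame()
  cands[[mid]]$error <- numeric(0)
  priors <- learn_segment_priors(scene$poses, sk, sigma_floor = 0.01)
  sol <- map_solve(cands, sk, priors, st$maps, scene$rig)
  expect_false(sol$resolved[mid])
  expect_true(all(sol$resolved[setdiff(leg, mid)]))
})

test_that("Gaussian segment priors recover simulated lengths", {
  sk <- fly_skeleton()
  edge <- sk$edges[sk$edges$family == "gaussian", ][1, ]
  set.seed(77)
  n <- 1000
  lengths <- rnorm(n, 2.0, 0.1)
  poses <- array(0, c(n, max(sk$keypoints$id), 3))
  poses[, edge$from, 1] <- 0
  poses[, edge$to, 1] <- lengths
  priors <- learn_segment_priors(poses, sk, min_samples = 30)
  pr <- priors[[paste0(edge$from, "-", edge$to)]]
  expect_equal(pr$family, "gaussian")
  expect_lt(abs(pr$mu - 2.0), 3 * 0.1 / sqrt(n))
  expect_lt(abs(pr$sigma - 0.1) / 0.1, 0.15)
})

test_that("constant lengths hit the sigma floor instead of failing", {
  sk <- fly_skeleton()
  edge <- sk$edges[1, ]
  poses <- array(0, c(40, max(sk$keypoints$id), 3))
  poses[, edge$to, 1] <- 2.0
  priors <- learn_segment_priors(poses, sk, min_samples = 30)
  pr <- priors[[paste0(edge$from, "-", edge$to)]]
  expect_equal(pr$mu, 2.0)
  expect_gt(pr$sigma, 0)
})

test_that("high-reprojection frames are excluded from prior learning", {
  sk <- fly_skeleton()
  edge <- sk$edges[1, ]
  set.seed(5)
  n <- 200
  poses <- array(0, c(n + 10, max(sk$keypoints$id), 3))
  poses[, edge$to, 1] <- c(rnorm(n, 1.5, 0.05), rep(50, 10))
  reproj <- matrix(0, n + 10, max(sk$keypoints$id))
  reproj[n + 1:10, edge$to] <- 1e4
  with_bad <- learn_segment_priors(poses, sk, reproj = reproj,
                                   reproj_cutoff = 100)
  clean <- learn_segment_priors(poses[1:n, , , drop = FALSE], sk)
  key <- paste0(edge$from, "-", edge$to)
  expect_equal(with_bad[[key]]$mu, clean[[key]]$mu)
  expect_equal(with_bad[[key]]$sigma, clean[[key]]$sigma)
})

test_that("Beta priors are fitted for the tarsal segments", {
  sk <- fly_skeleton()
  edge <- sk$edges[sk$edges$family == "beta", ][1, ]
  set.seed(31)
  n <- 500
  scale_true <- 0.3
  lengths <- scale_true * rbeta(n, 5, 2)
  poses <- array(0, c(n, max(sk$keypoints$id), 3))
  poses[, edge$to, 2] <- lengths
  priors <- learn_segment_priors(poses, sk)
  pr <- priors[[paste0(edge$from, "-", edge$to)]]
  expect_equal(pr$family, "beta")
  expect_equal(pr$length_scale, 1.05 * max(lengths))
  # mean of the fitted Beta close to the sample mean (on the rescaled axis)
  fitted_mean <- pr$alpha / (pr$alpha + pr$beta) * pr$length_scale
  expect_lt(abs(fitted_mean - mean(lengths)) / mean(lengths), 0.05)
})

test_that("too few samples yield an uninformative prior that scores zero", {
  sk <- fly_skeleton()
  poses <- array(rnorm(5 * max(sk$keypoints$id) * 3),
                 c(5, max(sk$keypoints$id), 3))
  priors <- learn_segment_priors(poses, sk, min_samples = 30)
  expect_true(all(!vapply(priors, function(p) p$informative, logical(1))))
  expect_equal(pairwise_logprior(c(1, 2, 3), priors[[1]]), c(0, 0, 0))
})
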