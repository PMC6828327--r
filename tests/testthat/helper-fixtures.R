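# Fixtures and independent oracles shared across the suite.

# Two ideal pinhole cameras with a horizontal baseline, aimed at +z.
simple_stereo_rig <- function(fx = 100, baseline = 1) {
  list(
    camera_model(1, fx = fx, fy = fx, cx = 50, cy = 50,
                 image_size = c(101, 101)),
    camera_model(2, fx = fx, fy = fx, cx = 50, cy = 50,
                 image_size = c(101, 101),
                 translation = c(-baseline, 0, 0)))
}

# A random camera with isotropic radial distortion (k1x = k1y, k2x = k2y)
# so the scalar-radius oracle below applies.
random_camera <- function(seed, distortion = TRUE) {
  set.seed(seed)
  k1 <- if (distortion) runif(1, -0.1, 0.1) else 0
  k2 <- if (distortion) runif(1, -0.02, 0.02) else 0
  camera_model(1, fx = runif(1, 200, 2000), fy = runif(1, 200, 2000),
               cx = runif(1, 100, 400), cy = runif(1, 100, 400),
               image_size = c(500, 500),
               rotation = runif(3, -0.5, 0.5),
               translation = c(runif(2, -5, 5), runif(1, 20, 60)),
               distortion = c(k1, k2, k1, k2))
}

# Independent projection oracle: composes the extrinsic transform, the
# pinhole division and the radial model step by step. The distortion
# inversion is done by root-finding on the scalar radius (valid for
# isotropic coefficients), fully independent of the package's fixed-point
# iteration.
oracle_project <- function(cam, X) {
  th <- sqrt(sum(cam$rotation^2))
  R <- if (th < 1e-12) diag(3) else {
    k <- cam$rotation / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  Xc <- as.numeric(R %*% X + cam$translation)
  stopifnot(Xc[3] > 0)
  xn <- Xc[1] / Xc[3]; yn <- Xc[2] / Xc[3]
  k1 <- cam$distortion[1]; k2 <- cam$distortion[2]
  ru <- sqrt(xn^2 + yn^2)
  if (k1 == 0 && k2 == 0 || ru == 0) {
    rd <- ru
  } else {
    f <- function(r) r * (1 + k1 * r^2 + k2 * r^4) - ru
    # bracket the root by scanning outward from zero (the radial polynomial
    # need not be monotone far from the working range)
    grid <- seq(0, 3 * ru + 0.5, length.out = 4000)
    fg <- vapply(grid, f, numeric(1))
    up <- which(fg >= 0)[1]
    stopifnot(!is.na(up), up > 1)
    rd <- uniroot(f, c(grid[up - 1], grid[up]), tol = 1e-15)$root
  }
  s <- if (ru > 0) rd / ru else 1
  c(cam$fx * xn * s + cam$cx, cam$fy * yn * s + cam$cy)
}

# Exhaustive-scan oracle for local maxima with the Chebyshev separation
# rule; mirrors the documented contract, coded independently.
oracle_local_maxima <- function(H, n, min_sep) {
  nr <- nrow(H); nc <- ncol(H)
  cand <- list()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (H[r, cc] <= 0) next
    ok <- TRUE; lower <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc) {
        if (H[rr, ccc] > H[r, cc]) ok <- FALSE
        if (H[rr, ccc] < H[r, cc]) lower <- TRUE
      }
    }
    if (ok && lower) cand[[length(cand) + 1]] <- c(r, cc, H[r, cc])
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  keep <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(cand))) {
    if (nrow(keep) &&
          any(pmax(abs(keep[, 1] - cand[i, 1]),
                   abs(keep[, 2] - cand[i, 2])) <= min_sep)) next
    keep <- rbind(keep, cand[i, ])
    if (nrow(keep) == n) break
  }
  keep
}

# Brute-force MAP by enumerating every joint assignment of a tree model
# (vectorized over assignments).
oracle_tree_map <- function(unary, edges, pairwise) {
  k <- lengths(unary)
  grid <- as.matrix(expand.grid(lapply(k, seq_len)))
  score <- rep(0, nrow(grid))
  for (v in seq_along(unary)) score <- score + unary[[v]][grid[, v]]
  if (!is.null(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      score <- score + pairwise[[e]][cbind(grid[, edges$i[e]],
                                           grid[, edges$j[e]])]
    }
  }
  best <- which.max(score)
  list(assignment = as.integer(grid[best, ]), score = score[best])
}

# Random tree model (random topology via random parent links).
random_tree_model <- function(seed, n_max = 6, k_max = 6) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  k <- sample(1:k_max, n, replace = TRUE)
  unary <- lapply(k, function(ki) rnorm(ki))
  edges <- data.frame(i = integer(0), j = integer(0))
  for (v in 2:n) {
    p <- sample(seq_len(v - 1), 1)
    # random direction, as map_solve sees edges in either orientation
    if (runif(1) < 0.5) edges <- rbind(edges, data.frame(i = p, j = v))
    else edges <- rbind(edges, data.frame(i = v, j = p))
  }
  pairwise <- lapply(seq_len(nrow(edges)), function(e) {
    matrix(rnorm(k[edges$i[e]] * k[edges$j[e]]), k[edges$i[e]], k[edges$j[e]])
  })
  list(unary = unary, edges = edges, pairwise = pairwise)
}

# Add a Gaussian bump to a probability map (for constructed false
# positives).
add_bump <- function(map, u_map, v_map, height, sigma = 1) {
  gx <- matrix(rep(0:(ncol(map$values) - 1), each = nrow(map$values)),
               nrow(map$values))
  gy <- matrix(rep(0:(nrow(map$values) - 1), ncol(map$values)),
               nrow(map$values))
  map$values <- map$values +
    height * exp(-((gx - u_map)^2 + (gy - v_map)^2) / (2 * sigma^2))
  map
}
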