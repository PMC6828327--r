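# Self-calibration of the camera ring from the animal's own keypoints.
#
# The rig is calibrated by minimizing the Huber-robustified reprojection
# error jointly over ten free parameters per camera (three rotations, three
# translations, four radial-distortion coefficients; intrinsics stay fixed at
# their configured values) and the 3D positions of the keypoints used as
# calibration targets. The first camera's extrinsics are frozen to remove
# the rotation/translation gauge and the overall scale is pinned to the
# configured ring radius.

#' Huber loss
#'
#' Quadratic (`a^2/2`) for `|a| <= delta`, linear (`delta (|a| - delta/2)`)
#' beyond; continuous, even and convex. Limits the influence of gross
#' outliers on the calibration objective.
#'
#' @param a numeric residual(s).
#' @param delta transition point in the residual's units (pixels here);
#'   must be positive.
#' @return non-negative numeric of the same length as `a`.
#' @export
huber <- function(a, delta = 20) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    stop("invalid configuration: huber delta must be a positive scalar")
  }
  aa <- abs(a)
  ifelse(aa <= delta, aa^2 / 2, delta * (aa - delta / 2))
}

# IRLS weight for the Huber kernel: rho'(a)/a.
huber_weight <- function(a, delta) {
  aa <- pmax(abs(a), .Machine$double.eps)
  pmin(1, delta / aa)
}

#' Calibration configuration
#'
#' @param huber_delta Huber transition, pixels.
#' @param ring_radius camera-ring radius, mm.
#' @param n_cameras number of cameras on the ring.
#' @param epipolar_row_threshold row-consensus tolerance, pixels.
#' @param max_iterations joint-refinement iteration cap (per reweighting
#'   round).
#' @param convergence_tol relative decrease of the robust objective below
#'   which the outer reweighting loop stops.
#' @param max_outer reweighting rounds for the robust kernel.
#' @return list of class `calib_config`.
#' @export
calib_config <- function(huber_delta = 20, ring_radius = 94, n_cameras = 7,
                         epipolar_row_threshold = 5, max_iterations = 100,
                         convergence_tol = 1e-10, max_outer = 5) {
  stopifnot(huber_delta > 0, ring_radius > 0, n_cameras >= 2,
            epipolar_row_threshold >= 0, max_iterations >= 1, max_outer >= 1)
  structure(list(huber_delta = huber_delta, ring_radius = ring_radius,
                 n_cameras = n_cameras,
                 epipolar_row_threshold = epipolar_row_threshold,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol, max_outer = max_outer),
            class = "calib_config")
}

#' Initial extrinsics for an inward-looking camera ring
#'
#' Places `n_cameras` camera centers uniformly on a horizontal circle of
#' radius `ring_radius` in the z = 0 plane, each optical axis pointing at the
#' world origin (where the tethered animal sits) and image rows horizontal,
#' so that corresponding detections fall on nearly the same rows across
#' cameras. Distortion is meant to start at zero.
#'
#' @param config a [calib_config()].
#' @param angles optional per-camera azimuths (radians) overriding the
#'   uniform spacing.
#' @return list with one `list(rotation, translation)` per camera (axis-angle
#'   rotation vector; translation in mm).
#' @export
init_extrinsics <- function(config = calib_config(), angles = NULL) {
  n <- config$n_cameras
  if (is.null(angles)) angles <- 2 * pi * (seq_len(n) - 1) / n
  stopifnot(length(angles) == n)
  lapply(seq_len(n), function(i) {
    th <- angles[i]
    C <- config$ring_radius * c(cos(th), sin(th), 0)
    f <- -C / sqrt(sum(C^2))              # optical axis, through the origin
    x_c <- c(f[2], -f[1], 0)              # horizontal image u axis
    x_c <- x_c / sqrt(sum(x_c^2))
    y_c <- c(f[2] * x_c[3] - f[3] * x_c[2],
             f[3] * x_c[1] - f[1] * x_c[3],
             f[1] * x_c[2] - f[2] * x_c[1])
    R <- unname(rbind(x_c, y_c, f))
    list(rotation = matrix_to_rotvec(R), translation = as.numeric(-R %*% C))
  })
}

#' Epipolar outlier pruning by row consensus
#'
#' For a horizontal inward-looking ring, corresponding projections of one
#' keypoint must lie on nearly the same image row in every camera. Detections
#' whose row deviates from the consensus row (the median across visible
#' cameras) by more than `threshold` pixels are discarded (their visibility
#' flag is set to zero).
#'
#' @param uv n_cameras x 2 matrix of detections for one keypoint.
#' @param rig optional camera list; unused by the row rule but kept so
#'   callers can pass the rig uniformly. The rule presumes the ring layout of
#'   [init_extrinsics()].
#' @param threshold row tolerance in pixels.
#' @param visible logical per-camera visibility; defaults to finite rows.
#' @return list with `visible` (updated flags) and `usable` (`FALSE` when all
#'   detections were discarded).
#' @export
epipolar_prune <- function(uv, rig = NULL, threshold = 5, visible = NULL) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2, byrow = TRUE)
  if (is.null(visible)) visible <- rowSums(is.finite(uv)) == 2
  visible <- as.logical(visible) & rowSums(is.finite(uv)) == 2
  if (!any(visible)) return(list(visible = visible, usable = FALSE))
  consensus <- stats::median(uv[visible, 2])
  keep <- visible & abs(uv[, 2] - consensus) <= threshold
  list(visible = keep, usable = any(keep))
}

# Apply a packed free-parameter vector for one camera (camera 1 keeps its
# extrinsics frozen as the gauge and only exposes its distortion).
set_camera_params <- function(cam, par, is_gauge) {
  if (is_gauge) {
    cam$distortion <- par
  } else {
    cam$rotation <- par[1:3]
    cam$translation <- par[4:6]
    cam$distortion <- par[7:10]
  }
  cam
}

get_camera_params <- function(cam, is_gauge) {
  if (is_gauge) cam$distortion else c(cam$rotation, cam$translation,
                                      cam$distortion)
}

# Weighted residual matrix (n_j x 2) of one camera over its visible points.
camera_residuals <- function(cam, points, target, w) {
  p <- project(cam, points, behind = "na")
  r <- p - target
  r[!is.finite(r)] <- 1e4
  r * w
}

# Sparse Levenberg-Marquardt over cameras and points, exploiting the bundle
# structure: block Jacobians by forward differences, normal equations
# reduced to the cameras by the Schur complement on the (3x3) point blocks.
# Weights implement the robust kernel via IRLS (sqrt-weighted rows). A weak
# zero-centered Gaussian prior (sd `distortion_prior_sd`) keeps the radial
# coefficients bounded where the rig's small field of view leaves them
# unidentified; at physical coefficient magnitudes its cost is negligible.
sparse_bundle_lm <- function(cameras, points, obs, weights = NULL,
                             max_iter = 100, tol = 1e-14,
                             distortion_prior_sd = 10, verbose = FALSE) {
  n_cams <- length(cameras)
  n_pts <- nrow(points)
  js_of <- lapply(seq_len(n_cams), function(ci) which(obs$visible[ci, ]))
  targets <- lapply(seq_len(n_cams), function(ci) {
    cbind(obs$uv[ci, js_of[[ci]], 1], obs$uv[ci, js_of[[ci]], 2])
  })
  w_of <- lapply(seq_len(n_cams), function(ci) {
    if (is.null(weights)) rep(1, length(js_of[[ci]]))
    else sqrt(weights[[ci]])
  })
  np <- ifelse(seq_len(n_cams) == 1, 4L, 10L)
  cam_off <- c(0, cumsum(np))
  P <- sum(np)
  prior_prec <- 1 / distortion_prior_sd^2
  objective <- function(cams, pts) {
    sum(vapply(seq_len(n_cams), function(ci) {
      sum(camera_residuals(cams[[ci]], pts[js_of[[ci]], , drop = FALSE],
                           targets[[ci]], w_of[[ci]])^2)
    }, numeric(1))) +
      prior_prec * sum(vapply(cams, function(cm) sum(cm$distortion^2),
                              numeric(1)))
  }
  cur <- objective(cameras, points)
  lambda <- 1e-3
  for (iter in seq_len(max_iter)) {
    # residuals and FD Jacobian blocks
    res <- vector("list", n_cams)    # n_j x 2
    A <- vector("list", n_cams)      # n_j x 2 x np  (d res / d camera)
    B <- vector("list", n_cams)      # n_j x 2 x 3   (d res / d point)
    for (ci in seq_len(n_cams)) {
      js <- js_of[[ci]]
      pts <- points[js, , drop = FALSE]
      r0 <- camera_residuals(cameras[[ci]], pts, targets[[ci]], w_of[[ci]])
      res[[ci]] <- r0
      par0 <- get_camera_params(cameras[[ci]], ci == 1)
      Ac <- array(0, c(length(js), 2, np[ci]))
      for (p in seq_len(np[ci])) {
        h <- 1e-7 * max(abs(par0[p]), 1)
        par <- par0; par[p] <- par[p] + h
        camh <- set_camera_params(cameras[[ci]], par, ci == 1)
        Ac[, , p] <- (camera_residuals(camh, pts, targets[[ci]],
                                       w_of[[ci]]) - r0) / h
      }
      A[[ci]] <- Ac
      Bc <- array(0, c(length(js), 2, 3))
      for (d in 1:3) {
        h <- 1e-7
        ptsh <- pts; ptsh[, d] <- ptsh[, d] + h
        Bc[, , d] <- (camera_residuals(cameras[[ci]], ptsh, targets[[ci]],
                                       w_of[[ci]]) - r0) / h
      }
      B[[ci]] <- Bc
    }
    # normal-equation blocks
    U <- vector("list", n_cams)          # np x np
    gc <- vector("list", n_cams)         # np
    V <- array(0, c(3, 3, n_pts))
    gp <- matrix(0, n_pts, 3)
    Wblocks <- vector("list", n_cams)    # per camera: list over points
    for (ci in seq_len(n_cams)) {
      js <- js_of[[ci]]
      Ac <- A[[ci]]; Bc <- B[[ci]]; r0 <- res[[ci]]
      A2 <- rbind(matrix(Ac[, 1, ], ncol = np[ci]),
                  matrix(Ac[, 2, ], ncol = np[ci]))
      r2 <- c(r0[, 1], r0[, 2])
      U[[ci]] <- crossprod(A2)
      gc[[ci]] <- -as.numeric(crossprod(A2, r2))
      kix <- if (ci == 1) 1:4 else 7:10     # distortion prior contribution
      diag(U[[ci]])[kix] <- diag(U[[ci]])[kix] + prior_prec
      gc[[ci]][kix] <- gc[[ci]][kix] - prior_prec * cameras[[ci]]$distortion
      Wc <- vector("list", length(js))
      for (i in seq_along(js)) {
        Ai <- matrix(Ac[i, , ], 2, np[ci])
        Bi <- matrix(Bc[i, , ], 2, 3)
        Wc[[i]] <- crossprod(Ai, Bi)
        j <- js[i]
        V[, , j] <- V[, , j] + crossprod(Bi)
        gp[j, ] <- gp[j, ] - as.numeric(crossprod(Bi, r0[i, ]))
      }
      Wblocks[[ci]] <- Wc
    }
    # damping floor relative to the largest curvature: parameters whose
    # information is many orders smaller (e.g. r^4 distortion terms at the
    # small normalized radii of a close-up rig) are effectively frozen
    # rather than allowed to destabilize the solve
    dmax <- max(c(vapply(U, function(u) max(diag(u)), numeric(1)),
                  apply(V, 3, function(v) max(diag(v)))), 1)
    dfloor <- 1e-8 * dmax
    accepted <- FALSE
    for (try_i in 1:25) {
      Vinv <- array(0, c(3, 3, n_pts))
      ok_pt <- rep(TRUE, n_pts)
      for (j in seq_len(n_pts)) {
        Vj <- V[, , j] + lambda * diag(pmax(diag(V[, , j]), dfloor))
        inv <- tryCatch(solve(Vj), error = function(e) NULL)
        if (is.null(inv)) ok_pt[j] <- FALSE else Vinv[, , j] <- inv
      }
      S <- matrix(0, P, P)
      b <- numeric(P)
      for (ci in seq_len(n_cams)) {
        ix <- cam_off[ci] + seq_len(np[ci])
        S[ix, ix] <- U[[ci]] + lambda * diag(pmax(diag(U[[ci]]), dfloor))
        b[ix] <- gc[[ci]]
      }
      for (j in seq_len(n_pts)) {
        if (!ok_pt[j]) next
        cams_j <- which(vapply(seq_len(n_cams),
                               function(ci) j %in% js_of[[ci]], logical(1)))
        Ys <- lapply(cams_j, function(ci) {
          i <- match(j, js_of[[ci]])
          Wblocks[[ci]][[i]] %*% Vinv[, , j]
        })
        for (a_i in seq_along(cams_j)) {
          ca <- cams_j[a_i]
          ixa <- cam_off[ca] + seq_len(np[ca])
          b[ixa] <- b[ixa] - as.numeric(Ys[[a_i]] %*% gp[j, ])
          for (b_i in seq_along(cams_j)) {
            cb <- cams_j[b_i]
            ixb <- cam_off[cb] + seq_len(np[cb])
            i_b <- match(j, js_of[[cb]])
            S[ixa, ixb] <- S[ixa, ixb] -
              Ys[[a_i]] %*% t(Wblocks[[cb]][[i_b]])
          }
        }
      }
      delta_c <- tryCatch(solve(S, b), error = function(e) NULL)
      if (is.null(delta_c)) { lambda <- lambda * 5; next }
      new_cams <- cameras
      for (ci in seq_len(n_cams)) {
        par <- get_camera_params(cameras[[ci]], ci == 1) +
          delta_c[cam_off[ci] + seq_len(np[ci])]
        new_cams[[ci]] <- set_camera_params(cameras[[ci]], par, ci == 1)
      }
      new_pts <- points
      for (j in seq_len(n_pts)) {
        if (!ok_pt[j]) next
        cams_j <- which(vapply(seq_len(n_cams),
                               function(ci) j %in% js_of[[ci]], logical(1)))
        wsum <- gp[j, ]
        for (ci in cams_j) {
          i <- match(j, js_of[[ci]])
          wsum <- wsum - as.numeric(t(Wblocks[[ci]][[i]]) %*%
                                      delta_c[cam_off[ci] + seq_len(np[ci])])
        }
        new_pts[j, ] <- points[j, ] + as.numeric(Vinv[, , j] %*% wsum)
      }
      val <- objective(new_cams, new_pts)
      if (is.finite(val) && val < cur) {
        cameras <- new_cams
        points <- new_pts
        improved <- cur - val
        cur <- val
        lambda <- max(lambda / 3, 1e-12)
        accepted <- TRUE
        break
      }
      lambda <- lambda * 5
    }
    if (verbose) {
      message(sprintf("  lm iter %d: objective %.6g lambda %.3g%s", iter, cur,
                      lambda, if (accepted) "" else " [no step]"))
    }
    if (!accepted) break
    if (improved < tol * max(cur, 1e-12)) break
  }
  list(cameras = cameras, points = points, value = cur)
}

# Re-triangulate each structure point from the current cameras, keeping the
# new position only where it lowers that point's summed squared residual.
# Rescues points stranded behind a camera, where the clamped residual is
# flat and gradient-based refinement cannot move them.
retriangulate_points <- function(cameras, points, obs) {
  for (j in seq_len(nrow(points))) {
    tri <- tryCatch(triangulate(obs$uv[, j, ], cameras, obs$visible[, j]),
                    error = function(e) list(ok = FALSE))
    if (!isTRUE(tri$ok)) next
    old <- if (all(is.finite(points[j, ]))) {
      reprojection_error(points[j, ], obs$uv[, j, ], cameras,
                         obs$visible[, j])
    } else Inf
    if (tri$error < old) points[j, ] <- tri$point
  }
  points
}

# Per-camera list of per-observation residual norms.
rig_residual_norms <- function(cameras, points, obs) {
  lapply(seq_along(cameras), function(c_i) {
    js <- which(obs$visible[c_i, ])
    if (!length(js)) return(numeric(0))
    p <- project(cameras[[c_i]], points[js, , drop = FALSE], behind = "na")
    r2 <- rowSums((p - cbind(obs$uv[c_i, js, 1], obs$uv[c_i, js, 2]))^2)
    r2[!is.finite(r2)] <- 1e8
    sqrt(r2)
  })
}

#' Robust calibration objective
#'
#' `sum_c sum_j e_cj huber(|| pi_c(X_j) - x_cj ||, delta)` over all visible
#' observations.
#'
#' @param cameras list of `camera_model`.
#' @param points m x 3 matrix of structure points.
#' @param obs observation set as built by [observation_set()].
#' @param delta Huber transition, pixels.
#' @return non-negative scalar.
#' @export
robust_objective <- function(cameras, points, obs, delta = 20) {
  sum(vapply(rig_residual_norms(cameras, points, obs),
             function(r) sum(huber(r, delta)), numeric(1)))
}

#' Bundle observations into the calibration layout
#'
#' @param uv array `n_cameras x n_points x 2` of pixel detections.
#' @param visible logical `n_cameras x n_points` visibility matrix `e_cj`;
#'   defaults to finite entries of `uv`.
#' @return list of class `observation_set` with elements `uv` and `visible`.
#' @export
observation_set <- function(uv, visible = NULL) {
  stopifnot(length(dim(uv)) == 3, dim(uv)[3] == 2)
  if (is.null(visible)) visible <- is.finite(uv[, , 1]) & is.finite(uv[, , 2])
  if (is.null(dim(visible))) visible <- matrix(visible, dim(uv)[1], dim(uv)[2])
  visible <- visible & is.finite(uv[, , 1]) & is.finite(uv[, , 2])
  structure(list(uv = uv, visible = visible), class = "observation_set")
}

#' Self-calibrate the rig by Huber-robust bundle adjustment
#'
#' Jointly refines every camera's rotation, translation and radial
#' distortion (intrinsics fixed) together with the 3D positions of the
#' observed keypoints, minimizing the robust reprojection objective of
#' [robust_objective()]. The robust kernel is handled by iteratively
#' reweighted Levenberg-Marquardt: each round solves a weighted least-squares
#' problem with Huber weights frozen at the current residuals, then the
#' weights are refreshed. Points are initialized by triangulation from the
#' initial cameras (unless supplied). Camera 1's extrinsics are frozen to fix
#' the rotation/translation gauge; the global scale is pinned by rescaling
#' the mean camera-center distance to `config$ring_radius`.
#'
#' @param obs an [observation_set()]; keypoints seen by fewer than two
#'   cameras are ignored.
#' @param init list of `camera_model` giving the initial rig.
#' @param config a [calib_config()].
#' @param points optional m x 3 initial structure points.
#' @param fix_scale rescale to the ring-radius prior afterwards (default
#'   `TRUE`).
#' @param loss `"huber"` (default) or `"squared"` (no reweighting; for
#'   robustness comparisons).
#' @param trim after the robust fit converges, observations whose residual
#'   exceeds `trim * huber_delta` pixels are discarded and the fit is
#'   refined once more on the survivors (`NULL` disables). Only applies to
#'   the Huber loss.
#' @return list of class `rig_calibration`: `cameras`, `points`, `objective`,
#'   `initial_objective`, `converged`, `rms_px` (root mean squared pixel
#'   residual over the observations used - after trimming, the survivors).
#' @export
bundle_adjust <- function(obs, init, config = calib_config(), points = NULL,
                          fix_scale = TRUE, loss = c("huber", "squared"),
                          trim = 3) {
  loss <- match.arg(loss)
  stopifnot(inherits(obs, "observation_set"), length(init) == dim(obs$uv)[1])
  usable <- colSums(obs$visible) >= 2
  if (!all(usable)) {
    obs <- observation_set(obs$uv[, usable, , drop = FALSE],
                           obs$visible[, usable, drop = FALSE])
  }
  n_points <- dim(obs$uv)[2]
  if (n_points < 6) stop("too few triangulatable keypoints for calibration")
  cameras <- init
  if (is.null(points)) {
    points <- t(vapply(seq_len(n_points), function(j) {
      triangulate(obs$uv[, j, ], cameras, obs$visible[, j])$point
    }, numeric(3)))
  }
  delta <- config$huber_delta
  objective <- function(cams, pts) {
    if (loss == "huber") robust_objective(cams, pts, obs, delta)
    else sum(vapply(rig_residual_norms(cams, pts, obs),
                    function(r) sum(r^2) / 2, numeric(1)))
  }
  best <- list(cameras = cameras, points = points,
               value = objective(cameras, points))
  initial_objective <- best$value
  converged <- FALSE
  obs_used <- obs
  for (outer in seq_len(config$max_outer)) {
    pts <- retriangulate_points(best$cameras, best$points, obs)
    val <- objective(best$cameras, pts)
    if (val <= best$value) best <- list(cameras = best$cameras, points = pts,
                                        value = val)
    weights <- if (loss == "huber") {
      lapply(rig_residual_norms(best$cameras, best$points, obs),
             huber_weight, delta = delta)
    } else NULL
    fit <- sparse_bundle_lm(best$cameras, best$points, obs, weights,
                            max_iter = config$max_iterations)
    value <- objective(fit$cameras, fit$points)
    if (value <= best$value) {
      improved <- (best$value - value) > config$convergence_tol *
        max(best$value, 1e-12)
      best <- list(cameras = fit$cameras, points = fit$points, value = value)
      if (!improved || loss == "squared") { converged <- TRUE; break }
    } else {
      # reweighted step overshot the robust objective: keep the best iterate
      converged <- TRUE
      break
    }
  }
  if (loss == "huber" && !is.null(trim)) {
    # reject gross outliers the robust fit has isolated, refit on survivors
    norms <- rig_residual_norms(best$cameras, best$points, obs)
    cut <- trim * delta
    if (any(unlist(norms) > cut)) {
      obs_t <- obs
      for (ci in seq_along(best$cameras)) {
        js <- which(obs$visible[ci, ])
        obs_t$visible[ci, js[norms[[ci]] > cut]] <- FALSE
      }
      weights <- lapply(rig_residual_norms(best$cameras, best$points, obs_t),
                        huber_weight, delta = delta)
      fit <- sparse_bundle_lm(best$cameras, best$points, obs_t, weights,
                              max_iter = config$max_iterations)
      # judge the refit on the surviving observations; the discarded gross
      # outliers no longer belong to the calibration set
      trimmed_objective <- function(cams, pts) {
        sum(vapply(rig_residual_norms(cams, pts, obs_t),
                   function(r) sum(huber(r, delta)), numeric(1)))
      }
      value <- objective(fit$cameras, fit$points)
      if (trimmed_objective(fit$cameras, fit$points) <=
            trimmed_objective(best$cameras, best$points) &&
            value <= initial_objective) {
        best <- list(cameras = fit$cameras, points = fit$points,
                     value = value)
        obs_used <- obs_t
      }
    }
  }
  cameras <- best$cameras
  points <- retriangulate_points(cameras, best$points, obs_used)
  if (fix_scale) {
    centers <- t(vapply(cameras, camera_center, numeric(3)))
    s <- config$ring_radius / mean(sqrt(rowSums(centers^2)))
    cameras <- lapply(cameras, function(cam) {
      cam$translation <- s * cam$translation
      cam
    })
    points <- s * points
  }
  norms <- unlist(rig_residual_norms(cameras, points, obs_used))
  structure(list(cameras = cameras, points = points,
                 objective = objective(cameras, points),
                 initial_objective = initial_objective,
                 converged = converged,
                 rms_px = sqrt(mean(norms^2))),
            class = "rig_calibration")
}

#' @export
print.rig_calibration <- function(x, ...) {
  cat(sprintf(
    "rig calibration: %d cameras, %d points, objective %.6g (from %.6g), RMS %.3g px%s\n",
    length(x$cameras), nrow(x$points), x$objective, x$initial_objective,
    x$rms_px, if (x$converged) "" else " [not converged]"))
  invisible(x)
}
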