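# Synthetic scenes with full ground truth.
#
# Emulates the acquisition geometry this package targets: a ring of seven
# inward-looking cameras about 94 mm from a tethered fly on a spherical
# treadmill, an articulated 38-keypoint skeleton with millimetre-scale
# segments, periodic per-leg gait trajectories built by forward kinematics
# (so segment lengths are constant by construction), and detector-like
# probability maps - a sigma = 1 px Gaussian bump at each true projection,
# optional pixel noise and injected false-positive peaks. Every corruption
# is logged so tests can condition on the exact ground truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic camera ring
#'
#' Cameras on the layout of [init_extrinsics()] with optional jitter on
#' positions and orientations and radial-distortion coefficients drawn
#' uniformly within a range. Zero jitter and zero distortion reproduce the
#' initialization layout exactly.
#'
#' @param n_cameras,radius ring geometry (defaults: 7 cameras, 94 mm).
#' @param fx,fy,cx,cy,image_size shared intrinsics. The defaults give a
#'   pixel scale where 1 mm at the ring center spans about 300 px.
#' @param distortion_range range for the four radial coefficients per
#'   camera (`c(0, 0)` for ideal pinholes).
#' @param position_jitter,rotation_jitter Gaussian jitter (mm / radians).
#' @param seed RNG seed.
#' @return list of `camera_model` objects.
#' @export
make_rig <- function(n_cameras = 7, radius = 94, fx = 28000, fy = 28000,
                     cx = 480, cy = 240, image_size = c(480, 960),
                     distortion_range = c(0, 0), position_jitter = 0,
                     rotation_jitter = 0, seed = 1) {
  stopifnot(n_cameras >= 2)
  ext <- init_extrinsics(calib_config(n_cameras = n_cameras,
                                      ring_radius = radius))
  with_seed(seed, {
    lapply(seq_len(n_cameras), function(i) {
      rot <- ext[[i]]$rotation + stats::rnorm(3, 0, rotation_jitter)
      R <- rotvec_to_matrix(rot)
      C <- -as.numeric(crossprod(rotvec_to_matrix(ext[[i]]$rotation),
                                 ext[[i]]$translation))
      C <- C + stats::rnorm(3, 0, position_jitter)
      k <- stats::runif(4, distortion_range[1], distortion_range[2])
      camera_model(id = i, fx = fx, fy = fy, cx = cx, cy = cy,
                   image_size = image_size, rotation = matrix_to_rotvec(R),
                   translation = as.numeric(-R %*% C), distortion = k)
    })
  })
}

#' Default fly geometry
#'
#' Resting keypoint layout and segment lengths (mm) for the synthetic
#' articulated fly: body axis along +x (head forward), left side +y, z up.
#'
#' @return list with `leg_roots` (6 x 3 body-coxa positions, rows L1 L2 L3
#'   R1 R2 R3), `segment_lengths` (coxa, femur, tibia, tarsus), `abdomen`
#'   (per-side 3 x 3 base positions), `antenna` (per-side positions).
#' @export
fly_geometry <- function() {
  roots <- rbind(
    c(0.30, 0.15, -0.05), c(0.00, 0.17, -0.05), c(-0.30, 0.15, -0.05),
    c(0.30, -0.15, -0.05), c(0.00, -0.17, -0.05), c(-0.30, -0.15, -0.05))
  rownames(roots) <- c("L1", "L2", "L3", "R1", "R2", "R3")
  abd <- rbind(c(-0.45, 0.10, 0.00), c(-0.65, 0.09, -0.02),
               c(-0.85, 0.07, -0.05))
  list(leg_roots = roots,
       segment_lengths = c(coxa = 0.10, femur = 0.15, tibia = 0.13,
                           tarsus = 0.11),
       abdomen = abd, antenna = c(0.55, 0.06, 0.05),
       leg_tilt = c(0.5, 0, -0.5))
}

# Planar forward kinematics for one leg at one time: phi are cumulative
# segment angles (radians) in the plane spanned by b1 (outward) and b2
# (down); returns the 4 distal keypoints.
leg_chain <- function(root, b1, b2, lengths, phi) {
  p <- root
  out <- matrix(NA_real_, 4, 3)
  for (k in 1:4) {
    p <- p + lengths[k] * (cos(phi[k]) * b1 + sin(phi[k]) * b2)
    out[k, ] <- p
  }
  out
}

rot_about <- function(points, center, axis, angle) {
  R <- rotvec_to_matrix(axis / sqrt(sum(axis^2)) * angle)
  sweep(sweep(points, 2, center) %*% t(R), 2, center, "+")
}

#' Simulate periodic articulated motion
#'
#' Per-leg sinusoidal joint-angle trajectories composed through forward
#' kinematics from fixed segment lengths (so lengths are constant across
#' frames to machine precision), with opposite tripod phases, a rigid
#' abdominal wag and a rigid head (antennal) tilt. Multiple behaviors are
#' concatenated with their ground-truth labels.
#'
#' @param skeleton a [fly_skeleton()].
#' @param behaviors data.frame with columns `label`, `frequency` (Hz),
#'   `amplitude` (radians) and `n_frames`; one row per behavioral bout.
#' @param rate sampling rate, Hz.
#' @param geometry a [fly_geometry()].
#' @param seed accepted for interface uniformity; the trajectories are
#'   deterministic.
#' @return list with `poses` (T x 38 x 3 array, mm), `labels` (character,
#'   length T), `rate`.
#' @export
simulate_motion <- function(skeleton,
                            behaviors = data.frame(label = "walk",
                                                   frequency = 10,
                                                   amplitude = 0.5,
                                                   n_frames = 200),
                            rate = 100, geometry = fly_geometry(), seed = 1) {
  kp <- skeleton$keypoints
  T_total <- sum(behaviors$n_frames)
  poses <- array(NA_real_, c(T_total, nrow(kp), 3))
  labels <- character(T_total)
  base_mean <- c(0.7, 0.9, 1.3, 1.5)   # cumulative segment angles at rest
  amp_scale <- c(0.25, 1.0, 0.8, 0.6)
  phase_k <- c(0, 0.6, 1.2, 1.8)
  legs <- rownames(geometry$leg_roots)
  t0 <- 0
  for (b in seq_len(nrow(behaviors))) {
    f <- behaviors$frequency[b]; amp <- behaviors$amplitude[b]
    for (ti in seq_len(behaviors$n_frames[b])) {
      t <- (t0 + ti - 1) / rate
      frame <- matrix(NA_real_, nrow(kp), 3)
      for (li in seq_along(legs)) {
        limb <- legs[li]
        s <- if (substr(limb, 1, 1) == "L") 1 else -1
        tilt <- geometry$leg_tilt[as.integer(substr(limb, 2, 2))]
        b1 <- c(tilt, s, 0); b1 <- b1 / sqrt(sum(b1^2))
        b2 <- c(0, 0, -1)
        tripod <- if (limb %in% c("L1", "R2", "L3")) 0 else pi
        phi <- base_mean + amp * amp_scale *
          sin(2 * pi * f * t + tripod + phase_k)
        ids <- kp$id[kp$limb == limb]
        root <- geometry$leg_roots[limb, ]
        frame[ids[1], ] <- root
        frame[ids[2:5], ] <- leg_chain(root, b1, b2,
                                       geometry$segment_lengths, phi)
      }
      for (s in c(1, -1)) {
        limb <- if (s == 1) "abdL" else "abdR"
        ids <- kp$id[kp$limb == limb]
        pts <- geometry$abdomen
        pts[, 2] <- s * pts[, 2]
        wag <- 0.2 * amp * sin(2 * pi * (f / 2) * t)
        frame[ids, ] <- rot_about(pts, c(-0.4, 0, 0), c(0, 1, 0), wag)
      }
      ant <- rbind(geometry$antenna * c(1, 1, 1),
                   geometry$antenna * c(1, -1, 1))
      tiltang <- 0.3 * amp * sin(2 * pi * (f / 2) * t)
      ids <- kp$id[kp$limb == "head"]
      frame[ids, ] <- rot_about(ant, c(0.5, 0, 0.02), c(0, 1, 0), tiltang)
      poses[t0 + ti, , ] <- frame
      labels[t0 + ti] <- behaviors$label[b]
    }
    t0 <- t0 + behaviors$n_frames[b]
  }
  list(poses = poses, labels = labels, rate = rate)
}

#' Assemble a synthetic scene
#'
#' Generates a rig, a skeleton, motion, and the per-frame true 2D
#' projections of every keypoint into every camera that sees it.
#' Regeneration with the same seed reproduces the scene bit-exactly.
#'
#' @param n_frames frames of the default single-behavior motion (ignored
#'   when `behaviors` is given).
#' @param behaviors behavior table passed to [simulate_motion()].
#' @param seed master seed.
#' @param ... passed to [make_rig()].
#' @return object of class `synthetic_scene`: `rig`, `skeleton`, `poses`,
#'   `labels`, `projections` (T x n_cameras x 38 x 2; `NA` where the
#'   keypoint is invisible or behind the camera), `rate`, `seed`.
#' @export
make_scene <- function(n_frames = 100, behaviors = NULL, seed = 1, ...) {
  rig <- make_rig(seed = seed, ...)
  skeleton <- fly_skeleton(n_cameras = length(rig))
  if (is.null(behaviors)) {
    behaviors <- data.frame(label = "walk", frequency = 10, amplitude = 0.5,
                            n_frames = n_frames)
  }
  motion <- simulate_motion(skeleton, behaviors, seed = seed)
  T_n <- dim(motion$poses)[1]
  n_kp <- dim(motion$poses)[2]
  proj <- array(NA_real_, c(T_n, length(rig), n_kp, 2))
  flat <- matrix(aperm(motion$poses, c(1, 2, 3)), T_n * n_kp, 3)
  for (ci in seq_along(rig)) {
    p <- project(rig[[ci]], flat, behind = "na")
    pu <- matrix(p[, 1], T_n, n_kp)
    pv <- matrix(p[, 2], T_n, n_kp)
    invisible_kp <- !skeleton$visibility[, ci]
    pu[, invisible_kp] <- NA_real_
    pv[, invisible_kp] <- NA_real_
    proj[, ci, , 1] <- pu
    proj[, ci, , 2] <- pv
  }
  structure(list(rig = rig, skeleton = skeleton, poses = motion$poses,
                 labels = motion$labels, projections = proj,
                 rate = motion$rate, seed = seed),
            class = "synthetic_scene")
}

#' Render detector-like probability maps for one frame
#'
#' For each (camera, keypoint) pair where the keypoint is visible: a
#' Gaussian bump (sigma = `peak_sigma` map pixels, height 1) at the true
#' projection in map-grid coordinates, plus an optional uniform noise floor
#' and injected false-positive bumps. Every injected false positive is
#' logged.
#'
#' @param scene a [make_scene()] result.
#' @param frame frame index.
#' @param map_size map grid `c(rows, cols)`.
#' @param peak_sigma bump width, map pixels.
#' @param noise amplitude of additive uniform noise.
#' @param fp_rate probability of injecting a false-positive bump per map.
#' @param fp_height false-positive height relative to the true peak.
#' @param fp_min_dist minimum Chebyshev distance (map px) between a false
#'   positive and the true peak.
#' @param snap place the true bump at the nearest grid center instead of
#'   the exact (fractional) projection.
#' @param keypoints optional keypoint ids to render (default all); others
#'   get `NULL` map slots.
#' @param seed RNG seed for noise and false positives.
#' @return object of class `prob_map_stack`: `maps` (`[[camera]][[keypoint]]`,
#'   `NULL` where invisible), `corruption` (data.frame log), `frame`.
#' @export
render_maps <- function(scene, frame = 1, map_size = c(64, 128),
                        peak_sigma = 1, noise = 0, fp_rate = 0,
                        fp_height = 1.2, fp_min_dist = 5, snap = FALSE,
                        keypoints = NULL, seed = 1) {
  rig <- scene$rig
  n_kp <- dim(scene$poses)[2]
  su <- rig[[1]]$image_size[2] / map_size[2]
  sv <- rig[[1]]$image_size[1] / map_size[1]
  gx <- matrix(rep(0:(map_size[2] - 1), each = map_size[1]), map_size[1])
  gy <- matrix(rep(0:(map_size[1] - 1), map_size[2]), map_size[1])
  bump <- function(u, v, h) h * exp(-((gx - u)^2 + (gy - v)^2) /
                                      (2 * peak_sigma^2))
  log_rows <- list()
  maps <- with_seed(seed, {
    lapply(seq_along(rig), function(ci) {
      lapply(seq_len(n_kp), function(j) {
        if (!is.null(keypoints) && !(j %in% keypoints)) return(NULL)
        if (!scene$skeleton$visibility[j, ci]) return(NULL)
        uv <- scene$projections[frame, ci, j, ]
        if (any(!is.finite(uv))) return(NULL)
        um <- uv[1] / su; vm <- uv[2] / sv
        if (snap) { um <- round(um); vm <- round(vm) }
        H <- bump(um, vm, 1)
        if (noise > 0) {
          H <- H + noise * stats::runif(length(H))
        }
        if (fp_rate > 0 && stats::runif(1) < fp_rate) {
          repeat {
            fu <- stats::runif(1, 0, map_size[2] - 1)
            fv <- stats::runif(1, 0, map_size[1] - 1)
            if (max(abs(fu - um), abs(fv - vm)) >= fp_min_dist) break
          }
          H <- H + bump(fu, fv, fp_height)
          log_rows[[length(log_rows) + 1]] <<- data.frame(
            camera = ci, keypoint = j, type = "false_positive",
            u_map = fu, v_map = fv, height = fp_height)
        }
        prob_map(H, keypoint = j, camera = ci, scale = c(su, sv))
      })
    })
  })
  structure(list(maps = maps,
                 corruption = if (length(log_rows)) do.call(rbind, log_rows)
                 else data.frame(),
                 frame = frame, map_size = map_size,
                 scale = c(su, sv)),
            class = "prob_map_stack")
}

#' Displace a fraction of 2D observations
#'
#' Corrupts the stated fraction of the visible observations by a shift of
#' the given magnitude in a uniformly random direction, logging originals.
#'
#' @param obs an [observation_set()].
#' @param rate fraction of visible observations to corrupt, in `[0, 1]`.
#' @param magnitude shift length, pixels.
#' @param seed RNG seed.
#' @return list with `obs` (corrupted copy) and `log` (data.frame: `camera`,
#'   `point`, `u0`, `v0`, `u`, `v`).
#' @export
corrupt_observations <- function(obs, rate, magnitude = 100, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  vis <- which(obs$visible, arr.ind = TRUE)
  with_seed(seed, {
    n_bad <- round(rate * nrow(vis))
    pick <- if (n_bad > 0) sample(nrow(vis), n_bad) else integer(0)
    log <- data.frame(camera = integer(0), point = integer(0),
                      u0 = numeric(0), v0 = numeric(0),
                      u = numeric(0), v = numeric(0))
    for (r in pick) {
      ci <- vis[r, 1]; j <- vis[r, 2]
      th <- stats::runif(1, 0, 2 * pi)
      u0 <- obs$uv[ci, j, 1]; v0 <- obs$uv[ci, j, 2]
      obs$uv[ci, j, 1] <- u0 + magnitude * cos(th)
      obs$uv[ci, j, 2] <- v0 + magnitude * sin(th)
      log <- rbind(log, data.frame(camera = ci, point = j, u0 = u0, v0 = v0,
                                   u = obs$uv[ci, j, 1],
                                   v = obs$uv[ci, j, 2]))
    }
    list(obs = obs, log = log)
  })
}
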