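# End-to-end driver: synthetic scene (or prepared inputs) through
# calibration, candidate generation, pictorial-structures correction,
# quality control and (optionally) the behavioral embedding.

#' Pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param n_frames frames to simulate.
#' @param behaviors optional behavior table for [simulate_motion()].
#' @param calibrate re-estimate the rig by [bundle_adjust()] from detections
#'   instead of using the scene's true rig.
#' @param n_peaks peaks per probability map.
#' @param noise,fp_rate map corruption levels for [render_maps()].
#' @param reproj_cutoff reprojection cutoff (squared px) for prior learning.
#' @param embed run the behavioral-embedding stage (needs enough frames for
#'   the t-SNE perplexity).
#' @param perplexity t-SNE perplexity for the embedding stage.
#' @param out_dir optional directory; when set, the rig, priors, poses and
#'   a run log are written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_frames = 20, behaviors = NULL,
                            calibrate = FALSE, n_peaks = 3, noise = 0.05,
                            fp_rate = 0, reproj_cutoff = 100, embed = FALSE,
                            perplexity = 35, out_dir = NULL) {
  structure(list(seed = seed, n_frames = n_frames, behaviors = behaviors,
                 calibrate = calibrate, n_peaks = n_peaks, noise = noise,
                 fp_rate = fp_rate, reproj_cutoff = reproj_cutoff,
                 embed = embed, perplexity = perplexity, out_dir = out_dir),
            class = "pipeline_config")
}

# Per-frame best-peak detections from a list of map stacks.
peak_detections <- function(stacks, rig, n_kp) {
  T_n <- length(stacks)
  det <- array(NA_real_, c(T_n, length(rig), n_kp, 2))
  for (t in seq_len(T_n)) {
    for (ci in seq_along(rig)) {
      for (j in seq_len(n_kp)) {
        m <- stacks[[t]]$maps[[ci]][[j]]
        if (is.null(m)) next
        pk <- local_maxima(m, n = 1)
        if (nrow(pk)) det[t, ci, j, ] <- c(pk$u[1], pk$v[1])
      }
    }
  }
  det
}

#' Run the full pose-estimation pipeline on a synthetic scene
#'
#' Stages: scene generation; optional rig self-calibration (epipolar-pruned
#' detections, bundle adjustment from the ring-layout initialization);
#' probability-map rendering; a first pass of best-peak triangulation that
#' feeds segment-prior learning; pictorial-structures correction of every
#' frame; reprojection-based frame scoring; and, when requested, the
#' behavioral embedding and map. Reruns with an identical configuration are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `poses` (T x 38 x 3), `resolved`,
#'   `solutions`, `scores` ([score_frames()] result), `priors`, `rig`
#'   (the rig used), `scene`, `embedding`/`map` (when `embed = TRUE`),
#'   `log` (stage timings and counts).
#' @export
pipeline_run <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, value, t0) {
    log[[name]] <<- c(seconds = round(tic() - t0, 3), value)
  }
  t0 <- tic()
  scene <- make_scene(n_frames = config$n_frames,
                      behaviors = config$behaviors, seed = config$seed)
  n_kp <- dim(scene$poses)[2]
  T_n <- dim(scene$poses)[1]
  stage("scene", c(frames = T_n, keypoints = n_kp), t0)

  t0 <- tic()
  rig <- scene$rig
  if (config$calibrate) {
    cc <- calib_config(n_cameras = length(rig))
    frames <- unique(round(seq(1, T_n, length.out = min(T_n, 10))))
    uv <- array(NA_real_, c(length(rig), length(frames) * n_kp, 2))
    for (fi in seq_along(frames)) {
      for (j in seq_len(n_kp)) {
        col <- (fi - 1) * n_kp + j
        obs_uv <- scene$projections[frames[fi], , j, ]
        pr <- epipolar_prune(obs_uv, rig = NULL,
                             threshold = cc$epipolar_row_threshold)
        obs_uv[!pr$visible, ] <- NA_real_
        uv[, col, ] <- obs_uv
      }
    }
    init <- make_rig(n_cameras = length(rig), distortion_range = c(0, 0),
                     seed = config$seed)
    ba <- bundle_adjust(observation_set(uv), init, cc)
    rig <- ba$cameras
    stage("calibrate", c(objective = ba$objective, rms_px = ba$rms_px), t0)
  } else {
    stage("calibrate", c(skipped = 1), t0)
  }

  t0 <- tic()
  stacks <- lapply(seq_len(T_n), function(t) {
    render_maps(scene, frame = t, noise = config$noise,
                fp_rate = config$fp_rate, seed = config$seed + t)
  })
  stage("maps", c(frames = T_n), t0)

  t0 <- tic()
  det <- peak_detections(stacks, rig, n_kp)
  first_pass <- score_frames(det, rig, visible = t(scene$skeleton$visibility))
  priors <- learn_segment_priors(first_pass$points, scene$skeleton,
                                 reproj = first_pass$residuals,
                                 reproj_cutoff = config$reproj_cutoff,
                                 min_samples = min(30, T_n))
  stage("priors", c(edges = length(priors)), t0)

  t0 <- tic()
  poses <- array(NA_real_, c(T_n, n_kp, 3))
  resolved <- matrix(FALSE, T_n, n_kp)
  solutions <- vector("list", T_n)
  for (t in seq_len(T_n)) {
    cands <- lapply(seq_len(n_kp), function(j) {
      maps_j <- lapply(stacks[[t]]$maps, function(cm) cm[[j]])
      generate_candidates(maps_j, rig,
                          visible = scene$skeleton$visibility[j, ],
                          n_peaks = config$n_peaks)
    })
    sol <- map_solve(cands, scene$skeleton, priors, stacks[[t]]$maps, rig)
    solutions[[t]] <- sol
    poses[t, , ] <- sol$points
    resolved[t, ] <- sol$resolved
  }
  stage("correct", c(resolved = mean(resolved)), t0)

  t0 <- tic()
  chosen <- array(NA_real_, c(T_n, length(rig), n_kp, 2))
  for (t in seq_len(T_n)) chosen[t, , , ] <- solutions[[t]]$observations
  scores <- score_frames(chosen, rig, visible = t(scene$skeleton$visibility))
  stage("qa", c(threshold = scores$threshold), t0)

  embedding <- NULL; bmap <- NULL
  if (config$embed) {
    t0 <- tic()
    sm <- smooth_poses(poses, rate = scene$rate)
    ang <- compute_angles(sm, scene$skeleton, rate = scene$rate)
    feats <- normalize_features(wavelet_features(ang))
    embedding <- tsne_embed(feats, perplexity = config$perplexity,
                            seed = config$seed)
    bmap <- behavior_map(embedding)
    stage("embed", c(regions = bmap$n_regions), t0)
  }

  result <- structure(list(poses = poses, resolved = resolved,
                           solutions = solutions, scores = scores,
                           priors = priors, rig = rig, scene = scene,
                           embedding = embedding, map = bmap,
                           config = config, log = log),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rig(rig, file.path(config$out_dir, "rig.yaml"))
    write_priors(priors, file.path(config$out_dir, "priors.yaml"))
    write_poses(poses, file.path(config$out_dir, "poses.csv"), resolved)
    writeLines(yaml::as.yaml(list(seed = config$seed, log = log)),
               file.path(config$out_dir, "run_log.yaml"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d frames, %.1f%% keypoints resolved\n",
              dim(x$poses)[1], 100 * mean(x$resolved)))
  invisible(x)
}
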