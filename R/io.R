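# Readers and writers for the package's plain-text formats.
#
# All artifacts are diffable text: annotations and pose archives as CSV,
# the camera rig and the segment priors as YAML. The annotation schema is
# frame, camera, keypoint (name), u, v, source - one row per (frame,
# camera, keypoint), coordinates in the 0-based pixel convention of the
# geometry module.

annotation_columns <- c("frame", "camera", "keypoint", "u", "v", "source")
annotation_sources <- c("manual", "network", "pictorial", "pinned")

#' Read an annotation table
#'
#' @param path CSV file with columns `frame`, `camera`, `keypoint`, `u`,
#'   `v`, `source`.
#' @param skeleton optional skeleton; when given, keypoint names are checked
#'   against it and offending rows reported.
#' @return data.frame of class `annotation_table`.
#' @export
read_annotations <- function(path, skeleton = NULL) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    warning("empty annotation file")
    df <- stats::setNames(
      data.frame(integer(0), integer(0), character(0), numeric(0),
                 numeric(0), character(0)), annotation_columns)
    class(df) <- c("annotation_table", "data.frame")
    return(df)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df, skeleton)
}

#' Validate an annotation table
#'
#' @param df data.frame in the annotation schema.
#' @param skeleton optional skeleton for keypoint-name checking.
#' @return the validated table with class `annotation_table`.
#' @export
validate_annotations <- function(df, skeleton = NULL) {
  missing_cols <- setdiff(annotation_columns, names(df))
  if (length(missing_cols)) {
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(df$u) | !is.finite(df$v) | is.na(df$frame) |
                 is.na(df$camera) | !df$source %in% annotation_sources)
  if (length(bad)) {
    stop("malformed annotation row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(df$frame, df$camera, df$keypoint)
  if (anyDuplicated(key)) {
    stop("duplicate (frame, camera, keypoint) at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  if (!is.null(skeleton)) {
    unknown <- which(!df$keypoint %in% skeleton$keypoints$name)
    if (length(unknown)) {
      stop("unknown keypoint name(s) at row(s): ",
           paste(utils::head(unknown, 5), collapse = ", "),
           " (e.g. '", df$keypoint[unknown[1]], "')")
    }
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Write an annotation table
#'
#' @param df annotation table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_annotations <- function(df, path) {
  utils::write.csv(df[annotation_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write / read a camera rig file
#'
#' One YAML document holding, per camera: id, intrinsics, image size,
#' axis-angle rotation, translation and the four radial-distortion
#' coefficients; the round trip is lossless to full double precision.
#'
#' @param cameras list of `camera_model`.
#' @param path file path.
#' @return `write_rig`: the path, invisibly; `read_rig`: list of
#'   `camera_model`.
#' @export
write_rig <- function(cameras, path) {
  doc <- list(cameras = lapply(cameras, function(cam) {
    list(id = cam$id, fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
         image_size = as.list(cam$image_size),
         rotation = as.list(cam$rotation),
         translation = as.list(cam$translation),
         distortion = as.list(cam$distortion),
         distortion_frame = cam$distortion_frame)
  }))
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' @rdname write_rig
#' @export
read_rig <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc$cameras, function(x) {
    camera_model(id = x$id, fx = x$fx, fy = x$fy, cx = x$cx, cy = x$cy,
                 image_size = unlist(x$image_size),
                 rotation = unlist(x$rotation),
                 translation = unlist(x$translation),
                 distortion = unlist(x$distortion),
                 distortion_frame = x$distortion_frame)
  })
}

#' Write / read segment priors
#'
#' YAML serialization of a named list of [segment_prior()] objects,
#' including family, parameters and sample counts.
#'
#' @param priors named list of `segment_prior`.
#' @param path file path.
#' @return `write_priors`: the path, invisibly; `read_priors`: the list.
#' @export
write_priors <- function(priors, path) {
  doc <- lapply(priors, function(p) {
    list(from = p$from, to = p$to, family = p$family, mu = p$mu,
         sigma = p$sigma, alpha = p$alpha, beta = p$beta,
         length_scale = p$length_scale, n_samples = p$n_samples,
         informative = p$informative)
  })
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(x) {
    segment_prior(x$from, x$to, x$family,
                  mu = x$mu %||% NA_real_, sigma = x$sigma %||% NA_real_,
                  alpha = x$alpha %||% NA_real_, beta = x$beta %||% NA_real_,
                  length_scale = x$length_scale %||% NA_real_,
                  n_samples = x$n_samples %||% 0L,
                  informative = isTRUE(x$informative))
  })
}

#' Write / read a pose archive
#'
#' Long-format CSV (`frame`, `keypoint`, `x`, `y`, `z`, `resolved`) of a
#' T x n_keypoints x 3 pose array in mm.
#'
#' @param poses T x n_keypoints x 3 array.
#' @param path file path.
#' @param resolved optional T x n_keypoints logical matrix.
#' @return `write_poses`: the path, invisibly; `read_poses`: list with
#'   `poses` and `resolved`.
#' @export
write_poses <- function(poses, path, resolved = NULL) {
  T_n <- dim(poses)[1]; n_kp <- dim(poses)[2]
  if (is.null(resolved)) resolved <- !is.na(poses[, , 1, drop = FALSE][, , 1])
  if (is.null(dim(resolved))) resolved <- matrix(resolved, T_n, n_kp)
  df <- data.frame(frame = rep(seq_len(T_n), n_kp),
                   keypoint = rep(seq_len(n_kp), each = T_n),
                   x = as.numeric(poses[, , 1]),
                   y = as.numeric(poses[, , 2]),
                   z = as.numeric(poses[, , 3]),
                   resolved = as.logical(resolved))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path) {
  df <- utils::read.csv(path)
  T_n <- max(df$frame); n_kp <- max(df$keypoint)
  poses <- array(NA_real_, c(T_n, n_kp, 3))
  resolved <- matrix(FALSE, T_n, n_kp)
  idx <- cbind(df$frame, df$keypoint)
  for (d in 1:3) poses[cbind(idx, d)] <- df[[c("x", "y", "z")[d]]]
  resolved[idx] <- df$resolved
  list(poses = poses, resolved = resolved)
}
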