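# Multi-view quality control and active-learning frame selection.
#
# The redundancy of the camera ring turns the reprojection error into an
# error detector: frames whose triangulated keypoints disagree with their 2D
# detections across views are flagged, ranked and (up to a budget) selected
# for manual annotation; the rest are treated as automatically corrected.

#' Score frames by multi-view reprojection inconsistency
#'
#' Triangulates every keypoint of every frame from its 2D detections and
#' records the summed squared reprojection residual; the frame aggregate is
#' the maximum (default), sum or mean over keypoints.
#'
#' @param detections `T x n_cameras x n_keypoints x 2` array of 2D
#'   detections (pixels; `NA` for missing).
#' @param rig list of `camera_model`.
#' @param visible optional `n_cameras x n_keypoints` visibility matrix
#'   applied to every frame.
#' @param aggregate `"max"`, `"sum"` or `"mean"`.
#' @param threshold aggregate value above which a frame is flagged
#'   `needs_annotation`; default is the 95th percentile of the aggregates.
#' @return list of class `frame_scores`: `scores` (data.frame: `frame`,
#'   `aggregate`, `flag`), `residuals` (T x n_keypoints), `points`
#'   (T x n_keypoints x 3 triangulated positions), `threshold`.
#' @export
score_frames <- function(detections, rig, visible = NULL,
                         aggregate = c("max", "sum", "mean"),
                         threshold = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(dim(detections)) == 4, dim(detections)[4] == 2,
            dim(detections)[2] == length(rig))
  T_n <- dim(detections)[1]; n_kp <- dim(detections)[3]
  residuals <- matrix(NA_real_, T_n, n_kp)
  points <- array(NA_real_, c(T_n, n_kp, 3))
  for (t in seq_len(T_n)) {
    for (j in seq_len(n_kp)) {
      uv <- detections[t, , j, ]
      vis <- rowSums(is.finite(uv)) == 2
      if (!is.null(visible)) vis <- vis & visible[, j]
      if (sum(vis) < 2) next
      tri <- triangulate(uv, rig, vis)
      if (tri$ok) {
        residuals[t, j] <- tri$error
        points[t, j, ] <- tri$point
      }
    }
  }
  agg <- apply(residuals, 1, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) return(NA_real_)
    switch(aggregate, max = max(r), sum = sum(r), mean = mean(r))
  })
  if (is.null(threshold)) {
    threshold <- stats::quantile(agg, 0.95, na.rm = TRUE, names = FALSE)
  }
  scores <- data.frame(frame = seq_len(T_n), aggregate = agg,
                       flag = ifelse(is.finite(agg) & agg > threshold,
                                     "needs_annotation", "auto_corrected"))
  structure(list(scores = scores, residuals = residuals, points = points,
                 threshold = threshold),
            class = "frame_scores")
}

#' Select frames for manual annotation
#'
#' Frames whose aggregate score exceeds the threshold, ranked by descending
#' score and truncated to the budget.
#'
#' @param scores a [score_frames()] result (or its `scores` data.frame).
#' @param budget maximum number of frames to return (>= 0).
#' @param threshold selection cutoff; defaults to the threshold stored in
#'   `scores`.
#' @return integer vector of frame ids.
#' @export
select_for_annotation <- function(scores, budget, threshold = NULL) {
  stopifnot(budget >= 0)
  df <- if (inherits(scores, "frame_scores")) scores$scores else scores
  if (is.null(threshold)) {
    threshold <- if (inherits(scores, "frame_scores")) scores$threshold else 0
  }
  cand <- df[is.finite(df$aggregate) & df$aggregate > threshold, , drop = FALSE]
  cand <- cand[order(-cand$aggregate), , drop = FALSE]
  utils::head(cand$frame, budget)
}

#' 2D accuracy metrics: PCK, RMSE and MAE
#'
#' PCK is the percentage of predictions within `pck_threshold` pixels of the
#' ground truth, over all keypoints. RMSE (root mean squared pixel distance),
#' MAE and the per-keypoint MAE omit the excluded keypoints - by default the
#' body-coxa and coxa-femur joints, which barely move and would otherwise
#' dominate the averages.
#'
#' @param predictions,truth n x 2 matrices of pixel coordinates, row-aligned.
#' @param keypoint character/factor vector naming the keypoint class of each
#'   row (used for exclusions and the per-keypoint breakdown); optional.
#' @param pck_threshold PCK radius, pixels.
#' @param exclude keypoint classes excluded from RMSE/MAE.
#' @return list with `pck` (percent), `rmse`, `mae`, `per_keypoint_mae`,
#'   and `n`.
#' @export
evaluate_2d <- function(predictions, truth, keypoint = NULL,
                        pck_threshold = 50,
                        exclude = c("body_coxa", "coxa_femur")) {
  predictions <- as.matrix(predictions); truth <- as.matrix(truth)
  stopifnot(ncol(predictions) == 2, all(dim(predictions) == dim(truth)))
  ok <- rowSums(is.finite(predictions)) == 2 & rowSums(is.finite(truth)) == 2
  if (!any(ok)) stop("no overlapping finite prediction/truth keypoints")
  d <- sqrt(rowSums((predictions - truth)^2))
  pck <- 100 * mean(d[ok] <= pck_threshold)
  keep <- ok
  if (!is.null(keypoint)) keep <- keep & !(as.character(keypoint) %in% exclude)
  rmse <- sqrt(mean(d[keep]^2))
  mae <- mean(d[keep])
  per_kp <- if (!is.null(keypoint)) {
    tapply(d[keep], as.character(keypoint)[keep], mean)
  } else NULL
  list(pck = pck, rmse = rmse, mae = mae, per_keypoint_mae = per_kp,
       n = sum(ok))
}
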