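# Multiple-hypothesis extraction from detector probability maps.
#
# A 2D keypoint detector emits, per camera and keypoint, a grid of
# non-negative scores ("probability map"; the scores need not sum to one).
# Instead of keeping only the global argmax, several local maxima are
# retained per map and triangulated pairwise across cameras into 3D
# candidates, which the pictorial-structures stage later disambiguates.

#' Construct a probability map
#'
#' @param values rows x cols matrix of non-negative scores (default grid is
#'   64 x 128).
#' @param keypoint integer keypoint id.
#' @param camera integer camera id.
#' @param scale length-2 factor `c(su, sv)` mapping map-grid pixel
#'   coordinates to acquisition-image pixel coordinates
#'   (`u_image = u_map * su`).
#' @return object of class `prob_map`.
#' @export
prob_map <- function(values, keypoint = NA_integer_, camera = NA_integer_,
                     scale = c(1, 1)) {
  stopifnot(is.matrix(values), all(values >= 0), length(scale) == 2,
            all(scale > 0))
  structure(list(values = values, keypoint = as.integer(keypoint),
                 camera = as.integer(camera), scale = as.numeric(scale)),
            class = "prob_map")
}

#' Extract separated local maxima from a probability map
#'
#' Finds grid cells with positive score that are at least as large as all
#' eight neighbors and strictly larger than at least one of them (so flat
#' plateaus - in particular the zero background - yield no maxima), then
#' greedily keeps up to `n` of them in descending score order (ties broken
#' row-major: smaller row, then smaller column), subject to every kept pair
#' being more than `min_separation` apart in Chebyshev distance on the map
#' grid.
#'
#' @param map a [prob_map()].
#' @param n maximum number of maxima to return.
#' @param min_separation minimum pairwise Chebyshev separation, map pixels.
#' @return data.frame with columns `u`, `v` (acquisition-image frame, via the
#'   map's scale), `u_map`, `v_map` (0-based grid coordinates) and `score`,
#'   sorted by descending score. Fewer than `n` rows when fewer separated
#'   maxima exist.
#' @export
local_maxima <- function(map, n = 10, min_separation = 1) {
  H <- map$values
  nr <- nrow(H); nc <- ncol(H)
  stopifnot(nr >= 1, nc >= 1, n >= 1)
  P <- matrix(-Inf, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- H
  Phi <- matrix(Inf, nr + 2, nc + 2)   # +Inf pad: out-of-bounds never "lower"
  Phi[2:(nr + 1), 2:(nc + 1)] <- H
  ismax <- matrix(TRUE, nr, nc)
  haslower <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (H >= P[2:(nr + 1) + dr, 2:(nc + 1) + dc])
    haslower <- haslower | (H > Phi[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  idx <- which(ismax & haslower & H > 0, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(u = numeric(0), v = numeric(0), u_map = numeric(0),
                      v_map = numeric(0), score = numeric(0)))
  }
  sc <- H[idx]
  ord <- order(-sc, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  sc <- sc[ord]
  keep_r <- integer(0); keep_c <- integer(0)
  for (i in seq_len(nrow(idx))) {
    if (length(keep_r)) {
      cheb <- pmax(abs(keep_r - idx[i, 1]), abs(keep_c - idx[i, 2]))
      if (any(cheb <= min_separation)) next
    }
    keep_r <- c(keep_r, idx[i, 1]); keep_c <- c(keep_c, idx[i, 2])
    if (length(keep_r) == n) break
  }
  sel <- match(paste(keep_r, keep_c), paste(idx[, 1], idx[, 2]))
  v_map <- keep_r - 1
  u_map <- keep_c - 1
  data.frame(u = u_map * map$scale[1], v = v_map * map$scale[2],
             u_map = u_map, v_map = v_map, score = sc[sel])
}

#' Triangulate peak pairs into 3D keypoint candidates
#'
#' For every unordered pair of visible cameras and every pair of their map
#' peaks, triangulates a 3D hypothesis through the calibrated rig. With `v`
#' visible cameras and up to `n_peaks` peaks per map, at most
#' `choose(v, 2) * n_peaks^2` candidates result.
#'
#' @param maps list of [prob_map()] (or `NULL`), one slot per camera in
#'   `rig`, all for the same keypoint.
#' @param rig list of `camera_model`.
#' @param visible logical per-camera visibility `e_cj` for this keypoint.
#' @param n_peaks peaks retained per map.
#' @param min_separation peak separation, map pixels.
#' @return object of class `candidate_set`: list with `keypoint`, `points`
#'   (N x 3 matrix, mm), `support` (data.frame: `cam1`, `cam2`, `u1`, `v1`,
#'   `u2`, `v2`, `score1`, `score2`), `error` (per-candidate summed squared
#'   reprojection error over the supporting pair), and `flag`
#'   (`"ok"` or `"too_few_views"`).
#' @export
generate_candidates <- function(maps, rig, visible = NULL, n_peaks = 10,
                                min_separation = 1) {
  if (is.null(visible)) visible <- !vapply(maps, is.null, logical(1))
  visible <- as.logical(visible) & !vapply(maps, is.null, logical(1))
  keypoint <- NA_integer_
  for (m in maps) if (!is.null(m)) { keypoint <- m$keypoint; break }
  empty <- function(flag) {
    structure(list(keypoint = keypoint, points = matrix(numeric(0), 0, 3),
                   support = data.frame(), error = numeric(0), flag = flag),
              class = "candidate_set")
  }
  vis_idx <- which(visible)
  if (length(vis_idx) < 2) return(empty("too_few_views"))
  peaks <- lapply(vis_idx, function(ci) {
    local_maxima(maps[[ci]], n = n_peaks, min_separation = min_separation)
  })
  points <- list(); rows <- list(); errs <- numeric(0)
  pair_idx <- utils::combn(seq_along(vis_idx), 2)
  for (p in seq_len(ncol(pair_idx))) {
    i1 <- pair_idx[1, p]; i2 <- pair_idx[2, p]
    c1 <- vis_idx[i1]; c2 <- vis_idx[i2]
    pk1 <- peaks[[i1]]; pk2 <- peaks[[i2]]
    if (!nrow(pk1) || !nrow(pk2)) next
    for (a in seq_len(nrow(pk1))) for (b in seq_len(nrow(pk2))) {
      uv <- matrix(NA_real_, length(rig), 2)
      uv[c1, ] <- c(pk1$u[a], pk1$v[a])
      uv[c2, ] <- c(pk2$u[b], pk2$v[b])
      tri <- triangulate(uv, rig)
      if (!tri$ok) next
      points[[length(points) + 1]] <- tri$point
      errs <- c(errs, tri$error)
      rows[[length(rows) + 1]] <- data.frame(
        cam1 = c1, cam2 = c2, u1 = pk1$u[a], v1 = pk1$v[a],
        u2 = pk2$u[b], v2 = pk2$v[b],
        score1 = pk1$score[a], score2 = pk2$score[b])
    }
  }
  if (!length(points)) return(empty("ok"))
  structure(list(keypoint = keypoint,
                 points = do.call(rbind, points),
                 support = do.call(rbind, rows),
                 error = errs, flag = "ok"),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set for keypoint %s: %d candidates [%s]\n",
              x$keypoint, nrow(x$points), x$flag))
  invisible(x)
}
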