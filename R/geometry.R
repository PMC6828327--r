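# Projection model and triangulation for a multi-camera rig.
#
# Pixel convention used throughout the package: 0-based coordinates,
# u = column, v = row, origin at the top-left corner, integer coordinates at
# pixel centers. World units are millimetres.

skew3 <- function(r) {
  matrix(c(0, r[3], -r[2],
           -r[3], 0, r[1],
           r[2], -r[1], 0), 3, 3)
}

#' Convert an axis-angle rotation vector to a rotation matrix
#'
#' The rotation vector encodes the axis as its direction and the angle
#' (radians) as its norm; the expansion is the matrix exponential (Rodrigues
#' formula). Near zero angle a second-order Taylor expansion is used.
#'
#' @param r numeric length-3 rotation vector.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
rotvec_to_matrix <- function(r) {
  stopifnot(length(r) == 3, all(is.finite(r)))
  th <- sqrt(sum(r^2))
  if (th < 1e-9) {
    K <- skew3(r)
    return(diag(3) + K + 0.5 * K %*% K)
  }
  K <- skew3(r / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Convert a rotation matrix to an axis-angle rotation vector
#'
#' Inverse of [rotvec_to_matrix()]; the returned angle lies in `[0, pi]`.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector.
#' @export
matrix_to_rotvec <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == 3))
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  R <- unname(R)
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  st <- sqrt(sum(w^2)) / 2
  th <- atan2(st, ct)          # well-conditioned near both 0 and pi
  if (th < 1e-7) {
    return(w / 2)
  }
  if (st < 1e-9 && ct < 0) {
    # near pi the skew part vanishes; recover the axis from R + I
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    i <- which.max(axis)
    axis <- B[, i] / axis[i]
    axis <- axis / sqrt(sum(axis^2))
    # fix the sign using the (possibly tiny) skew part
    if (sum(axis * w) < 0) axis <- -axis
    return(th * axis)
  }
  th * w / (2 * st)
}

#' Construct a camera model
#'
#' Bundles the intrinsics (focal scalings and principal point, fixed during
#' calibration), the extrinsics (axis-angle rotation and translation mapping
#' world to camera coordinates, `Xc = R X + T`), and four radial-distortion
#' coefficients. The distortion model scales coordinates by
#' `1 + k1 r^2 + k2 r^4` with separate coefficients for the u and v axes; by
#' default the radius and the scaling act on principal-point-centered,
#' focal-normalized coordinates (`distortion_frame = "normalized"`), with a
#' literal raw-pixel variant available as `distortion_frame = "raw"`.
#'
#' @param id integer camera identifier, unique within a rig.
#' @param fx,fy focal scalings in pixels (positive).
#' @param cx,cy principal point in pixels.
#' @param image_size integer pair `c(rows, cols)`.
#' @param rotation axis-angle rotation vector (length 3).
#' @param translation translation vector in mm (length 3).
#' @param distortion radial coefficients `c(k1x, k2x, k1y, k2y)`.
#' @param distortion_frame `"normalized"` (default) or `"raw"`.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(id, fx, fy, cx, cy, image_size,
                         rotation = c(0, 0, 0),
                         translation = c(0, 0, 0),
                         distortion = c(0, 0, 0, 0),
                         distortion_frame = c("normalized", "raw")) {
  distortion_frame <- match.arg(distortion_frame)
  stopifnot(fx > 0, fy > 0, is.finite(cx), is.finite(cy),
            length(image_size) == 2, all(image_size > 0),
            length(rotation) == 3, length(translation) == 3,
            length(distortion) == 4, all(is.finite(distortion)))
  cam <- list(id = as.integer(id), fx = fx, fy = fy, cx = cx, cy = cy,
              image_size = as.integer(image_size),
              rotation = as.numeric(rotation),
              translation = as.numeric(translation),
              distortion = as.numeric(distortion),
              distortion_frame = distortion_frame)
  class(cam) <- "camera_model"
  cam
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera %d: fx=%.6g fy=%.6g c=(%.6g, %.6g) image %dx%d\n",
              x$id, x$fx, x$fy, x$cx, x$cy, x$image_size[1], x$image_size[2]))
  cat(sprintf("  rotation (axis-angle): %s\n", paste(signif(x$rotation, 6), collapse = " ")))
  cat(sprintf("  translation (mm): %s\n", paste(signif(x$translation, 6), collapse = " ")))
  cat(sprintf("  distortion: %s [%s]\n", paste(signif(x$distortion, 6), collapse = " "),
              x$distortion_frame))
  invisible(x)
}

#' Camera center in world coordinates
#'
#' @param camera a `camera_model`.
#' @return length-3 numeric vector, mm.
#' @export
camera_center <- function(camera) {
  R <- rotvec_to_matrix(camera$rotation)
  as.numeric(-crossprod(R, camera$translation))
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    points <- matrix(points, 1, 3)
  }
  stopifnot(ncol(points) == 3)
  points
}

# Forward radial scaling: undistorted = distorted * (1 + k1 r^2 + k2 r^4),
# radius taken on the distorted coordinates. Works on centered coordinates
# (normalized frame) or raw pixels (raw frame).
radial_forward <- function(x, y, k) {
  r2 <- x^2 + y^2
  cbind(x * (1 + k[1] * r2 + k[2] * r2^2),
        y * (1 + k[3] * r2 + k[4] * r2^2))
}

# Numerical inverse of radial_forward by fixed-point iteration: given the
# undistorted coordinates, recover the distorted ones.
radial_inverse <- function(xu, yu, k, tol = 1e-14, max_iter = 200) {
  x <- xu
  y <- yu
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    xn <- xu / (1 + k[1] * r2 + k[2] * r2^2)
    yn <- yu / (1 + k[3] * r2 + k[4] * r2^2)
    delta <- max(abs(xn - x), abs(yn - y), 0)
    x <- xn
    y <- yn
    if (is.finite(delta) && delta < tol) break
  }
  cbind(x, y)
}

#' Project world points through a camera
#'
#' Applies the extrinsic transform, the pinhole projection and the radial
#' distortion, returning the pixel coordinates at which the point would be
#' observed. With zero distortion this is the pure pinhole projection
#' `u = fx x/z + cx`, `v = fy y/z + cy` in camera coordinates.
#'
#' @param camera a `camera_model`.
#' @param points length-3 vector or n x 3 matrix of world points (mm).
#' @param behind `"error"` (default) to signal points at or behind the optical
#'   plane (camera-frame z <= 0), or `"na"` to return `NA` rows for them.
#' @return n x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project <- function(camera, points, behind = c("error", "na")) {
  behind <- match.arg(behind)
  points <- as_points_matrix(points)
  R <- rotvec_to_matrix(camera$rotation)
  Xc <- points %*% t(R) + rep(camera$translation, each = nrow(points))
  z <- Xc[, 3]
  bad <- !(z > 0)
  if (any(bad)) {
    if (behind == "error") {
      stop("point at or behind the optical plane (camera-frame z <= 0)")
    }
  }
  z[bad] <- NA_real_
  xn <- Xc[, 1] / z
  yn <- Xc[, 2] / z
  k <- camera$distortion
  if (all(k == 0)) {
    uv <- cbind(camera$fx * xn + camera$cx, camera$fy * yn + camera$cy)
  } else if (camera$distortion_frame == "normalized") {
    d <- radial_inverse(xn, yn, k)
    uv <- cbind(camera$fx * d[, 1] + camera$cx, camera$fy * d[, 2] + camera$cy)
  } else {
    up <- camera$fx * xn + camera$cx
    vp <- camera$fy * yn + camera$cy
    uv <- radial_inverse(up, vp, k)
  }
  colnames(uv) <- c("u", "v")
  uv
}

#' Correct observed pixel coordinates for radial distortion
#'
#' Maps observed (distorted) pixel coordinates to the coordinates the ideal
#' pinhole model would have produced, by applying the radial scaling
#' `1 + k1 r^2 + k2 r^4` evaluated at the observation's own radius. With all
#' coefficients zero, and at the principal point (r = 0), this is the
#' identity.
#'
#' @param camera a `camera_model`.
#' @param uv length-2 vector or n x 2 matrix of observed pixel coordinates.
#' @return n x 2 matrix of distortion-corrected pixel coordinates.
#' @export
to_pinhole <- function(camera, uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2)
  stopifnot(ncol(uv) == 2)
  if (!all(is.finite(uv))) stop("invalid observation: non-finite coordinates")
  oob <- uv[, 1] < 0 | uv[, 1] > camera$image_size[2] - 1 |
    uv[, 2] < 0 | uv[, 2] > camera$image_size[1] - 1
  if (any(oob)) {
    warning(sprintf("%d observation(s) outside the image bounds", sum(oob)))
  }
  k <- camera$distortion
  if (camera$distortion_frame == "normalized") {
    xn <- (uv[, 1] - camera$cx) / camera$fx
    yn <- (uv[, 2] - camera$cy) / camera$fy
    p <- radial_forward(xn, yn, k)
    out <- cbind(camera$fx * p[, 1] + camera$cx, camera$fy * p[, 2] + camera$cy)
  } else {
    out <- radial_forward(uv[, 1], uv[, 2], k)
  }
  colnames(out) <- c("u", "v")
  out
}

#' Triangulate a 3D point from multiple 2D observations
#'
#' Observed coordinates are first distortion-corrected with [to_pinhole()],
#' then the point is recovered as the linear-least-squares solution of the
#' homogeneous DLT system (two rows per camera, in focal-normalized
#' coordinates), via SVD. The residual reprojection error through the full
#' distorted projection is reported alongside.
#'
#' @param uv n_cameras x 2 matrix of observed pixel coordinates (rows aligned
#'   with `cameras`; invisible rows may hold `NA`).
#' @param cameras list of `camera_model` objects.
#' @param visible logical vector of per-camera visibility flags `e_c`;
#'   defaults to rows of `uv` that are finite.
#' @return list with `point` (length-3, mm), `error` (summed squared pixel
#'   reprojection error over visible cameras), `ok` (logical; `FALSE` for a
#'   degenerate SVD system), `n_views`.
#' @export
triangulate <- function(uv, cameras, visible = NULL) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2, byrow = TRUE)
  stopifnot(length(cameras) == nrow(uv))
  if (is.null(visible)) visible <- rowSums(is.finite(uv)) == 2
  visible <- as.logical(visible) & rowSums(is.finite(uv)) == 2
  idx <- which(visible)
  if (length(idx) < 2) {
    stop("untriangulatable keypoint: fewer than two visible observations")
  }
  A <- matrix(0, 2 * length(idx), 4)
  for (i in seq_along(idx)) {
    cam <- cameras[[idx[i]]]
    p <- suppressWarnings(to_pinhole(cam, uv[idx[i], , drop = FALSE]))
    a <- (p[1, 1] - cam$cx) / cam$fx
    b <- (p[1, 2] - cam$cy) / cam$fy
    M <- cbind(rotvec_to_matrix(cam$rotation), cam$translation)
    A[2 * i - 1, ] <- a * M[3, ] - M[1, ]
    A[2 * i, ] <- b * M[3, ] - M[2, ]
  }
  sv <- svd(A)
  d <- sv$d
  ok <- (d[3] - d[4]) > 1e-12 * max(d) && abs(sv$v[4, 4]) > 1e-14
  if (!ok) {
    return(list(point = rep(NA_real_, 3), error = NA_real_, ok = FALSE,
                n_views = length(idx)))
  }
  X <- sv$v[1:3, 4] / sv$v[4, 4]
  err <- reprojection_error(X, uv, cameras, visible)
  list(point = X, error = err, ok = TRUE, n_views = length(idx))
}

#' Summed squared reprojection error of a 3D point
#'
#' Sum over visible cameras of the squared pixel distance between the
#' point's projection and the observation; cameras with `e = 0` contribute
#' zero. A visible camera for which the point lies behind the optical plane
#' contributes `Inf`.
#'
#' @param point length-3 world point (mm).
#' @param uv n_cameras x 2 matrix of observations.
#' @param cameras list of `camera_model` objects.
#' @param visible logical per-camera visibility flags.
#' @return non-negative scalar (squared pixels).
#' @export
reprojection_error <- function(point, uv, cameras, visible = NULL) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2, byrow = TRUE)
  stopifnot(all(is.finite(point)))
  if (is.null(visible)) visible <- rowSums(is.finite(uv)) == 2
  total <- 0
  for (i in which(as.logical(visible))) {
    p <- project(cameras[[i]], point, behind = "na")
    d2 <- sum((p[1, ] - uv[i, ])^2)
    total <- total + if (is.finite(d2)) d2 else Inf
  }
  total
}

#' Apply a rigid world transform to a camera rig
#'
#' Re-expresses every camera's extrinsics after the world change of
#' coordinates `X' = R0 X + t0`, so that projections of transformed points
#' through the transformed rig equal projections of the original points
#' through the original rig.
#'
#' @param cameras list of `camera_model` objects.
#' @param rotation 3x3 rotation matrix `R0` or axis-angle vector.
#' @param translation length-3 vector `t0`.
#' @return list of transformed `camera_model` objects.
#' @export
transform_rig <- function(cameras, rotation, translation = c(0, 0, 0)) {
  R0 <- if (is.matrix(rotation)) rotation else rotvec_to_matrix(rotation)
  lapply(cameras, function(cam) {
    R <- rotvec_to_matrix(cam$rotation)
    Rn <- R %*% t(R0)
    cam$rotation <- matrix_to_rotvec(Rn)
    cam$translation <- as.numeric(cam$translation - Rn %*% translation)
    cam
  })
}
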