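# Unsupervised behavioral embedding from 3D pose.
#
# 3D traces are smoothed with an adaptive one-euro filter, converted into
# joint angles (scale- and translation-invariant; rotation-invariant for
# three-point angles), expanded into a posture-dynamics space by a Morlet
# continuous wavelet transform, row-normalized into per-frame distributions,
# embedded in 2D with t-SNE under a Kullback-Leibler dissimilarity, and
# finally accumulated, smoothed and watershed-segmented into a behavioral
# map.

#' One-euro filter
#'
#' Causal adaptive low-pass filter: the cutoff frequency rises with the
#' (filtered) signal speed, `fc = min_cutoff + beta |dx|`, trading jitter
#' suppression at rest against lag during fast motion. The first sample
#' passes through unchanged.
#'
#' @param x numeric vector or T x C matrix (one column per channel).
#' @param rate sampling rate, Hz.
#' @param min_cutoff minimum cutoff frequency, Hz.
#' @param beta speed coefficient (cutoff gain per unit speed).
#' @param d_cutoff cutoff of the derivative estimate, Hz.
#' @return filtered object of the same shape.
#' @export
one_euro_filter <- function(x, rate = 100, min_cutoff = 1, beta = 0.01,
                            d_cutoff = 1) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  alpha <- function(fc) 1 / (1 + rate / (2 * pi * fc))
  out <- x
  hat <- x[1, ]
  dhat <- rep(0, ncol(x))
  a_d <- alpha(d_cutoff)
  for (t in 2:nrow(x)) {
    dx <- (x[t, ] - hat) * rate
    dhat <- a_d * dx + (1 - a_d) * dhat
    fc <- min_cutoff + beta * abs(dhat)
    a <- alpha(fc)
    hat <- a * x[t, ] + (1 - a) * hat
    out[t, ] <- hat
  }
  if (vec) out[, 1] else out
}

#' Smooth a 3D pose series with the one-euro filter
#'
#' @param poses T x n_keypoints x 3 array (mm).
#' @param rate sampling rate, Hz.
#' @param timestamps optional sample times; must be uniform.
#' @param ... passed to [one_euro_filter()].
#' @return smoothed array of the same shape.
#' @export
smooth_poses <- function(poses, rate = 100, timestamps = NULL, ...) {
  stopifnot(length(dim(poses)) == 3)
  if (!is.null(timestamps)) {
    dt <- diff(timestamps)
    if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt))) {
      stop("non-uniform timestamps: the filter assumes uniform sampling")
    }
    rate <- 1 / dt[1]
  }
  d <- dim(poses)
  flat <- matrix(poses, d[1], d[2] * d[3])
  sm <- one_euro_filter(flat, rate = rate, ...)
  array(sm, d, dimnames = dimnames(poses))
}

#' Angle channel presets
#'
#' `"angles20"`: three interior joint angles per leg (coxa-femur,
#' femur-tibia, tibia-tarsus) for six legs plus one interior angle per
#' abdominal stripe side - 20 channels, all invariant to similarity
#' transforms of the pose. `"angles27"`: additionally two orientation angles
#' of each coxa segment (against the gravity axis and the body axis) and the
#' antennal-line tilt against gravity - 27 channels, of which the
#' axis-referenced ones are not rotation-invariant.
#'
#' @param skeleton a [fly_skeleton()].
#' @param preset `"angles20"` or `"angles27"`.
#' @return list of channel definitions (`type = "joint"` with keypoints
#'   `a`, `j`, `b`, or `type = "axis"` with keypoints `a`, `b` and a
#'   reference `axis`), named by channel.
#' @export
angle_channels <- function(skeleton, preset = c("angles20", "angles27")) {
  preset <- match.arg(preset)
  kp <- skeleton$keypoints
  id_of <- function(name) kp$id[match(name, kp$name)]
  ch <- list()
  for (side in c("L", "R")) for (leg in 1:3) {
    limb <- paste0(side, leg)
    nm <- function(part) id_of(paste0(limb, "_", part))
    if (preset == "angles27") {
      ch[[paste0(limb, "_coxa_gravity")]] <- list(
        type = "axis", a = nm("body_coxa"), b = nm("coxa_femur"),
        axis = c(0, 0, 1))
      ch[[paste0(limb, "_coxa_body")]] <- list(
        type = "axis", a = nm("body_coxa"), b = nm("coxa_femur"),
        axis = c(1, 0, 0))
    }
    ch[[paste0(limb, "_coxa_femur")]] <- list(
      type = "joint", a = nm("body_coxa"), j = nm("coxa_femur"),
      b = nm("femur_tibia"))
    ch[[paste0(limb, "_femur_tibia")]] <- list(
      type = "joint", a = nm("coxa_femur"), j = nm("femur_tibia"),
      b = nm("tibia_tarsus"))
    if (preset == "angles20") {
      ch[[paste0(limb, "_tibia_tarsus")]] <- list(
        type = "joint", a = nm("femur_tibia"), j = nm("tibia_tarsus"),
        b = nm("pretarsus"))
    }
  }
  for (side in c("L", "R")) {
    ch[[paste0("abd", side)]] <- list(
      type = "joint", a = id_of(paste0("abd", side, "_1")),
      j = id_of(paste0("abd", side, "_2")),
      b = id_of(paste0("abd", side, "_3")))
  }
  if (preset == "angles27") {
    ch[["antenna_tilt"]] <- list(type = "axis", a = id_of("antenna_L"),
                                 b = id_of("antenna_R"), axis = c(0, 0, 1))
  }
  ch
}

#' Convert a 3D pose series into joint angles
#'
#' Interior ("joint") channels are `acos` of the normalized dot product of
#' the two segments meeting at a joint, in `[0, pi]`; axis channels are the
#' angle between a two-point line and a fixed reference axis. Frames with a
#' coincident point pair (zero-length segment) are flagged and carry the
#' previous frame's angle.
#'
#' @param poses T x n_keypoints x 3 array (mm).
#' @param skeleton a skeleton (used for the default channel list).
#' @param channels channel list as from [angle_channels()].
#' @param rate sampling rate, Hz (stored on the result).
#' @return T x A matrix of angles (radians) with class `angle_series`,
#'   attributes `rate` and `flagged` (logical T x A).
#' @export
compute_angles <- function(poses, skeleton,
                           channels = angle_channels(skeleton), rate = 100) {
  stopifnot(length(dim(poses)) == 3, dim(poses)[3] == 3)
  T_n <- dim(poses)[1]
  out <- matrix(NA_real_, T_n, length(channels),
                dimnames = list(NULL, names(channels)))
  flagged <- matrix(FALSE, T_n, length(channels))
  for (a in seq_along(channels)) {
    chd <- channels[[a]]
    if (chd$type == "joint") {
      v1 <- poses[, chd$a, ] - poses[, chd$j, ]
      v2 <- poses[, chd$b, ] - poses[, chd$j, ]
    } else {
      v1 <- poses[, chd$b, ] - poses[, chd$a, ]
      v2 <- matrix(chd$axis, T_n, 3, byrow = TRUE)
    }
    if (T_n == 1) { v1 <- matrix(v1, 1); v2 <- matrix(v2, 1) }
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    cosang <- rowSums(v1 * v2) / (n1 * n2)
    bad <- !is.finite(cosang) | n1 == 0 | n2 == 0
    ang <- acos(pmin(pmax(cosang, -1), 1))
    ang[bad] <- NA_real_
    # carry the previous frame over degenerate geometry
    if (any(bad)) {
      for (t in which(bad)) if (t > 1) ang[t] <- ang[t - 1]
      if (is.na(ang[1])) ang[1] <- ang[which(!is.na(ang))[1]]
    }
    out[, a] <- ang
    flagged[, a] <- bad
  }
  structure(out, class = c("angle_series", "matrix", "array"),
            rate = rate, flagged = flagged)
}

#' Morlet wavelet posture-dynamics features
#'
#' Continuous wavelet transform of every angle channel at `n_scales` scales
#' whose center frequencies are dyadically (log2-uniformly) spaced from
#' `f_min` to `f_max` inclusive; the feature is the coefficient magnitude.
#' Channel means are removed before the transform; the CWT is computed by
#' FFT after reflection-padding each channel by the support of the largest
#' wavelet, so the two ends of the series do not contaminate each other.
#'
#' @param angles T x A [compute_angles()] matrix (or plain matrix).
#' @param n_scales number of wavelet scales.
#' @param f_min,f_max center-frequency range, Hz; needs `rate > 2 f_max`.
#' @param rate sampling rate, Hz; defaults to the `rate` attribute.
#' @param omega0 Morlet center parameter.
#' @return T x (A * n_scales) non-negative matrix with class
#'   `posture_dynamics`, attributes `frequencies` and `rate`. Columns are
#'   ordered channel-major (`channel1_f1, channel1_f2, ...`).
#' @export
wavelet_features <- function(angles, n_scales = 25, f_min = 5, f_max = 50,
                             rate = NULL, omega0 = 5) {
  rate <- rate %||% attr(angles, "rate") %||% 100
  stopifnot(rate >= 2 * f_max, f_min > 0, f_max > f_min, n_scales >= 2)
  x <- unclass(angles)
  T_n <- nrow(x); A <- ncol(x)
  freqs <- f_min * 2^((seq_len(n_scales) - 1) / (n_scales - 1) *
                        log2(f_max / f_min))
  dt <- 1 / rate
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs)
  if (T_n * dt < 2 * sqrt(2) * max(scales)) {
    stop("series shorter than the support of the largest wavelet")
  }
  pad <- min(T_n - 1, ceiling(2 * sqrt(2) * max(scales) / dt))
  N <- T_n + 2 * pad
  # angular frequencies of the DFT bins on the padded series
  k <- seq_len(N) - 1
  omega <- 2 * pi * ifelse(k <= N / 2, k, k - N) / (N * dt)
  out <- matrix(NA_real_, T_n, A * n_scales)
  cn <- character(A * n_scales)
  ch_names <- colnames(x) %||% paste0("ch", seq_len(A))
  for (a in seq_len(A)) {
    xa <- x[, a] - mean(x[, a])
    xa <- c(xa[(pad + 1):2], xa, xa[(T_n - 1):(T_n - pad)])
    xa_hat <- stats::fft(xa)
    for (s in seq_len(n_scales)) {
      psi <- sqrt(2 * pi * scales[s] / dt) * pi^(-0.25) *
        exp(-((scales[s] * omega - omega0)^2) / 2) * (omega > 0)
      w <- stats::fft(xa_hat * psi, inverse = TRUE) / N
      col <- (a - 1) * n_scales + s
      out[, col] <- Mod(w)[pad + seq_len(T_n)]
      cn[col] <- sprintf("%s_%.3gHz", ch_names[a], freqs[s])
    }
  }
  colnames(out) <- cn
  structure(out, class = c("posture_dynamics", "matrix", "array"),
            frequencies = freqs, rate = rate)
}

#' Normalize posture-dynamics rows into distributions
#'
#' Divides each per-frame feature vector by its sum so it can be treated as
#' a distribution over frequency channels. All-zero rows are replaced by the
#' uniform distribution and flagged.
#'
#' @param features non-negative T x F matrix.
#' @return row-stochastic matrix of the same shape, attribute
#'   `flagged_rows`.
#' @export
normalize_features <- function(features) {
  x <- unclass(features)
  stopifnot(all(x >= 0))
  s <- rowSums(x)
  zero <- s == 0
  x[zero, ] <- 1 / ncol(x)
  s[zero] <- 1
  out <- x / s
  attr(out, "flagged_rows") <- which(zero)
  class(out) <- class(features)
  attr(out, "frequencies") <- attr(features, "frequencies")
  attr(out, "rate") <- attr(features, "rate")
  out
}

#' Accumulate, smooth and watershed-segment an embedding into a behavior map
#'
#' Min-max normalizes the 2D embedding into a square grid (with an interior
#' margin of `5 sigma` cells so no mass sits on the boundary), accumulates a
#' 2D histogram, convolves it with a Gaussian kernel (circular FFT
#' convolution, which conserves total mass), and segments the smoothed
#' density by a watershed transform flooding from the density maxima
#' (8-neighborhood); cells below `density_threshold` form the background
#' (label 0). Each frame inherits the label of its grid cell.
#'
#' @param embedding T x 2 matrix of embedding coordinates.
#' @param grid grid side length (cells).
#' @param sigma Gaussian kernel width, grid cells.
#' @param density_threshold background cutoff on the smoothed density;
#'   default `1e-3 * max(density)`.
#' @param tolerance watershed merge tolerance (minimum depth separating two
#'   basins), on the density scale.
#' @return object of class `behavior_map`: `histogram`, `density`
#'   (smoothed), `labels` (grid matrix, 0 = background), `assignments`
#'   (data.frame `frame`, `gx`, `gy`, `label`), `n_regions`, `grid`,
#'   `sigma`, `threshold`.
#' @export
behavior_map <- function(embedding, grid = 1000, sigma = 10,
                         density_threshold = NULL, tolerance = 0) {
  embedding <- as.matrix(embedding)
  if (!nrow(embedding)) stop("empty embedding")
  stopifnot(ncol(embedding) == 2, all(is.finite(embedding)))
  margin <- ceiling(5 * sigma)
  stopifnot(grid > 2 * margin + 1)
  norm1 <- function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(rep(round((grid + 1) / 2), length(x)))
    1 + margin + round((x - rng[1]) / (rng[2] - rng[1]) *
                         (grid - 1 - 2 * margin))
  }
  gx <- norm1(embedding[, 1])
  gy <- norm1(embedding[, 2])
  H <- matrix(0, grid, grid)
  for (t in seq_len(nrow(embedding))) H[gy[t], gx[t]] <- H[gy[t], gx[t]] + 1
  # separable circular Gaussian convolution via the 2D FFT
  wrap <- pmin(0:(grid - 1), grid - (0:(grid - 1)))
  k1 <- exp(-wrap^2 / (2 * sigma^2))
  K <- outer(k1, k1)
  K <- K / sum(K)
  density <- Re(stats::fft(stats::fft(H) * stats::fft(K), inverse = TRUE)) /
    grid^2
  density[density < 0] <- 0
  if (is.null(density_threshold)) density_threshold <- 1e-3 * max(density)
  masked <- density
  masked[masked <= density_threshold] <- 0
  labels <- EBImage::watershed(masked, tolerance = tolerance, ext = 1)
  labels <- matrix(as.integer(labels), grid, grid)
  assignments <- data.frame(frame = seq_len(nrow(embedding)), gx = gx,
                            gy = gy, label = labels[cbind(gy, gx)])
  structure(list(histogram = H, density = density, labels = labels,
                 assignments = assignments,
                 n_regions = length(setdiff(unique(as.integer(labels)), 0L)),
                 grid = grid, sigma = sigma, threshold = density_threshold),
            class = "behavior_map")
}

#' @export
print.behavior_map <- function(x, ...) {
  cat(sprintf("behavior map: %d x %d grid, %d frames, %d regions\n",
              x$grid, x$grid, nrow(x$assignments), x$n_regions))
  invisible(x)
}
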