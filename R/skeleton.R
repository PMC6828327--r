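# Articulated skeleton of the tethered fly: 38 tracked landmarks.
#
# Five keypoints per leg (body-coxa, coxa-femur, femur-tibia, tibia-tarsus,
# pretarsus) on six legs, three abdominal stripe points per side, and one
# point per antenna. Limb connectivity is a forest of chains (one chain per
# leg, per abdominal side, plus the two antennal points); each chain is a
# rooted tree with no loops, which is what makes exact max-sum inference
# possible.

leg_parts <- c("body_coxa", "coxa_femur", "femur_tibia", "tibia_tarsus",
               "pretarsus")

#' Per-keypoint camera visibility for a sided animal on a camera ring
#'
#' Each keypoint is declared visible from the cameras whose viewing
#' direction (origin to camera center) lies within `half_angle` of the
#' keypoint's outward side normal (left = +y, right = -y), keeping at most
#' `max_cameras` of them (the nearest in angle). With seven uniformly spaced
#' cameras this yields exactly four cameras per side.
#'
#' @param sides character vector of `"left"`/`"right"` per keypoint.
#' @param camera_angles per-camera azimuths, radians.
#' @param half_angle acceptance half-angle, degrees.
#' @param max_cameras visibility cap per keypoint.
#' @return logical n_keypoints x n_cameras matrix (the camera-sees-joint
#'   table).
#' @export
camera_visibility <- function(sides, camera_angles, half_angle = 115,
                              max_cameras = 4) {
  normals <- ifelse(sides == "left", pi / 2, -pi / 2)
  t(vapply(normals, function(nth) {
    d <- abs(((camera_angles - nth + pi) %% (2 * pi)) - pi) * 180 / pi
    ok <- d <= half_angle
    if (sum(ok) > max_cameras) {
      keep <- order(d)[seq_len(max_cameras)]
      ok <- seq_along(d) %in% keep
    }
    ok
  }, logical(length(camera_angles))))
}

#' Construct the default fly skeleton
#'
#' @param n_cameras number of cameras on the ring (visibility table size).
#' @param camera_angles per-camera azimuths (radians); default uniform
#'   spacing starting at 0.
#' @return object of class `skeleton`: list with `keypoints` (data.frame:
#'   `id`, `name`, `limb`, `side`, `part`), `edges` (data.frame: `from`,
#'   `to`, `family` - `"beta"` for the distal tarsal segments, else
#'   `"gaussian"`), `roots` (one keypoint id per chain), and `visibility`
#'   (camera-sees-joint matrix).
#' @export
fly_skeleton <- function(n_cameras = 7, camera_angles = NULL) {
  if (is.null(camera_angles)) {
    camera_angles <- 2 * pi * (seq_len(n_cameras) - 1) / n_cameras
  }
  kp <- list(); edges <- list(); roots <- integer(0)
  id <- 0
  for (side in c("L", "R")) {
    for (leg in 1:3) {
      limb <- paste0(side, leg)
      ids <- id + seq_along(leg_parts)
      kp[[length(kp) + 1]] <- data.frame(
        id = ids, name = paste0(limb, "_", leg_parts), limb = limb,
        side = ifelse(side == "L", "left", "right"), part = leg_parts)
      edges[[length(edges) + 1]] <- data.frame(
        from = ids[-length(ids)], to = ids[-1],
        family = c("gaussian", "gaussian", "beta", "beta"))
      roots <- c(roots, ids[1])
      id <- max(ids)
    }
  }
  for (side in c("L", "R")) {
    limb <- paste0("abd", side)
    ids <- id + 1:3
    kp[[length(kp) + 1]] <- data.frame(
      id = ids, name = paste0(limb, "_", 1:3), limb = limb,
      side = ifelse(side == "L", "left", "right"), part = "abdomen")
    edges[[length(edges) + 1]] <- data.frame(
      from = ids[-3], to = ids[-1], family = "gaussian")
    roots <- c(roots, ids[1])
    id <- max(ids)
  }
  ids <- id + 1:2
  kp[[length(kp) + 1]] <- data.frame(
    id = ids, name = c("antenna_L", "antenna_R"), limb = "head",
    side = c("left", "right"), part = "antenna")
  edges[[length(edges) + 1]] <- data.frame(from = ids[1], to = ids[2],
                                           family = "gaussian")
  roots <- c(roots, ids[1])
  keypoints <- do.call(rbind, kp)
  edges <- do.call(rbind, edges)
  rownames(keypoints) <- rownames(edges) <- NULL
  skel <- structure(list(keypoints = keypoints, edges = edges, roots = roots,
                         visibility = camera_visibility(keypoints$side,
                                                        camera_angles),
                         camera_angles = camera_angles),
                    class = "skeleton")
  validate_skeleton(skel)
  skel
}

#' Validate a skeleton
#'
#' Checks that every connected component of the limb graph is acyclic (a
#' tree), that edge endpoints are known keypoints, and that every keypoint is
#' visible from at least two cameras.
#'
#' @param skeleton a `skeleton`.
#' @return the skeleton, invisibly; errors on violation.
#' @export
validate_skeleton <- function(skeleton) {
  ids <- skeleton$keypoints$id
  stopifnot(!anyDuplicated(ids), all(skeleton$edges$from %in% ids),
            all(skeleton$edges$to %in% ids))
  # union-find cycle check
  parent <- seq_len(max(ids))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(skeleton$edges))) {
    a <- find(skeleton$edges$from[e]); b <- find(skeleton$edges$to[e])
    if (a == b) stop("skeleton limb graph contains a loop")
    parent[a] <- b
  }
  if (any(rowSums(skeleton$visibility) < 2)) {
    stop("every keypoint must be visible from at least two cameras")
  }
  invisible(skeleton)
}

#' Connected chain components of the skeleton
#'
#' @param skeleton a `skeleton`.
#' @return list of components, each a list with `nodes` (keypoint ids),
#'   `edges` (row indices into `skeleton$edges`) and `root`.
#' @export
skeleton_components <- function(skeleton) {
  ids <- skeleton$keypoints$id
  comp <- stats::setNames(seq_along(ids), ids)
  for (e in seq_len(nrow(skeleton$edges))) {
    a <- comp[as.character(skeleton$edges$from[e])]
    b <- comp[as.character(skeleton$edges$to[e])]
    comp[comp == b] <- a
  }
  lapply(unique(comp), function(ci) {
    nodes <- ids[comp == ci]
    erows <- which(skeleton$edges$from %in% nodes &
                     skeleton$edges$to %in% nodes)
    root <- intersect(skeleton$roots, nodes)
    list(nodes = nodes, edges = erows,
         root = if (length(root)) root[1] else nodes[1])
  })
}
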