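# Pictorial-structures correction of keypoint candidates.
#
# One 3D candidate per keypoint is selected by MAP inference in a
# tree-structured graphical model whose log-score decomposes into (i) unary
# image evidence, the log probability-map intensity at the candidate's 2D
# projections, (ii) a pairwise segment-length prior along every limb edge,
# and (iii) a reprojection term, the negative log product of squared
# distances between the candidate's projections and its supporting
# detections. Inference is exact max-sum belief propagation (log-domain
# Viterbi on a tree): one leaf-ward sweep of messages and one backtracking
# sweep, O(n k^2) for n keypoints with k candidates each.

#' Construct a segment-length prior
#'
#' Gaussian priors are parameterized by the mean and standard deviation of
#' the segment length; Beta priors (used for the distal tarsal segments,
#' whose apparent length is shortened by occlusions) live on
#' `[0, length_scale]` with shape parameters `alpha`, `beta`.
#'
#' @param from,to keypoint ids of the segment's endpoints.
#' @param family `"gaussian"` or `"beta"`.
#' @param mu,sigma Gaussian parameters (mm); `sigma > 0`.
#' @param alpha,beta,length_scale Beta parameters; `length_scale > 0` (mm).
#' @param n_samples number of segment-length samples behind the estimate.
#' @param informative `FALSE` marks a default prior from insufficient data;
#'   uninformative priors contribute zero to the pairwise score.
#' @return object of class `segment_prior`.
#' @export
segment_prior <- function(from, to, family = c("gaussian", "beta"),
                          mu = NA_real_, sigma = NA_real_,
                          alpha = NA_real_, beta = NA_real_,
                          length_scale = NA_real_, n_samples = 0L,
                          informative = TRUE) {
  family <- match.arg(family)
  if (informative) {
    if (family == "gaussian") stopifnot(is.finite(mu), sigma > 0)
    else stopifnot(alpha > 0, beta > 0, length_scale > 0)
  }
  structure(list(from = from, to = to, family = family, mu = mu,
                 sigma = sigma, alpha = alpha, beta = beta,
                 length_scale = length_scale, n_samples = as.integer(n_samples),
                 informative = informative),
            class = "segment_prior")
}

prior_key <- function(from, to) paste0(from, "-", to)

#' Log-density of a segment length under its prior
#'
#' @param length numeric segment length(s), mm.
#' @param prior a [segment_prior()].
#' @param log_floor lower bound applied to the log-density (also used for
#'   lengths outside the Beta support).
#' @return numeric log-density, same length as `length`.
#' @export
pairwise_logprior <- function(length, prior, log_floor = -745) {
  if (!prior$informative) return(rep(0, length(length)))
  out <- if (prior$family == "gaussian") {
    stats::dnorm(length, prior$mu, prior$sigma, log = TRUE)
  } else {
    x <- length / prior$length_scale
    v <- rep(log_floor, length(length))
    ok <- x > 0 & x < 1
    v[ok] <- stats::dbeta(x[ok], prior$alpha, prior$beta, log = TRUE) -
      log(prior$length_scale)
    v
  }
  pmax(out, log_floor)
}

#' Unary log-likelihood of 3D candidates under the probability maps
#'
#' Sum over cameras of the log map intensity at the candidate's projection,
#' with intensities floored at `eps_p`. Cameras where the keypoint is not
#' visible (or without a map) contribute `log(eps_p)`, a constant that
#' cancels when candidates are compared. Pinned cameras contribute 0
#' (probability one).
#'
#' @param points N x 3 matrix (or length-3 vector) of candidate positions.
#' @param maps list of [prob_map()] (or `NULL`), one per camera, for this
#'   keypoint.
#' @param rig list of `camera_model`.
#' @param visible logical per-camera visibility for this keypoint.
#' @param eps_p intensity floor.
#' @param pinned_cameras integer camera indices carrying a user pin.
#' @return numeric vector of log-likelihoods, one per candidate.
#' @export
unary_loglik <- function(points, maps, rig, visible = NULL, eps_p = 1e-6,
                         pinned_cameras = integer(0)) {
  points <- as_points_matrix(points)
  if (is.null(visible)) visible <- !vapply(maps, is.null, logical(1))
  out <- numeric(nrow(points))
  for (ci in seq_along(rig)) {
    if (ci %in% pinned_cameras) next
    if (!isTRUE(visible[ci]) || is.null(maps[[ci]])) {
      out <- out + log(eps_p)
      next
    }
    m <- maps[[ci]]
    p <- project(rig[[ci]], points, behind = "na")
    col <- round(p[, 1] / m$scale[1]) + 1
    row <- round(p[, 2] / m$scale[2]) + 1
    ok <- is.finite(row) & is.finite(col) & row >= 1 & col >= 1 &
      row <= nrow(m$values) & col <= ncol(m$values)
    vals <- rep(eps_p, nrow(points))
    if (any(ok)) {
      vals[ok] <- pmax(m$values[cbind(row[ok], col[ok])], eps_p)
    }
    out <- out + log(vals)
  }
  out
}

#' Reprojection log-term of a candidate
#'
#' The log of the product over visible cameras of the inverse squared
#' distance between the candidate's projection and its chosen 2D
#' observation, `sum_c e_c * (-log max(d_c, eps_r)^2)`; distances are clamped
#' below at `eps_r` pixels to avoid the singularity at zero.
#'
#' @param point length-3 candidate position.
#' @param uv n_cameras x 2 matrix of chosen observations.
#' @param rig list of `camera_model`.
#' @param visible logical per-camera flags `e_c` selecting the observations
#'   that enter the product.
#' @param eps_r distance clamp, pixels.
#' @return scalar log-term.
#' @export
reprojection_logterm <- function(point, uv, rig, visible = NULL, eps_r = 1) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2, byrow = TRUE)
  if (is.null(visible)) visible <- rowSums(is.finite(uv)) == 2
  total <- 0
  for (ci in which(as.logical(visible))) {
    p <- project(rig[[ci]], point, behind = "na")
    d <- sqrt(sum((p[1, ] - uv[ci, ])^2))
    d <- if (is.finite(d)) max(d, eps_r) else 1e6
    total <- total - 2 * log(d)
  }
  total
}

# Per-candidate reprojection term over each candidate's own two supports.
candidate_reproj_terms <- function(cs, rig, eps_r = 1) {
  n <- nrow(cs$points)
  if (!n) return(numeric(0))
  out <- numeric(n)
  sup <- cs$support
  for (ci in unique(c(sup$cam1, sup$cam2))) {
    rows1 <- which(sup$cam1 == ci)
    rows2 <- which(sup$cam2 == ci)
    rows <- c(rows1, rows2)
    obs <- rbind(cbind(sup$u1[rows1], sup$v1[rows1]),
                 cbind(sup$u2[rows2], sup$v2[rows2]))
    p <- project(rig[[ci]], cs$points[rows, , drop = FALSE], behind = "na")
    d <- sqrt(rowSums((p - obs)^2))
    d <- ifelse(is.finite(d), pmax(d, eps_r), 1e6)
    out[rows] <- out[rows] - 2 * log(d)
  }
  out
}

#' Exact MAP inference on a tree by max-sum message passing
#'
#' Maximizes `sum_i unary[[i]][s_i] + sum_e pairwise[[e]][s_i, s_j]` over all
#' joint assignments, for an acyclic graph, by one leaf-ward message sweep
#' and one backtracking sweep. Ties are broken toward the lowest candidate
#' index.
#'
#' @param unary list of numeric score vectors, one per node.
#' @param edges data.frame with integer columns `i`, `j` (node indices); the
#'   edge set must be acyclic.
#' @param pairwise list of matrices aligned with the rows of `edges`;
#'   `pairwise[[e]]` has dimensions `length(unary[[i]]) x length(unary[[j]])`.
#' @return list with `assignment` (chosen state per node) and `score`.
#' @export
max_sum_tree <- function(unary, edges, pairwise = list()) {
  n <- length(unary)
  k <- lengths(unary)
  stopifnot(all(k >= 1))
  if (is.null(edges) || nrow(edges) == 0) {
    assignment <- vapply(unary, which.max, integer(1))
    return(list(assignment = assignment,
                score = sum(vapply(unary, max, numeric(1)))))
  }
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]
    adj[[i]] <- rbind(adj[[i]], c(j, e))
    adj[[j]] <- rbind(adj[[j]], c(i, e))
  }
  root <- 1L
  order <- integer(0); parent <- rep(NA_integer_, n)
  parent_edge <- rep(NA_integer_, n)
  queue <- root; seen <- rep(FALSE, n); seen[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    if (!is.null(adj[[v]])) {
      for (r in seq_len(nrow(adj[[v]]))) {
        w <- adj[[v]][r, 1]
        if (!seen[w]) {
          seen[w] <- TRUE; parent[w] <- v; parent_edge[w] <- adj[[v]][r, 2]
          queue <- c(queue, w)
        }
      }
    }
  }
  if (!all(seen)) stop("edge graph is not connected over the given nodes")
  belief <- unary
  best_state <- vector("list", n) # argmax of child state per parent state
  for (v in rev(order)) {
    if (v == root) next
    e <- parent_edge[v]; p <- parent[v]
    P <- pairwise[[e]]
    if (edges$i[e] == p) {
      # P is k_p x k_v
      M <- sweep(P, 2, belief[[v]], "+")
      msg <- apply(M, 1, max)
      arg <- max.col(M, ties.method = "first")
    } else {
      # P is k_v x k_p
      M <- sweep(P, 1, belief[[v]], "+")
      msg <- apply(M, 2, max)
      arg <- max.col(t(M), ties.method = "first")
    }
    belief[[p]] <- belief[[p]] + msg
    best_state[[v]] <- arg
  }
  assignment <- rep(NA_integer_, n)
  assignment[root] <- which.max(belief[[root]])
  for (v in order) {
    if (v == root) next
    assignment[v] <- best_state[[v]][assignment[parent[v]]]
  }
  list(assignment = assignment, score = max(belief[[root]]))
}

# Restrict a candidate set to the rows selected by `keep`.
subset_candidates <- function(cs, keep) {
  cs$points <- cs$points[keep, , drop = FALSE]
  cs$support <- cs$support[keep, , drop = FALSE]
  cs$error <- cs$error[keep]
  cs
}

# Apply user pins for one keypoint: restrict supports in the pinned camera
# to the pinned pixel; if no candidate uses it, build new candidates pairing
# the pinned observation with the other visible cameras' peaks.
apply_pins <- function(cs, pins, maps, rig, visible, n_peaks = 10) {
  for (r in seq_len(nrow(pins))) {
    ci <- pins$camera[r]
    tol <- if (!is.null(maps[[ci]])) max(maps[[ci]]$scale) * 0.51 else 0.51
    match1 <- cs$support$cam1 == ci &
      abs(cs$support$u1 - pins$u[r]) <= tol &
      abs(cs$support$v1 - pins$v[r]) <= tol
    match2 <- cs$support$cam2 == ci &
      abs(cs$support$u2 - pins$u[r]) <= tol &
      abs(cs$support$v2 - pins$v[r]) <= tol
    keep <- (match1 | match2) |
      (cs$support$cam1 != ci & cs$support$cam2 != ci)
    # a pinned camera must appear with the pinned pixel only
    keep <- keep & !(cs$support$cam1 == ci & !match1) &
      !(cs$support$cam2 == ci & !match2)
    if (any(match1 | match2)) {
      cs <- subset_candidates(cs, keep)
      next
    }
    # no candidate uses the pin: rebuild from the pin and the other views
    pts <- list(); rows <- list(); errs <- numeric(0)
    for (cj in setdiff(which(visible), ci)) {
      if (is.null(maps[[cj]])) next
      pk <- local_maxima(maps[[cj]], n = n_peaks)
      for (b in seq_len(nrow(pk))) {
        uv <- matrix(NA_real_, length(rig), 2)
        uv[ci, ] <- c(pins$u[r], pins$v[r])
        uv[cj, ] <- c(pk$u[b], pk$v[b])
        tri <- triangulate(uv, rig)
        if (!tri$ok) next
        pts[[length(pts) + 1]] <- tri$point
        errs <- c(errs, tri$error)
        rows[[length(rows) + 1]] <- data.frame(
          cam1 = ci, cam2 = cj, u1 = pins$u[r], v1 = pins$v[r],
          u2 = pk$u[b], v2 = pk$v[b], score1 = 1, score2 = pk$score[b])
      }
    }
    cs$points <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 3)
    cs$support <- if (length(rows)) do.call(rbind, rows) else data.frame()
    cs$error <- errs
  }
  cs
}

#' Select one geometrically consistent candidate per keypoint (MAP)
#'
#' Runs exact max-sum belief propagation over every chain of the skeleton,
#' maximizing unary map evidence plus segment-length priors plus the
#' reprojection term. Near-duplicate candidates (within `dedup_tol` mm) are
#' merged beforehand, keeping the best unary score. Keypoints with no
#' candidates are marked unresolved and their chain is split around them. A
#' pinned 2D annotation makes the pinned pixel the only admissible support
#' in its camera and sets its image likelihood to one.
#'
#' @param candidates list of [generate_candidates()] outputs, indexed by
#'   keypoint id.
#' @param skeleton a [fly_skeleton()]-style skeleton.
#' @param priors named list of [segment_prior()] keyed `"from-to"`.
#' @param maps probability-map stack for one frame: `maps[[camera]][[keypoint]]`.
#' @param rig list of `camera_model`.
#' @param pinned optional data.frame (`keypoint`, `camera`, `u`, `v`).
#' @param eps_p,eps_r floors of the unary and reprojection terms.
#' @param dedup_tol candidate merge radius, mm.
#' @return object of class `ps_solution`: `points` (n_keypoints x 3, `NA`
#'   rows for unresolved keypoints), `resolved`, `observations`
#'   (n_cameras x n_keypoints x 2; supporting detections where chosen,
#'   reprojections elsewhere), `support` (per-keypoint chosen support row),
#'   `score` and its per-keypoint `unary`/`reproj` decomposition.
#' @export
map_solve <- function(candidates, skeleton, priors, maps, rig, pinned = NULL,
                      eps_p = 1e-6, eps_r = 1, dedup_tol = 1e-3) {
  ids <- skeleton$keypoints$id
  n_kp <- max(ids)
  n_cams <- length(rig)
  node_unary <- vector("list", n_kp)
  node_score <- vector("list", n_kp)
  node_reproj <- vector("list", n_kp)
  sets <- vector("list", n_kp)
  for (j in ids) {
    cs <- if (j <= length(candidates)) candidates[[j]] else NULL
    if (is.null(cs) || !nrow(cs$points)) next
    visible <- skeleton$visibility[match(j, ids), ]
    kp_maps <- lapply(seq_len(n_cams), function(ci) {
      if (length(maps) >= ci && length(maps[[ci]]) >= j) maps[[ci]][[j]] else NULL
    })
    pinned_cams <- integer(0)
    if (!is.null(pinned) && nrow(pinned)) {
      pins <- pinned[pinned$keypoint == j, , drop = FALSE]
      if (nrow(pins)) {
        cs <- apply_pins(cs, pins, kp_maps, rig, visible)
        pinned_cams <- pins$camera
        if (!nrow(cs$points)) next
      }
    }
    u <- unary_loglik(cs$points, kp_maps, rig, visible, eps_p, pinned_cams)
    # deduplicate near-identical triangulations, keeping the best unary
    ord <- order(-u)
    keep <- logical(length(ord))
    for (i in ord) {
      kept <- which(keep)
      if (length(kept)) {
        d2 <- rowSums((cs$points[kept, , drop = FALSE] -
                         matrix(cs$points[i, ], length(kept), 3,
                                byrow = TRUE))^2)
        if (any(d2 < dedup_tol^2)) next
      }
      keep[i] <- TRUE
    }
    cs <- subset_candidates(cs, keep)
    u <- u[keep]
    r <- candidate_reproj_terms(cs, rig, eps_r)
    sets[[j]] <- cs
    node_unary[[j]] <- u
    node_reproj[[j]] <- r
    node_score[[j]] <- u + r
  }
  resolved <- !vapply(node_score, is.null, logical(1))
  points <- matrix(NA_real_, n_kp, 3)
  chosen <- rep(NA_integer_, n_kp)
  total <- 0
  for (comp in skeleton_components(skeleton)) {
    nodes <- comp$nodes[resolved[comp$nodes]]
    if (!length(nodes)) next
    erows <- comp$edges
    erows <- erows[skeleton$edges$from[erows] %in% nodes &
                     skeleton$edges$to[erows] %in% nodes]
    # removing unresolved nodes can split the chain: solve each piece
    sub <- stats::setNames(seq_along(nodes), nodes)
    for (e in erows) {
      a <- sub[as.character(skeleton$edges$from[e])]
      b <- sub[as.character(skeleton$edges$to[e])]
      sub[sub == b] <- a
    }
    for (piece in unique(sub)) {
      pn <- nodes[sub == piece]
      pe <- erows[skeleton$edges$from[erows] %in% pn]
      local <- stats::setNames(seq_along(pn), pn)
      edges_df <- if (length(pe)) {
        data.frame(i = local[as.character(skeleton$edges$from[pe])],
                   j = local[as.character(skeleton$edges$to[pe])])
      } else data.frame(i = integer(0), j = integer(0))
      pw <- lapply(pe, function(e) {
        a <- skeleton$edges$from[e]; b <- skeleton$edges$to[e]
        pa <- sets[[a]]$points; pb <- sets[[b]]$points
        D <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                    2 * pa %*% t(pb))
        D[!is.finite(D) | D < 0] <- 0
        pr <- priors[[prior_key(a, b)]]
        if (is.null(pr)) matrix(0, nrow(pa), nrow(pb))
        else matrix(pairwise_logprior(as.numeric(D), pr), nrow(pa), nrow(pb))
      })
      sol <- max_sum_tree(node_score[pn], edges_df, pw)
      total <- total + sol$score
      for (i in seq_along(pn)) {
        chosen[pn[i]] <- sol$assignment[i]
        points[pn[i], ] <- sets[[pn[i]]]$points[sol$assignment[i], ]
      }
    }
  }
  observations <- array(NA_real_, c(n_cams, n_kp, 2))
  support <- vector("list", n_kp)
  for (j in which(resolved & !is.na(chosen))) {
    for (ci in seq_len(n_cams)) {
      p <- try(project(rig[[ci]], points[j, ], behind = "na"), silent = TRUE)
      if (!inherits(p, "try-error")) observations[ci, j, ] <- p[1, ]
    }
    sup <- sets[[j]]$support[chosen[j], , drop = FALSE]
    observations[sup$cam1, j, ] <- c(sup$u1, sup$v1)
    observations[sup$cam2, j, ] <- c(sup$u2, sup$v2)
    support[[j]] <- sup
    if (!is.null(pinned) && nrow(pinned)) {
      pins <- pinned[pinned$keypoint == j, , drop = FALSE]
      for (r in seq_len(nrow(pins))) {
        observations[pins$camera[r], j, ] <- c(pins$u[r], pins$v[r])
      }
    }
  }
  structure(list(points = points, resolved = resolved & !is.na(chosen),
                 observations = observations, support = support,
                 score = total,
                 unary = vapply(seq_len(n_kp), function(j) {
                   if (is.na(chosen[j])) NA_real_ else node_unary[[j]][chosen[j]]
                 }, numeric(1)),
                 reproj = vapply(seq_len(n_kp), function(j) {
                   if (is.na(chosen[j])) NA_real_ else node_reproj[[j]][chosen[j]]
                 }, numeric(1))),
            class = "ps_solution")
}

#' @export
print.ps_solution <- function(x, ...) {
  cat(sprintf("pictorial-structures solution: %d/%d keypoints resolved, score %.4g\n",
              sum(x$resolved), length(x$resolved), x$score))
  invisible(x)
}

#' Learn segment-length priors from a pose archive
#'
#' Gaussian maximum-likelihood estimates (sample mean and standard
#' deviation) of the limb segment lengths per skeleton edge, with Beta
#' maximum likelihood (on lengths rescaled to `beta_scale_factor` times the
#' largest observed length) for the edges marked `"beta"` in the skeleton -
#' the distal tarsal segments whose apparent length distribution is skewed
#' by occlusion. Frames whose endpoints exceed the reprojection cutoff are
#' excluded, mirroring the exclusion applied during calibration.
#'
#' @param poses T x n_keypoints x 3 array of triangulated positions (mm).
#' @param skeleton a skeleton.
#' @param reproj optional T x n_keypoints matrix of reprojection errors.
#' @param reproj_cutoff exclusion threshold on `reproj`.
#' @param min_samples minimum retained frames for an informative prior.
#' @param sigma_floor lower bound on the Gaussian sigma.
#' @param beta_scale_factor Beta support as a multiple of the maximum
#'   observed length.
#' @return named list of [segment_prior()] keyed `"from-to"`.
#' @export
learn_segment_priors <- function(poses, skeleton, reproj = NULL,
                                 reproj_cutoff = Inf, min_samples = 30,
                                 sigma_floor = 1e-8,
                                 beta_scale_factor = 1.05) {
  stopifnot(length(dim(poses)) == 3, dim(poses)[3] == 3)
  out <- list()
  for (e in seq_len(nrow(skeleton$edges))) {
    a <- skeleton$edges$from[e]; b <- skeleton$edges$to[e]
    keep <- rep(TRUE, dim(poses)[1])
    if (!is.null(reproj)) {
      keep <- reproj[, a] <= reproj_cutoff & reproj[, b] <= reproj_cutoff
    }
    d <- poses[keep, a, , drop = FALSE] - poses[keep, b, , drop = FALSE]
    len <- sqrt(apply(d^2, 1, sum))
    len <- len[is.finite(len)]
    key <- prior_key(a, b)
    if (length(len) < min_samples) {
      out[[key]] <- segment_prior(a, b, "gaussian", informative = FALSE,
                                  n_samples = length(len))
      next
    }
    if (skeleton$edges$family[e] == "beta") {
      scale <- beta_scale_factor * max(len)
      if (!is.finite(scale) || scale <= 0 || stats::sd(len) == 0) {
        # degenerate lengths carry no shape information
        out[[key]] <- segment_prior(a, b, "beta", informative = FALSE,
                                    n_samples = length(len))
        next
      }
      x <- pmin(pmax(len / scale, 1e-9), 1 - 1e-9)
      moments <- function() {
        m <- mean(x); v <- max(stats::var(x), 1e-12)
        k <- max(m * (1 - m) / v - 1, 1e-6)
        c(shape1 = m * k, shape2 = (1 - m) * k)
      }
      fit <- tryCatch(fitdistrplus::fitdist(x, "beta")$estimate,
                      error = function(e) moments())
      if (!all(is.finite(fit)) || any(fit <= 0)) fit <- moments()
      out[[key]] <- segment_prior(a, b, "beta",
                                  alpha = unname(fit["shape1"]),
                                  beta = unname(fit["shape2"]),
                                  length_scale = scale,
                                  n_samples = length(len))
    } else {
      s <- stats::sd(len)
      if (!is.finite(s)) s <- 0
      out[[key]] <- segment_prior(a, b, "gaussian", mu = mean(len),
                                  sigma = max(s, sigma_floor),
                                  n_samples = length(len))
    }
  }
  out
}
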