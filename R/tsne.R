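# 2D embedding of the posture-dynamics space.
#
# Exact (dense) t-SNE driven by a precomputed dissimilarity: the symmetrized
# Kullback-Leibler divergence between per-frame feature distributions. The
# implementation follows the standard formulation - perplexity-calibrated
# input affinities, early exaggeration, adaptive gains, momentum - computed
# with dense matrices, which is appropriate at the series lengths this
# package targets.

#' Symmetrized Kullback-Leibler divergence matrix
#'
#' `D_ij = (KL(p_i || p_j) + KL(p_j || p_i)) / 2` between the rows of a
#' row-stochastic matrix. Rows are floored at `floor` and renormalized so
#' the divergence is finite.
#'
#' @param p row-stochastic T x F matrix.
#' @param floor probability floor.
#' @return symmetric T x T matrix with zero diagonal.
#' @export
kl_divergence_matrix <- function(p, floor = 1e-12) {
  p <- unclass(p)
  if (max(abs(rowSums(p) - 1)) > 1e-6) {
    stop("rows must be normalized distributions (see normalize_features)")
  }
  p <- pmax(p, floor)
  p <- p / rowSums(p)
  lp <- log(p)
  h <- rowSums(p * lp)
  kl <- h - p %*% t(lp)            # kl[i, j] = KL(p_i || p_j)
  d <- (kl + t(kl)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Perplexity-calibrated conditional affinities from a dissimilarity matrix
# (binary search on the per-point precision, as in standard t-SNE).
perplexity_affinities <- function(D, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(D)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      diff <- H - target
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P
}

#' Embed posture-dynamics features in 2D with t-SNE
#'
#' The pairwise input dissimilarity is the symmetrized KL divergence
#' between the row distributions (so rows must be normalized, see
#' [normalize_features()]); it takes the place of the squared Euclidean
#' distance in the standard t-SNE affinity calibration. The result is
#' deterministic for a fixed seed; rows are canonicalized (sorted) before
#' the optimization and un-permuted afterwards, so the embedding does not
#' depend on frame order.
#'
#' @param features row-stochastic T x F matrix; needs `T >= 3 * perplexity`.
#' @param perplexity t-SNE perplexity.
#' @param seed RNG seed for the initialization.
#' @param n_iter gradient-descent iterations.
#' @param learning_rate step size.
#' @param exaggeration early-exaggeration factor (first 100 iterations).
#' @param canonicalize sort rows before optimizing (frame-order invariance).
#' @return T x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(features, perplexity = 35, seed = 1, n_iter = 500,
                       learning_rate = 200, exaggeration = 12,
                       canonicalize = TRUE) {
  x <- unclass(features)
  n <- nrow(x)
  if (n < 3 * perplexity) {
    stop(sprintf("need at least 3 * perplexity = %d rows, got %d",
                 ceiling(3 * perplexity), n))
  }
  ord <- if (canonicalize) do.call(order, as.data.frame(x)) else seq_len(n)
  D <- kl_divergence_matrix(x[ord, , drop = FALSE])
  P <- perplexity_affinities(D, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)    # update (momentum) term
  gains <- matrix(1, n, 2)
  Pe <- P * exaggeration
  for (iter in seq_len(n_iter)) {
    Puse <- if (iter <= 100) Pe else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    PQ <- (Puse - Q) * num
    grad <- 4 * (rowSums(PQ) * Y - PQ %*% Y)
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - learning_rate * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  out <- matrix(NA_real_, n, 2)
  out[ord, ] <- Y
  colnames(out) <- c("x", "y")
  out
}
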