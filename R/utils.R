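# Small shared helpers.

#' Similarity (Procrustes) alignment of two point sets
#'
#' Finds the scale, rotation and translation minimizing
#' `sum_i || Y_i - (s R X_i + t) ||^2` (Umeyama's closed-form solution) and
#' returns the aligned copy of `X` together with the residual RMS distance.
#' Used to remove the global similarity gauge before comparing a recovered
#' camera/point configuration with ground truth.
#'
#' @param X,Y n x 3 matrices of corresponding points.
#' @param scale logical; estimate a scale factor (default `TRUE`).
#' @return list with `aligned` (n x 3), `rotation`, `scale`, `translation`,
#'   and `rmsd`.
#' @export
align_similarity <- function(X, Y, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(all(dim(X) == dim(Y)), ncol(X) == 3, nrow(X) >= 3)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  D <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) D[3, 3] <- -1
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (scale) {
    varx <- sum(Xc^2) / nrow(X)
    sum(diag(D) * sv$d) / varx
  } else 1
  t0 <- my - s * as.numeric(R %*% mx)
  aligned <- s * X %*% t(R) + rep(t0, each = nrow(X))
  list(aligned = aligned, rotation = R, scale = s, translation = t0,
       rmsd = sqrt(mean(rowSums((aligned - Y)^2))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
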