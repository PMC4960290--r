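# Cross-block association statistics: the RV coefficient (implemented
# chiefly to make its critiqued rotation invariance demonstrable), the SVD
# of the cross-covariance block (the recommended alternative, which keeps
# the directional structure the RV throws away), and the Mantel-style
# regression of one distance upon another through the origin.

check_block <- function(M, name) {
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop(name, " contains non-finite values")
  v <- apply(M, 2, var)
  if (any(v <= 0)) stop(name, " has zero-variance column(s): ",
                        paste(which(v <= 0), collapse = ", "))
  M
}

#' RV coefficient of two blocks of variables
#'
#' Escoufier's normalization:
#' `RV = tr(Sxy Syx) / sqrt(tr(Sxx^2) tr(Syy^2))` with S the sample
#' covariance blocks (n-1 denominator).  The statistic is invariant under
#' separate orthogonal rotation of either block -- the very invariance that
#' makes it a poor summary of biological cross-covariance, since rotating
#' one block's variables among themselves changes the biology but not the
#' RV.
#'
#' @param X,Y n x p and n x q data blocks (matching rows).
#' @return scalar in [0, 1].
#' @export
rv_coefficient <- function(X, Y) {
  X <- check_block(X, "X"); Y <- check_block(Y, "Y")
  if (nrow(X) != nrow(Y)) stop("X and Y need the same number of rows")
  if (nrow(X) < 3) stop("need n >= 3")
  Sxx <- cov(X); Syy <- cov(Y); Sxy <- cov(X, Y)
  sum(Sxy^2) / sqrt(sum(Sxx^2) * sum(Syy^2))
}

#' Two-block partial least squares via SVD of the cross-covariance
#'
#' Singular value decomposition of `Sxy`; each singular value is the
#' covariance of the corresponding pair of unit-coefficient linear
#' combinations (X scores, Y scores), so the individual axes stay
#' interpretable, unlike the single-number RV summary.  The sum of squared
#' singular values equals the RV numerator `tr(Sxy Syx)`.
#'
#' @param X,Y data blocks.
#' @param n_pairs number of singular pairs to return.
#' @return list with `singular_values`, `x_axes`, `y_axes` (unit-norm
#'   columns), `x_scores`, `y_scores` (centered data projected on axes).
#' @export
pls_svd <- function(X, Y, n_pairs = NULL) {
  X <- check_block(X, "X"); Y <- check_block(Y, "Y")
  if (nrow(X) != nrow(Y)) stop("X and Y need the same number of rows")
  if (nrow(X) < 3) stop("need n >= 3")
  Sxy <- cov(X, Y)
  r <- min(dim(Sxy))
  if (is.null(n_pairs)) n_pairs <- r
  if (n_pairs > r) stop("n_pairs = ", n_pairs, " exceeds min(p, q) = ", r)
  s <- svd(Sxy, nu = n_pairs, nv = n_pairs)
  u <- apply(s$u, 2, canon_sign)
  # keep each pair's covariance positive after sign canonicalization of u
  v <- s$v
  for (j in seq_len(n_pairs))
    if (sum(u[, j] * s$u[, j]) < 0) v[, j] <- -v[, j]
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  list(singular_values = s$d[seq_len(n_pairs)], x_axes = u, y_axes = v,
       x_scores = Xc %*% u, y_scores = Yc %*% v)
}

#' Regression of one distance upon another, through the origin
#'
#' The Mantel-style scalar summary: `slope = sum(d1 * d2) / sum(d1^2)` over
#' the unordered off-diagonal pairs.  A regression slope (not a
#' correlation) and forced through (0, 0): zero distance must predict zero
#' distance.  Optionally a permutation diagnostic (off by default).
#'
#' @param d1,d2 `dist` objects or numeric vectors of matching pairwise
#'   distances (each unordered pair once, diagonals excluded).
#' @param n_perm if > 0, permute objects of `d2` this many times and report
#'   the permuted-slope distribution alongside.
#' @param seed seed for the permutation diagnostic.
#' @return scalar slope; with `n_perm > 0`, a list `slope`, `perm_slopes`.
#' @export
distance_regression <- function(d1, d2, n_perm = 0, seed = 1) {
  v1 <- if (inherits(d1, "dist")) as.vector(d1) else as.numeric(d1)
  v2 <- if (inherits(d2, "dist")) as.vector(d2) else as.numeric(d2)
  if (length(v1) != length(v2)) stop("distance sets differ in length")
  if (all(v1 == 0)) stop("all d1 distances are zero: slope undefined")
  slope <- sum(v1 * v2) / sum(v1^2)
  if (n_perm > 0) {
    if (!inherits(d2, "dist"))
      stop("permutation diagnostic needs d2 as a 'dist' object")
    m2 <- as.matrix(d2)
    n <- nrow(m2)
    rng <- local_rng(seed)
    ps <- vapply(seq_len(n_perm), function(b) {
      p <- rng$sample(n)
      mp <- m2[p, p]
      sum(v1 * mp[lower.tri(mp)]) / sum(v1^2)
    }, 0)
    return(list(slope = slope, perm_slopes = ps))
  }
  slope
}
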