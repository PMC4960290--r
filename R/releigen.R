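# Relative eigenanalysis: eigenstructure of one SPD matrix in the metric of
# another, and the congruence-invariant log-eigenvalue distance between
# covariance structures.

check_sym <- function(A, name, tol = 1e-9) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop(name, " must be square")
  if (max(abs(A - t(A))) > tol * max(1, max(abs(A)))) stop(name, " is not symmetric")
  (A + t(A)) / 2
}

#' Relative eigenanalysis of A with respect to B
#'
#' Solves the generalized problem `A v = lambda B v` for symmetric A and
#' positive-definite B, via Cholesky whitening of B followed by a symmetric
#' eigensolve (stable for ill-conditioned B).  Relative eigenvalues are the
#' variance ratios along directions conjugate in both quadratic forms at
#' once; they are invariant under any joint congruence A -> MAM', B -> MBM'.
#'
#' @param A symmetric p x p matrix (may be PSD; zero eigenvalues are
#'   flagged in the result).
#' @param B symmetric positive-definite p x p matrix.
#' @param tol symmetry / rank tolerance.
#' @return object of class `relative_eigen`: `values` (descending),
#'   `vectors` (columns, B-orthonormal: v' B v = I), `distance`
#'   (sqrt(sum(log(values)^2)); `Inf` when A is rank-deficient),
#'   `null_rank` (number of nonpositive relative eigenvalues).
#' @export
relative_eigen <- function(A, B, tol = 1e-9) {
  A <- check_sym(A, "A", tol); B <- check_sym(B, "B", tol)
  if (nrow(A) != nrow(B)) stop("A and B must have the same dimension")
  L <- tryCatch(chol(B), error = function(e) {
    ns <- eigen(B, symmetric = TRUE)
    bad <- which(ns$values < max(ns$values) * 1e-12)
    stop("B is singular (null directions: eigenvector index ",
         paste(bad, collapse = ", "), ")")
  })
  # chol gives B = L'L with L upper triangular: whiten with L^-T A L^-1
  Linv <- backsolve(L, diag(nrow(B)))
  M <- t(Linv) %*% A %*% Linv
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  vals <- ev$values
  vecs <- Linv %*% ev$vectors
  vecs <- apply(vecs, 2, canon_sign)
  null_rank <- sum(vals <= tol * max(abs(vals), 1))
  dist <- if (null_rank > 0) Inf else sqrt(sum(log(vals)^2))
  structure(list(values = vals, vectors = vecs, distance = dist,
                 null_rank = null_rank),
            class = "relative_eigen")
}

#' @export
print.relative_eigen <- function(x, ...) {
  cat("Relative eigenanalysis: p =", length(x$values), "\n  eigenvalues:",
      paste(format(x$values, digits = 4), collapse = " "),
      "\n  log-eigenvalue distance:", format(x$distance, digits = 6), "\n")
  invisible(x)
}

#' Log-eigenvalue distance between covariance structures
#'
#' `sqrt(sum(log(lambda_i)^2))` over the relative eigenvalues of A with
#' respect to B.  Symmetric in its arguments, zero iff A = B, and invariant
#' under joint congruence -- so it does not depend on the basis in which
#' the two covariance structures are expressed.  Successive inflations of
#' one factor move the structure along a straight line in this metric
#' (their lengths add on the log scale).
#'
#' @param A,B symmetric positive-definite matrices of equal size.
#' @return nonnegative scalar (`Inf` if either matrix is rank-deficient).
#' @export
covariance_distance <- function(A, B) {
  relative_eigen(A, B)$distance
}
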