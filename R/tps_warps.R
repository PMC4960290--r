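# Thin-plate-spline bending energy and partial warps.
#
# Kernel convention: U(r) = r^2 log r in 2D (U(0) = 0), |r| in 3D.  Any
# constant factor on U rescales all bending-energy eigenvalues jointly,
# which shifts log-BE by a constant and leaves BE-PWV regression slopes
# invariant; the convention matters only when comparing raw eigenvalues
# across implementations.

tps_kernel <- function(r, d = 2L) {
  if (d == 2L) ifelse(r > 0, r^2 * log(r), 0) else r
}

# pairwise-distance kernel matrix between point sets (rows are points)
kernel_matrix <- function(P, Q = P, d = ncol(P)) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)
  d2[d2 < 0] <- 0
  tps_kernel(sqrt(d2), d)
}

#' Bending-energy matrix of a mean form
#'
#' The k x k quadratic form of the thin-plate spline on per-landmark
#' displacements: with kernel matrix K between the mean landmarks and
#' affine border Q = cbind(1, x, y), it is the upper-left k x k block of
#' the inverse of the bordered system.  Positive semidefinite of rank
#' k - 3 in 2D (rank k - 4 in 3D): affine displacement fields bend nothing.
#' In 3D the square of the matrix is what the deflation rule uses.
#'
#' @param ref a `mean_form` from [standardize_mean()] (k >= 4 in 2D).
#' @return symmetric k x k matrix.
#' @export
bending_energy_matrix <- function(ref) {
  stopifnot(inherits(ref, "mean_form"))
  d <- ref$d; k <- ref$k
  if (k < d + 2) stop("bending energy needs k >= ", d + 2, " landmarks")
  P <- matrix(ref$mu, ncol = d, byrow = TRUE)
  if (min(dist(P)) < 1e-12) stop("coincident landmarks: singular TPS kernel")
  K <- kernel_matrix(P, d = d)
  Q <- cbind(1, P)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, d + 1, d + 1)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  B <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  B <- (B + t(B)) / 2
  dimnames(B) <- list(ref$labels, ref$labels)
  B
}

# canonical sign: largest-|coordinate| entry positive (first on tie)
canon_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Partial-warp basis of a mean form
#'
#' Eigendecomposition of the bending-energy matrix restricted to its
#' positive eigenspace.  Eigenvalues are returned ascending, so the
#' largest-scale (smallest bending energy) warp comes first.  The uniform
#' (affine) shape subspace -- the two dimensions of zero bending energy
#' left after the J rows are removed in 2D -- is returned as an orthonormal
#' basis of dk-vectors.  Eigenvalue ties (symmetric configurations such as
#' grids) are ordered deterministically by the sign-canonicalized
#' eigenvector coordinates.
#'
#' @param ref a `mean_form`.
#' @param tol relative tolerance separating zero from positive eigenvalues.
#' @return object of class `partial_warp_basis`: `be_matrix`, `eigenvalues`
#'   (length k-3 in 2D, ascending), `warp_vectors` (k x (k-3), columns are
#'   unit k-vectors), `uniform_basis` (dk x 2 in 2D), `reference`.
#' @export
partial_warp_basis <- function(ref, tol = 1e-9) {
  B <- bending_energy_matrix(ref)
  k <- ref$k; d <- ref$d
  ev <- eigen(B, symmetric = TRUE)
  vals <- rev(ev$values); vecs <- ev$vectors[, rev(seq_len(k)), drop = FALSE]
  pos <- vals > tol * max(vals)
  nzero <- sum(!pos)
  expect_zero <- d + 1L
  if (nzero != expect_zero)
    warning("expected ", expect_zero, " zero bending-energy eigenvalues, found ",
            nzero)
  vals <- vals[pos]; vecs <- vecs[, pos, drop = FALSE]
  vecs <- apply(vecs, 2, canon_sign)
  # deterministic order within (near-)ties
  o <- order(round(vals / max(vals), 9),
             apply(vecs, 2, function(v) paste(sprintf("%+.6f", v), collapse = "")))
  vals <- vals[o]; vecs <- vecs[, o, drop = FALSE]
  uniform <- uniform_basis(ref, B, tol)
  structure(list(be_matrix = B, eigenvalues = vals, warp_vectors = vecs,
                 uniform_basis = uniform, reference = ref),
            class = "partial_warp_basis")
}

# orthonormal basis of the affine shape subspace (zero bending energy,
# orthogonal to the J rows)
uniform_basis <- function(ref, B, tol = 1e-9) {
  d <- ref$d; k <- ref$k
  P <- matrix(ref$mu, ncol = d, byrow = TRUE)
  # affine displacement fields: d*(d+1) of them (translation + linear part)
  fields <- list()
  for (i in seq_len(d)) {
    e <- numeric(d); e[i] <- 1
    fields[[length(fields) + 1]] <- matrix(e, k, d, byrow = TRUE)
    for (j in seq_len(d))
      fields[[length(fields) + 1]] <- outer(P[, j], e)
  }
  A <- do.call(cbind, lapply(fields, function(f) as.vector(t(f))))
  A <- project_to_shape_space(t(A), ref)   # rows = projected fields
  s <- svd(t(A))
  keep <- s$d > tol * max(s$d, 1)
  U <- s$u[, keep, drop = FALSE]
  apply(U, 2, canon_sign)
}

#' @export
print.partial_warp_basis <- function(x, ...) {
  cat("Partial-warp basis: k =", x$reference$k, "landmarks,",
      length(x$eigenvalues), "positive bending-energy eigenvalues\n")
  invisible(x)
}

# dk x m matrix whose columns are the warp directions for axis `axis`
# (warp eigenvector placed in that Cartesian slot, zeros elsewhere)
warp_directions <- function(basis, axis) {
  d <- basis$reference$d; k <- basis$reference$k
  m <- ncol(basis$warp_vectors)
  out <- matrix(0, d * k, m)
  idx <- (seq_len(k) - 1) * d + axis
  out[idx, ] <- basis$warp_vectors
  out
}

#' Partial-warp scores of shape vectors
#'
#' Projects dk-vectors (rows of `V`) on each warp direction per Cartesian
#' axis.  Input is J-projected internally against the basis reference.
#'
#' @param V n x dk matrix (or single vector) of coordinate rows.
#' @param basis a [partial_warp_basis()].
#' @return n x (m*d) matrix; columns ordered warp-major
#'   (warp1_x, warp1_y, warp2_x, ...).
#' @export
partial_warp_scores <- function(V, basis) {
  if (!is.matrix(V)) V <- matrix(V, nrow = 1)
  ref <- basis$reference
  V <- project_to_shape_space(V, ref)
  d <- ref$d
  W <- do.call(cbind, lapply(seq_len(d), function(a) warp_directions(basis, a)))
  m <- ncol(basis$warp_vectors)
  sc <- V %*% W                       # axis-major: all x-scores then y-scores
  perm <- as.vector(t(matrix(seq_len(m * d), m, d)))
  sc <- sc[, perm, drop = FALSE]
  colnames(sc) <- paste0("warp", rep(seq_len(m), each = d), "_",
                         rep(c("x", "y", "z")[seq_len(d)], m))
  sc
}

#' Thin-plate-spline deformation grid
#'
#' Fits the TPS interpolant carrying `source` landmarks exactly onto
#' `target` and evaluates it on a rectangular grid covering the source, for
#' plotting as deformation-grid polylines.
#'
#' @param source,target [landmark_config()] objects with matching labels (2D).
#' @param grid_density number of grid lines per axis (default 20).
#' @param margin fractional margin around the source bounding box.
#' @return object of class `tps_grid`: list with `rows` and `cols` (lists of
#'   polyline coordinate matrices in target space), `warp` (the interpolant
#'   as a function of an m x 2 matrix), `source`, `target`.
#' @export
tps_grid <- function(source, target, grid_density = 20, margin = 0.1) {
  S <- unclass(as.matrix(source)); Tm <- unclass(as.matrix(target))
  if (ncol(S) != 2) stop("tps_grid is 2D only")
  if (!identical(rownames(S), rownames(Tm)))
    stop("source and target must share landmark labels")
  k <- nrow(S)
  if (min(dist(S)) < 1e-12) stop("coincident source landmarks: singular kernel")
  K <- kernel_matrix(S)
  Q <- cbind(1, S)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  coefs <- solve(L, rbind(Tm, matrix(0, 3, 2)))
  W <- coefs[seq_len(k), , drop = FALSE]
  Aaff <- coefs[k + 1:3, , drop = FALSE]
  warp <- function(P) {
    P <- matrix(P, ncol = 2)
    U <- kernel_matrix(P, S)
    cbind(1, P) %*% Aaff + U %*% W
  }
  rng <- apply(S, 2, range)
  pad <- margin * diff(rng)
  xs <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = grid_density)
  ys <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = grid_density)
  fine <- 5L * grid_density
  rows <- lapply(ys, function(y)
    warp(cbind(seq(min(xs), max(xs), length.out = fine), y)))
  cols <- lapply(xs, function(x)
    warp(cbind(x, seq(min(ys), max(ys), length.out = fine))))
  structure(list(rows = rows, cols = cols, warp = warp,
                 source = S, target = Tm),
            class = "tps_grid")
}

#' @export
plot.tps_grid <- function(x, ...) {
  allpts <- do.call(rbind, c(x$rows, x$cols))
  plot(allpts, type = "n", asp = 1, xlab = "", ylab = "", ...)
  for (p in x$rows) lines(p, col = "grey40")
  for (p in x$cols) lines(p, col = "grey40")
  graphics::points(x$target, pch = 19)
  invisible(x)
}
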