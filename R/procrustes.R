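# Procrustes / Boas superposition via the explicit J-matrix formulation.
#
# The reference frame for a shape analysis is a standardized mean form mu
# (centered, unit centroid size, principal axes horizontal/vertical) together
# with the 4 x 2k matrix J whose orthonormal rows span the translation (2),
# rotation (1) and scale (1) directions at mu.  Projecting those rows out of
# a raw coordinate vector is, to first order in shape variation, the
# Procrustes superposition itself.

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid.  Linear in scale, invariant under rotation and translation.
#'
#' @param config a [landmark_config()] or a k x d coordinate matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  m <- unclass(as.matrix(config))
  cs2 <- sum(scale(m, scale = FALSE)^2)
  if (cs2 <= 0) stop("all landmarks coincide: centroid size is zero")
  sqrt(cs2)
}

# 2x2 rotation by angle theta (counterclockwise)
rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

# optimal rotation (det +1) taking configuration X onto Y, both centered
kabsch <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- ncol(X)
  sg <- diag(c(rep(1, d - 1), sign(det(s$u) * det(s$v))), d)
  s$u %*% sg %*% t(s$v)
}

#' Standardize a mean form and assemble its J matrix
#'
#' Centers the configuration, scales it to unit centroid size, and (in 2D)
#' rotates it to principal axes so that the coordinate sums satisfy
#' sum(x) = sum(y) = sum(xy) = 0 and sum(x^2 + y^2) = 1.  The returned J is
#' the 4 x 2k matrix with rows (1/sqrt(k), 0, ...), (0, 1/sqrt(k), ...),
#' (-y1, x1, ..., -yk, xk) and (x1, y1, ..., xk, yk); its rows are
#' orthonormal.  The rotation's sign ambiguity (a half-turn leaves the
#' principal axes fixed) is resolved by requiring the first landmark with a
#' non-negligible x-coordinate to have it nonnegative.
#'
#' In 3D only centering and scaling are performed (no canonical orientation)
#' and J generalizes to 7 x 3k: three translations, three infinitesimal
#' rigid rotations, and the scale direction, orthonormalized.
#'
#' @param config a [landmark_config()] or coordinate matrix (k >= 3,
#'   non-collinear in 2D).
#' @return object of class `mean_form`: list with `mu` (interleaved
#'   coordinate vector), `J`, `k`, `d`, `labels`.
#' @export
standardize_mean <- function(config) {
  m <- unclass(as.matrix(config))
  k <- nrow(m); d <- ncol(m)
  labels <- rownames(m)
  if (k < 3) stop("standardize_mean needs k >= 3 landmarks")
  m <- scale(m, scale = FALSE)
  attr(m, "scaled:center") <- NULL
  cs <- sqrt(sum(m^2))
  if (cs <= 0) stop("degenerate configuration: zero centroid size")
  m <- m / cs
  if (d == 2) {
    M <- crossprod(m)              # 2x2 second-moment matrix
    ev <- eigen(M, symmetric = TRUE)
    if (ev$values[2] < 1e-12) stop("degenerate configuration: landmarks are collinear")
    if ((ev$values[1] - ev$values[2]) > 1e-12 * ev$values[1]) {
      R <- ev$vectors
      if (det(R) < 0) R[, 2] <- -R[, 2]
      m <- m %*% R                 # principal axes horizontal/vertical
    }                              # isotropic moments: any frame works; keep input frame
    # half-turn sign rule: first landmark with |x| above tolerance gets x >= 0
    ix <- which(abs(m[, 1]) > 1e-9)
    if (length(ix) && m[ix[1], 1] < 0) m <- -m
  }
  mu <- as.vector(t(m))
  structure(list(mu = mu, J = j_matrix(m), k = k, d = d, labels = labels),
            class = "mean_form")
}

# rows of J for a centered, unit-centroid-size configuration
j_matrix <- function(m) {
  k <- nrow(m); d <- ncol(m)
  if (d == 2) {
    x <- m[, 1]; y <- m[, 2]
    J <- rbind(as.vector(rbind(rep(1 / sqrt(k), k), 0)),
               as.vector(rbind(0, rep(1 / sqrt(k), k))),
               as.vector(rbind(-y, x)),
               as.vector(rbind(x, y)))
    rownames(J) <- c("translate_x", "translate_y", "rotate", "scale")
  } else {
    x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
    zero <- rep(0, k)
    raw <- rbind(as.vector(rbind(rep(1, k), 0, 0)) / sqrt(k),
                 as.vector(rbind(0, rep(1, k), 0)) / sqrt(k),
                 as.vector(rbind(0, 0, rep(1, k))) / sqrt(k),
                 as.vector(rbind(zero, -z, y)),   # rotation about x
                 as.vector(rbind(z, zero, -x)),   # rotation about y
                 as.vector(rbind(-y, x, zero)),   # rotation about z
                 as.vector(rbind(x, y, z)))
    # rotation rows need not be mutually orthonormal: Gram-Schmidt
    J <- raw
    for (i in seq_len(nrow(J))) {
      v <- J[i, ]
      if (i > 1) v <- v - t(J[seq_len(i - 1), , drop = FALSE]) %*%
          (J[seq_len(i - 1), , drop = FALSE] %*% v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) stop("degenerate 3D configuration: rank-deficient rotation space")
      J[i, ] <- v / nv
    }
    rownames(J) <- c("translate_x", "translate_y", "translate_z",
                     "rotate_x", "rotate_y", "rotate_z", "scale")
  }
  J
}

#' @export
print.mean_form <- function(x, ...) {
  cat("Standardized mean form: k =", x$k, "landmarks in", x$d, "D; J is",
      nrow(x$J), "x", ncol(x$J), "\n")
  invisible(x)
}

mean_form_config <- function(ref)
  vec_to_config(ref$mu, d = ref$d, labels = ref$labels, specimen_id = "mean")

#' Project coordinate vectors into shape space
#'
#' Subtracts from `C` its components along every row of the reference's J
#' matrix: `C - sum_i J_i' (J_i C)`.  The result is orthogonal to the
#' translation, rotation and scale directions at the reference mean.  The
#' projection is idempotent and translation-invariant.
#'
#' @param C numeric vector of length d*k (interleaved x1,y1,...), or an
#'   n x dk matrix of such rows, or a [landmark_config()].
#' @param ref a `mean_form` from [standardize_mean()].
#' @param rows which J rows to project out (default all).
#' @return object of the same shape as `C` (vector or matrix).
#' @export
project_to_shape_space <- function(C, ref, rows = seq_len(nrow(ref$J))) {
  J <- ref$J[rows, , drop = FALSE]
  if (inherits(C, "landmark_config")) C <- config_to_vec(C)
  if (is.matrix(C)) {
    if (ncol(C) != ncol(J)) stop("dimension mismatch: expected ", ncol(J),
                                 " columns, got ", ncol(C))
    C - (C %*% t(J)) %*% J
  } else {
    if (length(C) != ncol(J)) stop("dimension mismatch: expected length ",
                                   ncol(J), ", got ", length(C))
    as.vector(C - t(J) %*% (J %*% C))
  }
}

#' Generalized Procrustes superposition (scaled or Boas)
#'
#' Iterative Gower-style fit: center every configuration, optionally scale
#' to unit centroid size, rotate (rotations only, det +1) to the running
#' mean, and re-estimate the mean until it moves by less than `recenter_tol`
#' in Procrustes distance.  With `scale = FALSE` the scaling step is skipped
#' throughout and the aligned coordinates are Boas coordinates, which retain
#' size.
#'
#' @param sample a [landmark_sample()] with n >= 2.
#' @param scale logical; divide out centroid size? (`FALSE` = Boas fit.)
#' @param recenter_tol convergence tolerance on the change of the mean.
#' @param max_iter iteration cap.
#' @return object of class `procrustes_fit`: `coords` (n x dk aligned
#'   coordinate rows in the frame of the standardized mean), `shape_coords`
#'   (residuals about the reference with J rows projected out: all rows for
#'   a scaled fit, translation+rotation rows only for a Boas fit),
#'   `centroid_sizes`, `rotations` (2D: net angle applied per specimen),
#'   `reference` (a `mean_form`), `scaled`, `iterations`.
#' @export
gpa <- function(sample, scale = TRUE, recenter_tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(sample, "landmark_sample"))
  n <- length(sample)
  if (n < 2) stop("GPA needs n >= 2 configurations")
  k <- n_landmarks(sample); d <- n_dim(sample)
  configs <- lapply(seq_len(n), function(i) {
    m <- scale(sample$coords[, , i], scale = FALSE)
    attr(m, "scaled:center") <- NULL
    m
  })
  sizes <- vapply(configs, function(m) sqrt(sum(m^2)), 0)
  if (any(sizes <= 0)) stop("degenerate configuration (zero centroid size) at index ",
                            which(sizes <= 0)[1])
  work <- if (scale) Map(`/`, configs, sizes) else configs
  mn <- work[[1]]
  delta <- Inf; it <- 0L
  while (delta > recenter_tol && it < max_iter) {
    it <- it + 1L
    work <- lapply(work, function(m) m %*% kabsch(m, mn))
    mn_new <- Reduce(`+`, work) / n
    mn_new <- scale(mn_new, scale = FALSE)
    attr(mn_new, "scaled:center") <- NULL
    if (scale) mn_new <- mn_new / sqrt(sum(mn_new^2))
    delta <- sqrt(sum((mn_new - mn)^2)) / sqrt(sum(mn_new^2))
    mn <- mn_new
  }
  if (delta > recenter_tol)
    stop("GPA did not converge in ", max_iter,
         " iterations (last mean change ", format(delta), ")")
  ref <- standardize_mean(landmark_config(mn, labels = sample$labels))
  mu_m <- matrix(ref$mu, ncol = d, byrow = TRUE)
  aligned <- lapply(work, function(m) m %*% kabsch(m, mu_m))
  rotations <- if (d == 2)
    vapply(seq_len(n), function(i) {
      R <- kabsch(configs[[i]], mu_m)
      atan2(R[1, 2], R[1, 1])
    }, 0) else rep(NA_real_, n)
  coords <- do.call(rbind, lapply(aligned, function(m) as.vector(t(m))))
  rownames(coords) <- sample$specimen_ids
  shape_coords <- if (scale) project_to_shape_space(coords, ref)
  else project_to_shape_space(coords, ref, rows = seq_len(nrow(ref$J) - 1L))
  structure(list(coords = coords, shape_coords = shape_coords,
                 centroid_sizes = sizes, rotations = rotations,
                 reference = ref, scaled = scale, iterations = it,
                 labels = sample$labels, specimen_ids = sample$specimen_ids,
                 d = d, k = k),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(if (x$scaled) "Procrustes" else "Boas (unscaled)",
      "fit: n =", nrow(x$coords), "specimens, k =", x$k, "landmarks,",
      x$iterations, "iterations\n")
  invisible(x)
}

# center + unit-scale a config matrix; returns matrix
unit_config <- function(m) {
  m <- scale(unclass(as.matrix(m)), scale = FALSE)
  attr(m, "scaled:center") <- NULL
  m / sqrt(sum(m^2))
}

#' Procrustes distance between two configurations
#'
#' In `"local"` mode, the mode the recentering argument calls for, both
#' forms are put on unit centroid size, rotated together, and projected
#' through the J matrix of their own pairwise mean; the distance is the
#' Euclidean norm of the difference of the projected vectors.  In
#' `"reference"` mode the projection uses a supplied reference frame
#' instead, so that distances across many pairs share one registration.
#'
#' @param a,b [landmark_config()] objects with identical labels.
#' @param mode `"local"` or `"reference"`.
#' @param ref a `mean_form`, required for `mode = "reference"`.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b, mode = c("local", "reference"),
                                ref = NULL) {
  mode <- match.arg(mode)
  if (!identical(rownames(a), rownames(b)))
    stop("configurations must share landmark labels and order")
  A <- unit_config(a); B <- unit_config(b)
  if (mode == "local") {
    B <- B %*% kabsch(B, A)
    M <- unit_config((A + B) / 2)
    J <- j_matrix(M)
    dv <- as.vector(t(A - B))
    dv <- dv - t(J) %*% (J %*% dv)
    sqrt(sum(dv^2))
  } else {
    if (is.null(ref)) stop("mode = 'reference' needs a ref mean_form")
    mu_m <- matrix(ref$mu, ncol = ref$d, byrow = TRUE)
    A <- A %*% kabsch(A, mu_m)
    B <- B %*% kabsch(B, mu_m)
    dv <- project_to_shape_space(as.vector(t(A - B)), ref)
    sqrt(sum(dv^2))
  }
}

#' Allometric regression diagnostics in Boas coordinates
#'
#' For every landmark, regresses its Boas (unscaled, superimposed)
#' coordinates on a size variable and compares the regression vector with
#' the radial direction from the centroid to the landmark's mean position.
#' When the third and fourth rows of J are set optimally for the data, the
#' regression vectors point along those radial lines; angular misalignment
#' flags landmarks whose size dependence the standard superposition
#' misregisters.
#'
#' @param fit a Boas [gpa()] fit (`scale = FALSE`).
#' @param size_var positive size variable per specimen; defaults to the
#'   centroid sizes stored in the fit.
#' @return data.frame with one row per landmark: regression slopes
#'   (`slope_x`, `slope_y`), mean position, unit radial direction,
#'   `misalign_deg` (angle in degrees between the two, 0 = perfectly
#'   radial), and `slope_norm`.
#' @export
boas_allometry <- function(fit, size_var = NULL) {
  stopifnot(inherits(fit, "procrustes_fit"))
  if (fit$scaled) stop("boas_allometry needs an unscaled (Boas) fit")
  if (fit$d != 2) stop("boas_allometry is implemented for 2D fits")
  if (is.null(size_var)) size_var <- fit$centroid_sizes
  if (any(size_var <= 0)) stop("size_var must be strictly positive")
  if (var(size_var) == 0) stop("size_var has zero variance")
  k <- fit$k
  sv <- size_var - mean(size_var)
  denom <- sum(sv^2)
  out <- data.frame(label = fit$labels, slope_x = NA_real_, slope_y = NA_real_,
                    mean_x = NA_real_, mean_y = NA_real_,
                    radial_x = NA_real_, radial_y = NA_real_,
                    misalign_deg = NA_real_, slope_norm = NA_real_,
                    stringsAsFactors = FALSE)
  for (l in seq_len(k)) {
    xs <- fit$coords[, 2 * l - 1]; ys <- fit$coords[, 2 * l]
    bx <- sum(sv * (xs - mean(xs))) / denom
    by <- sum(sv * (ys - mean(ys))) / denom
    mx <- mean(xs); my <- mean(ys)
    rn <- sqrt(mx^2 + my^2)
    rx <- mx / rn; ry <- my / rn
    sn <- sqrt(bx^2 + by^2)
    ang <- if (sn > 0) acos(pmin(1, pmax(-1, (bx * rx + by * ry) / sn))) * 180 / pi
    else NA_real_
    out[l, -1] <- c(bx, by, mx, my, rx, ry, ang, sn)
  }
  out
}

#' Shape-space direction of an interlandmark distance
#'
#' Builds the gradient of the distance between two named landmarks (equal
#' and opposite unit vectors at the two landmarks, pointing apart, zero
#' elsewhere), removes its components along all rows of the reference J
#' (the scale row carries the gradient's interaction with the superposition;
#' the translation and rotation rows are annihilated anyway for this
#' centered, torque-free field), and normalizes.
#'
#' @param ref a `mean_form`.
#' @param pair character vector of two distinct landmark labels.
#' @return unit dk-vector (class numeric) with attribute `raw_norm`, the
#'   norm of the projected raw gradient (the rate of change of the
#'   interlandmark distance per unit motion along the returned direction).
#' @export
distance_gradient <- function(ref, pair) {
  stopifnot(inherits(ref, "mean_form"))
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must name two distinct landmarks")
  idx <- match(pair, ref$labels)
  if (any(is.na(idx))) stop("unknown landmark label: ",
                            paste(pair[is.na(idx)], collapse = ", "))
  d <- ref$d
  mu_m <- matrix(ref$mu, ncol = d, byrow = TRUE)
  u <- mu_m[idx[1], ] - mu_m[idx[2], ]
  nu <- sqrt(sum(u^2))
  if (nu <= 0) stop("the two landmarks coincide in the mean form")
  u <- u / nu
  g <- numeric(d * ref$k)
  g[(idx[1] - 1) * d + seq_len(d)] <- u
  g[(idx[2] - 1) * d + seq_len(d)] <- -u
  gp <- project_to_shape_space(g, ref)
  ng <- sqrt(sum(gp^2))
  if (ng <= 0) stop("gradient vanishes after projection")
  structure(gp / ng, raw_norm = ng)
}
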