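# Synthetic-data generators: every fixture the toolkit's tests and demos
# need, built in code with explicit seeds.  Grids, offset isotropic
# Mardia-Dryden samples, the canonical deformation-pattern vocabulary
# (uniform / growth gradient / Pinocchio / random direction), Brownian
# shape evolution on trees, and factor-model correlation matrices.

#' Rectangular landmark grid
#'
#' `rows x cols` lattice with unit (or given) spacing, row-major labels
#' `rXcY`.  The 7 x 7 grid is the canonical mean form for the deflated
#' reference distribution (49 landmarks, 46 partial warps).
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @param spacing lattice spacing (length units).
#' @return a [landmark_config()].
#' @export
grid_config <- function(rows, cols, spacing = 1) {
  if (rows < 2 || cols < 2) stop("grid needs rows, cols >= 2")
  pts <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  coords <- cbind((pts$col - 1) * spacing, (pts$row - 1) * spacing)
  labels <- paste0("r", pts$row, "c", pts$col)
  landmark_config(coords, labels = labels, specimen_id = "grid")
}

#' Random non-symmetric polygon mean form
#'
#' Convenience generator of a generic k-gon (points on a circle with
#' seeded radial/angular jitter), useful wherever a mean form without the
#' eigenvalue multiplicities of a symmetric grid is wanted.
#'
#' @param k number of landmarks.
#' @param seed integer seed.
#' @param jitter relative jitter amplitude.
#' @return a [landmark_config()].
#' @export
polygon_config <- function(k, seed = 1, jitter = 0.25) {
  rng <- local_rng(seed)
  th <- 2 * pi * seq_len(k) / k + jitter * rng$runif(k, -0.5, 0.5)
  r <- 1 + jitter * rng$runif(k, -1, 1)
  landmark_config(cbind(r * cos(th), r * sin(th)),
                  specimen_id = paste0("polygon", k))
}

#' Sample an offset isotropic Mardia-Dryden distribution
#'
#' Independent Gaussian perturbation of every Cartesian coordinate of the
#' mean: configurations are draws from N(mu, sigma^2 I).  This is the
#' distribution whose shape statistics the plain Procrustes machinery
#' implicitly assumes.
#'
#' @param mean a [landmark_config()] or `mean_form` (its mu is used).
#' @param n number of configurations.
#' @param sigma per-coordinate standard deviation (same length units as
#'   the mean).
#' @param seed integer seed.
#' @return a [landmark_sample()].
#' @export
sample_isotropic <- function(mean, n, sigma, seed) {
  stopifnot(n >= 1, sigma > 0)
  if (inherits(mean, "mean_form")) mean <- mean_form_config(mean)
  m <- unclass(as.matrix(mean))
  k <- nrow(m); d <- ncol(m)
  rng <- local_rng(seed)
  V <- matrix(rep(as.vector(t(m)), n), nrow = n, byrow = TRUE) +
    matrix(rng$rnorm(n * k * d, sd = sigma), n, k * d)
  matrix_to_sample(V, d = d, labels = rownames(m), prefix = "iso")
}

#' Canonical deformation-pattern fields
#'
#' Generates a single shape-space direction of one of four kinds, all
#' rescaled to the requested Procrustes length after J-projection so they
#' are directly comparable:
#' * `"uniform"`: an affine (zero bending energy) field, a mix of the two
#'   uniform basis directions at angle `direction`;
#' * `"gradient"`: a growth gradient, displacement `(a + b s) u` where `s`
#'   is position along the unit axis `u` at angle `direction` (defaults
#'   a = 0, b = 1);
#' * `"pinocchio"`: a single landmark (`landmark`) displaced along
#'   `direction`, all others fixed (before projection);
#' * `"random"`: independent circular Gaussian displacement of every
#'   landmark (a direction with no meaning at all).
#'
#' @param ref a `mean_form`.
#' @param kind pattern kind.
#' @param amplitude requested post-projection Procrustes length.
#' @param direction angle in radians parameterizing the field.
#' @param landmark label (or index) of the displaced landmark for
#'   `"pinocchio"`.
#' @param a,b growth-gradient coefficients.
#' @param seed seed, used by `"random"` only.
#' @return dk-vector (shape-space direction of stated Procrustes length).
#' @export
pattern_field <- function(ref, kind = c("uniform", "gradient", "pinocchio",
                                        "random"),
                          amplitude = 0.1, direction = 0, landmark = 1,
                          a = 0, b = 1, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(ref, "mean_form"))
  if (ref$d != 2) stop("pattern fields are 2D")
  k <- ref$k
  P <- matrix(ref$mu, ncol = 2, byrow = TRUE)
  raw <- switch(kind,
    uniform = {
      basis <- partial_warp_basis(ref)$uniform_basis
      as.vector(basis %*% c(cos(direction), sin(direction)))
    },
    gradient = {
      u <- c(cos(direction), sin(direction))
      s <- as.vector(P %*% u)
      as.vector(t(outer(a + b * s, u)))
    },
    pinocchio = {
      li <- if (is.character(landmark)) match(landmark, ref$labels)
      else as.integer(landmark)
      if (is.na(li) || li < 1 || li > k) stop("unknown landmark: ", landmark)
      g <- numeric(2 * k)
      g[2 * li - 1] <- cos(direction); g[2 * li] <- sin(direction)
      g
    },
    random = {
      rng <- local_rng(seed)
      rng$rnorm(2 * k)
    })
  v <- project_to_shape_space(raw, ref)
  nv <- sqrt(sum(v^2))
  if (nv <= 0) stop("pattern field vanishes after projection")
  v * amplitude / nv
}

#' Brownian shape evolution on a phylogeny
#'
#' Accumulates independent Gaussian increments along every branch
#' (covariance `rate * branch length` per branch) from the root
#' configuration down to the tips.
#'
#' @param tree rooted bifurcating [ape::phylo] with branch lengths.
#' @param root a [landmark_config()] (or `mean_form`) at the root.
#' @param rate scalar rate (variance per coordinate per unit time), a
#'   dk-vector of per-coordinate rates, or a dk x dk SPD rate matrix.
#' @param seed integer seed.
#' @return a [landmark_sample()] of tip configurations, specimen ids equal
#'   to tip labels.
#' @export
brownian_tree_shapes <- function(tree, root, rate, seed) {
  tree <- validate_tree(tree)
  if (inherits(root, "mean_form")) root <- mean_form_config(root)
  m <- unclass(as.matrix(root))
  k <- nrow(m); d <- ncol(m); q <- k * d
  Rt <- if (is.matrix(rate)) {
    if (!all(dim(rate) == q)) stop("rate matrix must be ", q, " x ", q)
    chol(check_sym(rate, "rate"))
  } else NULL
  sds <- if (is.null(Rt)) {
    r <- rep_len(as.numeric(rate), q)
    if (any(r < 0)) stop("rates must be nonnegative")
    sqrt(r)
  } else NULL
  rng <- local_rng(seed)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  val <- matrix(NA_real_, ntip + nnode, q)
  val[ntip + 1L, ] <- as.vector(t(m))       # root node
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; len <- tr$edge.length[e]
    z <- rng$rnorm(q)
    inc <- if (is.null(Rt)) z * sds * sqrt(len)
    else as.vector(t(Rt) %*% z) * sqrt(len)
    val[ch, ] <- val[par, ] + inc
  }
  configs <- lapply(seq_len(ntip), function(i)
    vec_to_config(val[i, ], d = d, labels = rownames(m),
                  specimen_id = tree$tip.label[i]))
  landmark_sample(configs, specimen_ids = tree$tip.label)
}

#' Correlation matrix from a general/special factor model
#'
#' Assembles `g %o% g + sum_i s_i %o% s_i` on the off-diagonal with a unit
#' diagonal imposed: the generative counterpart of [fit_wright()].
#'
#' @param g p-vector of general loadings.
#' @param specials per-block shared special loadings (one per block; NA or
#'   0 for none).
#' @param blocks partition as in [fit_wright()].
#' @return correlation matrix (p x p).
#' @export
factor_correlation_matrix <- function(g, specials, blocks) {
  p <- length(g)
  blocks <- parse_blocks(blocks, p)
  if (length(specials) != length(blocks))
    stop("need one special loading per block")
  R <- outer(g, g)
  for (b in seq_along(blocks)) {
    s <- specials[b]
    if (is.na(s) || s == 0) next
    sv <- numeric(p); sv[blocks[[b]]] <- s
    R <- R + outer(sv, sv)
  }
  diag(R) <- 1
  if (any(abs(R[upper.tri(R)]) >= 1))
    stop("factor model implies off-diagonal correlation >= 1 in magnitude")
  if (!is.null(names(g))) dimnames(R) <- list(names(g), names(g))
  R
}

#' Sample multivariate data from a general/special factor model
#'
#' Standardized observations `x_j = g_j F + sum_b s_b B_b [j in block b] +
#' e_j` with independent standard-normal factors and residual variances
#' chosen to give each variable unit variance.  Returns the latent general
#' factor alongside so recovery can be scored.
#'
#' @param g,specials,blocks as in [factor_correlation_matrix()].
#' @param n sample size.
#' @param seed integer seed.
#' @return list with `data` (n x p) and `general_factor` (n-vector).
#' @export
sample_factor_model <- function(g, specials, blocks, n, seed) {
  p <- length(g)
  blocks <- parse_blocks(blocks, p)
  uniq <- 1 - g^2
  for (b in seq_along(blocks)) {
    s <- specials[b]
    if (!is.na(s) && s > 0) uniq[blocks[[b]]] <- uniq[blocks[[b]]] - s^2
  }
  if (any(uniq < 0)) stop("loadings imply negative residual variance")
  rng <- local_rng(seed)
  f <- rng$rnorm(n)
  X <- outer(f, g)
  for (b in seq_along(blocks)) {
    s <- specials[b]
    if (is.na(s) || s == 0) next
    fb <- rng$rnorm(n)
    X[, blocks[[b]]] <- X[, blocks[[b]]] + outer(fb, rep(s, length(blocks[[b]])))
  }
  X <- X + matrix(rng$rnorm(n * p), n, p) %*% diag(sqrt(uniq), p)
  list(data = X, general_factor = f)
}

#' Random birth-death-style tree (thin seeded wrapper)
#'
#' Seeded convenience wrapper around [ape::rtree()] guaranteeing strictly
#' positive branch lengths.
#'
#' @param ntip number of tips.
#' @param seed integer seed.
#' @return an [ape::phylo].
#' @export
random_tree <- function(ntip, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  tree <- ape::rtree(ntip, br = function(n) stats::runif(n, 0.1, 1))
  validate_tree(tree)
}
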