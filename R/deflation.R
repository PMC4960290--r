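# The deflated (self-similar) Procrustes reference distribution and the
# BE-PWV integration statistic.
#
# Deflation turns an isotropic Mardia-Dryden distribution into a
# scale-free reference model: drop the uniform (affine) component and give
# every partial warp a score variance inversely proportional to its bending
# energy (2D; inverse squared in 3D).  Under this model the log-log
# regression of per-warp variance on per-warp bending energy has slope -1;
# steeper slopes are the operational signature of integration, shallower
# ones of disintegration.

#' Sample the deflated reference distribution
#'
#' Draws independent Gaussian scores for every partial warp and Cartesian
#' axis with variance `sigma^2 / lambda_j` (2D) or `sigma^2 / lambda_j^2`
#' (3D), zero variance for the uniform component, and assembles
#' configurations `mu + sum(score * warp direction)`.  Every sampled shape
#' vector is orthogonal to the J rows and to the uniform subspace by
#' construction.
#'
#' @param ref a `mean_form`.
#' @param n number of configurations.
#' @param sigma base scale of the scores (Procrustes units).
#' @param seed integer seed (required: samples are deterministic).
#' @param basis optional precomputed [partial_warp_basis()] for `ref`.
#' @return a [landmark_sample()] of n configurations.
#' @export
sample_deflated <- function(ref, n, sigma, seed, basis = NULL) {
  stopifnot(inherits(ref, "mean_form"), n >= 1, sigma > 0)
  if (is.null(basis)) basis <- partial_warp_basis(ref)
  d <- ref$d
  lam <- basis$eigenvalues
  m <- length(lam)
  if (!m) stop("no positive bending-energy eigenvalues: k too small")
  sdv <- if (d == 2) sigma / sqrt(lam) else sigma / lam
  rng <- local_rng(seed)
  # scores: n x m per axis
  V <- matrix(rep(ref$mu, n), nrow = n, byrow = TRUE)
  for (a in seq_len(d)) {
    W <- warp_directions(basis, a)          # dk x m
    sc <- matrix(rng$rnorm(n * m), n, m) * rep(sdv, each = n)
    V <- V + sc %*% t(W)
  }
  matrix_to_sample(V, d = d, labels = ref$labels, prefix = "defl")
}

# private deterministic RNG stream (leaves the global RNG untouched)
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = function(n, ...) draw(stats::rnorm, n, ...),
       runif = function(n, ...) draw(stats::runif, n, ...),
       sample = function(...) draw(base::sample, ...))
}

matrix_to_sample <- function(V, d, labels, prefix = "s") {
  configs <- lapply(seq_len(nrow(V)), function(i)
    vec_to_config(V[i, ], d = d, labels = labels,
                  specimen_id = paste0(prefix, i)))
  landmark_sample(configs)
}

#' Bending-energy / partial-warp-variance table
#'
#' Per-warp variance of the partial-warp scores across a sample (summed
#' over the Cartesian axes of each warp, one scalar per warp), with the OLS
#' fit of log variance on log bending energy.  The uniform component has
#' bending energy zero, cannot sit on the log-log plot, and is reported
#' separately as `uniform_variance`.
#'
#' @param sample a [landmark_sample()] (J-projected internally against `ref`).
#' @param ref the `mean_form` the sample varies around.
#' @param basis optional precomputed [partial_warp_basis()].
#' @return object of class `be_pwv_table`: data.frame `table` with columns
#'   `warp`, `bending_energy`, `pw_variance`, `log_be`, `log_pwv`, plus
#'   fields `slope`, `intercept`, `uniform_variance`, `n`.
#' @export
be_pwv_table <- function(sample, ref, basis = NULL) {
  stopifnot(inherits(sample, "landmark_sample"))
  n <- length(sample)
  if (n < 3) stop("per-warp variances need n >= 3 specimens")
  if (is.null(basis)) basis <- partial_warp_basis(ref)
  V <- sample_to_matrix(sample)
  sc <- partial_warp_scores(V, basis)
  d <- ref$d
  m <- length(basis$eigenvalues)
  pwv <- vapply(seq_len(m), function(j)
    sum(apply(sc[, (j - 1) * d + seq_len(d), drop = FALSE], 2, var)), 0)
  Vp <- project_to_shape_space(V, ref)
  usc <- Vp %*% basis$uniform_basis
  uvar <- sum(apply(usc, 2, var))
  tab <- data.frame(warp = seq_len(m), bending_energy = basis$eigenvalues,
                    pw_variance = pwv)
  if (any(pwv <= 0)) {
    warning("zero partial-warp variance for warp(s) ",
            paste(which(pwv <= 0), collapse = ", "),
            "; dropped from the log-log fit")
  }
  tab$log_be <- log(tab$bending_energy)
  tab$log_pwv <- ifelse(tab$pw_variance > 0, log(tab$pw_variance), NA_real_)
  use <- is.finite(tab$log_pwv)
  if (sum(use) >= 2 && diff(range(tab$log_be[use])) > 0) {
    ft <- lm(log_pwv ~ log_be, data = tab[use, ])
    slope <- unname(coef(ft)[2]); intercept <- unname(coef(ft)[1])
  } else {
    warning("BE-PWV slope undefined (degenerate abscissa or too few warps)")
    slope <- NA_real_; intercept <- NA_real_
  }
  structure(list(table = tab, slope = slope, intercept = intercept,
                 uniform_variance = uvar, n = n, basis = basis),
            class = "be_pwv_table")
}

#' @export
print.be_pwv_table <- function(x, ...) {
  cat("BE-PWV table:", nrow(x$table), "partial warps, n =", x$n,
      "specimens\n  log-log slope =", format(x$slope, digits = 4),
      " intercept =", format(x$intercept, digits = 4),
      "\n  uniform variance (excluded from fit) =",
      format(x$uniform_variance, digits = 4), "\n")
  invisible(x)
}

#' Bootstrap test of integration on a BE-PWV table
#'
#' Integration means the variance of features falls faster than the inverse
#' of their bending energy: slope below -1 on the log-log plot.  Specimens
#' are resampled with replacement, per-warp variances and the slope are
#' recomputed, and the verdict compares the bootstrap interval with -1:
#' `"integrated"` if the whole interval is below -1, `"disintegrated"` if
#' wholly above, otherwise `"self-similar/indeterminate"`.
#'
#' @param sample,ref,basis as in [be_pwv_table()].
#' @param n_boot bootstrap replicates (>= 100 recommended).
#' @param seed integer seed.
#' @param conf confidence level of the percentile interval.
#' @return list with `slope`, `ci` (length 2), `verdict`, `boot_slopes`.
#' @export
integration_test <- function(sample, ref, n_boot = 1000, seed = 1,
                             basis = NULL, conf = 0.95) {
  if (n_boot < 100) warning("n_boot < 100: bootstrap interval will be unstable")
  if (is.null(basis)) basis <- partial_warp_basis(ref)
  tab <- be_pwv_table(sample, ref, basis)
  if (nrow(tab$table) < 4) stop("integration test needs >= 4 partial warps")
  V <- sample_to_matrix(sample)
  sc <- partial_warp_scores(V, basis)
  d <- ref$d
  m <- length(basis$eigenvalues)
  lbe <- log(basis$eigenvalues)
  n <- nrow(sc)
  rng <- local_rng(seed)
  slopes <- vapply(seq_len(n_boot), function(b) {
    idx <- rng$sample(n, n, replace = TRUE)
    s <- sc[idx, , drop = FALSE]
    pwv <- vapply(seq_len(m), function(j)
      sum(apply(s[, (j - 1) * d + seq_len(d), drop = FALSE], 2, var)), 0)
    ok <- pwv > 0
    if (sum(ok) < 2) return(NA_real_)
    unname(coef(lm(log(pwv[ok]) ~ lbe[ok]))[2])
  }, 0)
  a <- (1 - conf) / 2
  ci <- unname(quantile(slopes, c(a, 1 - a), na.rm = TRUE))
  verdict <- if (ci[2] < -1) "integrated"
  else if (ci[1] > -1) "disintegrated"
  else "self-similar/indeterminate"
  list(slope = tab$slope, ci = ci, verdict = verdict, boot_slopes = slopes)
}

#' Piecewise scaling regimes on a BE-PWV table
#'
#' Fits piecewise-linear least squares of log variance on log bending
#' energy over candidate breakpoints on the sorted log-BE axis, choosing
#' the number of segments (up to `max_regimes`) by BIC.  Distinct regimes
#' correspond to scale ranges with different self-similarity behavior
#' (e.g. an isotropic midrange between canalized extremes).
#'
#' @param table a [be_pwv_table()].
#' @param max_regimes 1 to 3 segments.
#' @param min_pts minimum warps per segment.
#' @return list with `n_regimes`, `breaks` (log-BE breakpoints), `segments`
#'   (data.frame: slope, intercept, first/last warp index in BE order),
#'   `bic` per candidate model.
#' @export
fit_scaling_regimes <- function(table, max_regimes = 2, min_pts = 3) {
  stopifnot(inherits(table, "be_pwv_table"))
  tab <- table$table[is.finite(table$table$log_pwv), ]
  if (nrow(tab) < 6) stop("regime fitting needs >= 6 usable warps")
  if (max_regimes > floor(nrow(tab) / min_pts))
    stop("max_regimes too large for ", nrow(tab), " warps")
  o <- order(tab$log_be)
  x <- tab$log_be[o]; y <- tab$log_pwv[o]; n <- length(x)
  if (diff(range(x)) < 1e-12) stop("degenerate abscissa: all bending energies equal")
  seg_fit <- function(i, j) {
    xi <- x[i:j]; yi <- y[i:j]
    if (diff(range(xi)) < 1e-12) return(NULL)
    ft <- lm(yi ~ xi)
    list(rss = sum(ft$residuals^2), slope = unname(coef(ft)[2]),
         intercept = unname(coef(ft)[1]))
  }
  best <- NULL; bics <- numeric(0)
  for (r in seq_len(max_regimes)) {
    cuts <- if (r == 1) list(integer(0)) else {
      cand <- utils::combn(seq(min_pts, n - min_pts), r - 1, simplify = FALSE)
      Filter(function(cc) all(diff(c(0, cc, n)) >= min_pts), cand)
    }
    r_best <- NULL
    for (cc in cuts) {
      bounds <- c(0, cc, n)
      fits <- lapply(seq_len(r), function(s)
        seg_fit(bounds[s] + 1, bounds[s + 1]))
      if (any(vapply(fits, is.null, TRUE))) next
      rss <- sum(vapply(fits, `[[`, 0, "rss"))
      if (is.null(r_best) || rss < r_best$rss)
        r_best <- list(rss = rss, cuts = cc, fits = fits)
    }
    if (is.null(r_best)) next
    p <- 2 * r + (r - 1)   # slopes+intercepts per segment, breakpoints
    bic <- n * log(max(r_best$rss, 1e-300) / n) + p * log(n)
    bics <- c(bics, setNames(bic, paste0("regimes", r)))
    if (is.null(best) || bic < best$bic)
      best <- c(r_best, list(bic = bic, r = r))
  }
  bounds <- c(0, best$cuts, n)
  segments <- do.call(rbind, lapply(seq_len(best$r), function(s)
    data.frame(segment = s, slope = best$fits[[s]]$slope,
               intercept = best$fits[[s]]$intercept,
               from_warp = tab$warp[o][bounds[s] + 1],
               to_warp = tab$warp[o][bounds[s + 1]],
               n_warps = bounds[s + 1] - bounds[s])))
  list(n_regimes = best$r,
       breaks = if (best$r > 1) (x[best$cuts] + x[best$cuts + 1]) / 2 else numeric(0),
       segments = segments, bic = bics)
}

#' Nonuniform shape scores of a landmark subset
#'
#' Extracts the named landmarks from every specimen, superimposes each
#' sub-configuration on the standardized mean of the extracted subset
#' (center, unit centroid size, optimal rotation), projects out the subset's
#' J rows and its uniform (affine) subspace, and returns the partial-warp
#' scores of what is left.  Under the deflated reference distribution the
#' covariance of these scores is the same for every square subset of a
#' grid, whatever its size, position or orientation -- the operational form
#' of self-similarity.
#'
#' @param sample a [landmark_sample()].
#' @param labels landmark labels of the subset (>= 4 for a nonempty
#'   nonuniform component in 2D).
#' @return n x m score matrix (m = d * (k_sub - 3) in 2D), with the
#'   subset's `partial_warp_basis` attached as attribute `basis`.
#' @export
nonuniform_component_scores <- function(sample, labels) {
  stopifnot(inherits(sample, "landmark_sample"))
  idx <- match(labels, sample$labels)
  if (any(is.na(idx))) stop("unknown label(s): ",
                            paste(labels[is.na(idx)], collapse = ", "))
  if (length(idx) < 4) stop("need >= 4 landmarks for a nonuniform component")
  sub <- sample$coords[idx, , , drop = FALSE]
  d <- dim(sub)[2]; n <- dim(sub)[3]
  mn <- apply(sub, c(1, 2), mean)
  ref <- standardize_mean(landmark_config(mn, labels = labels))
  basis <- partial_warp_basis(ref)
  mu_m <- matrix(ref$mu, ncol = d, byrow = TRUE)
  V <- matrix(NA_real_, n, length(idx) * d)
  for (i in seq_len(n)) {
    m <- scale(sub[, , i], scale = FALSE)
    m <- m / sqrt(sum(m^2))
    V[i, ] <- as.vector(t(m %*% kabsch(m, mu_m)))
  }
  sc <- partial_warp_scores(V, basis)
  attr(sc, "basis") <- basis
  sc
}
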