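# Wright-style path-analytic factor analysis: one general factor applying
# to every variable plus block-specific special factors, fitted to the
# off-diagonal of a correlation matrix.  The general loadings are a rank-1
# least-squares fit to the cross-block off-diagonal cells (alternating
# least squares); each block's shared special loading is the square root of
# the mean within-block off-diagonal residual.

#' Wright's 276-leghorn-chicken correlation matrix
#'
#' The classical 6 x 6 correlation matrix of skull length, skull width,
#' humerus length, ulna length, femur length and tibia length in 276
#' leghorn chickens (Wright 1932), the canonical worked example for
#' general/special factor analysis.
#'
#' @return symmetric 6 x 6 correlation matrix with measure names.
#' @export
leghorn_correlations <- function() {
  v <- c(1.000, 0.584, 0.615, 0.601, 0.570, 0.600,
         0.584, 1.000, 0.576, 0.530, 0.526, 0.555,
         0.615, 0.576, 1.000, 0.940, 0.875, 0.878,
         0.601, 0.530, 0.940, 1.000, 0.877, 0.886,
         0.570, 0.526, 0.875, 0.877, 1.000, 0.924,
         0.600, 0.555, 0.878, 0.886, 0.924, 1.000)
  nm <- c("skull_length", "skull_width", "humerus", "ulna", "femur", "tibia")
  matrix(v, 6, 6, dimnames = list(nm, nm))
}

#' Principal components of a correlation/covariance matrix
#'
#' Reference decomposition against which the factor model is contrasted.
#' Eigenvectors are sign-canonicalized so each has nonnegative mean
#' loading; for an all-positive correlation matrix the first component is
#' then all-positive (Perron-Frobenius).
#'
#' @param R symmetric matrix.
#' @param n_components how many components to return (default all).
#' @return list with `values` (descending eigenvalues) and `loadings`
#'   (unit-norm eigenvector columns).
#' @export
pca_reference <- function(R, n_components = ncol(R)) {
  R <- check_sym(R, "R")
  ev <- eigen(R, symmetric = TRUE)
  load <- apply(ev$vectors, 2, function(v) if (mean(v) < 0) -v else v)
  idx <- seq_len(min(n_components, ncol(R)))
  dimnames(load) <- list(colnames(R), paste0("PC", seq_len(ncol(R))))
  list(values = ev$values[idx], loadings = load[, idx, drop = FALSE])
}

# blocks: list of integer vectors partitioning 1..p (or a "1,2;3,4" string)
parse_blocks <- function(blocks, p) {
  if (is.character(blocks) && length(blocks) == 1)
    blocks <- lapply(strsplit(blocks, ";")[[1]],
                     function(s) as.integer(strsplit(s, ",")[[1]]))
  blocks <- lapply(blocks, as.integer)
  all_idx <- sort(unlist(blocks))
  if (!identical(all_idx, seq_len(p)))
    stop("blocks must partition 1..", p, " with no repeats")
  blocks
}

#' Fit Wright's general/special factor model
#'
#' Models the off-diagonal of a correlation matrix as
#' `g %o% g + sum_i s_i %o% s_i`, where `g` applies to all variables and
#' each special vector `s_i` carries one shared loading on the variables of
#' one block (zero elsewhere).  `g` is estimated by alternating least
#' squares on the cross-block off-diagonal cells only (within-block cells
#' are contaminated by the specials); each block's special loading is then
#' the square root of the mean within-block off-diagonal residual, clamped
#' at zero with a warning if negative.  Deterministic: initialization uses
#' square roots of cross-block row means.
#'
#' @param R symmetric correlation (or covariance) matrix, p >= 3.
#' @param blocks partition of the variables: list of index vectors, or a
#'   string like `"1,2;3,4;5,6"`.  Singleton blocks get no special factor.
#' @param tol ALS convergence tolerance on g.
#' @param max_iter iteration cap.
#' @return object of class `wright_factor_model`: `g`, `specials` (one
#'   shared loading per block, NA for singletons), `blocks`, `fitted`
#'   (off-diagonal reconstruction), `residual` (off-diagonal residual
#'   matrix), `rms_residual` (off-diagonal RMS), `iterations`.
#' @export
fit_wright <- function(R, blocks, tol = 1e-10, max_iter = 10000) {
  R <- check_sym(R, "R")
  p <- ncol(R)
  if (p < 3) stop("need p >= 3 variables")
  blocks <- parse_blocks(blocks, p)
  bid <- integer(p)
  for (b in seq_along(blocks)) bid[blocks[[b]]] <- b
  cross <- outer(bid, bid, `!=`)           # cross-block mask
  if (any(rowSums(cross) == 0))
    stop("variable ", which(rowSums(cross) == 0)[1],
         " has no cross-block cell: g not identifiable")
  # ALS for the rank-1 fit g g' to cross-block cells
  g <- sqrt(pmax(rowSums(R * cross) / rowSums(cross), 0))
  it <- 0L; delta <- Inf
  while (delta > tol && it < max_iter) {
    it <- it + 1L
    g_old <- g
    for (i in seq_len(p)) {         # in-place updates: each uses the freshest g
      w <- cross[i, ]
      denom <- sum(g[w]^2)
      g[i] <- if (denom <= 0) 0 else sum(R[i, w] * g[w]) / denom
    }
    delta <- max(abs(g - g_old))
  }
  if (delta > tol) warning("ALS did not reach tol in ", max_iter, " iterations")
  specials <- rep(NA_real_, length(blocks))
  S <- matrix(0, p, p)
  for (b in seq_along(blocks)) {
    ib <- blocks[[b]]
    if (length(ib) < 2) next
    w <- outer(seq_len(p) %in% ib, seq_len(p) %in% ib, `&`) & !diag(p)
    resid_b <- mean((R - outer(g, g))[w])
    if (resid_b < 0) {
      warning("negative within-block residual in block ", b,
              "; special loading clamped to 0")
      resid_b <- 0
    }
    specials[b] <- sqrt(resid_b)
    sv <- numeric(p); sv[ib] <- specials[b]
    S <- S + outer(sv, sv)
  }
  fitted <- outer(g, g) + S
  diag(fitted) <- diag(R)
  residual <- R - fitted
  diag(residual) <- 0
  off <- !diag(p)
  names(g) <- colnames(R)
  structure(list(g = g, specials = specials, blocks = blocks,
                 fitted = fitted, residual = residual,
                 rms_residual = sqrt(mean(residual[off]^2)),
                 iterations = it),
            class = "wright_factor_model")
}

#' @export
print.wright_factor_model <- function(x, ...) {
  cat("Wright general/special factor model\n  g:",
      paste(format(x$g, digits = 3), collapse = " "),
      "\n  special loadings:",
      paste(format(x$specials, digits = 3), collapse = " "),
      "\n  off-diagonal RMS residual:", format(x$rms_residual, digits = 3), "\n")
  invisible(x)
}

#' General-factor scores
#'
#' The linear combination with g for coefficients is, after scaling, the
#' best available estimate of the value of the common cause of the
#' variables.  Scaling convention: `scores = data %*% g / sum(g^2)`, so a
#' data row exactly equal to `c * g` scores `c`.
#'
#' @param model a [fit_wright()] model.
#' @param data n x p matrix of standardized observations (columns matching
#'   the model's variables).
#' @param rescale if `TRUE`, rescale scores to unit variance.
#' @return n-vector of scores.
#' @export
factor_scores <- function(model, data, rescale = FALSE) {
  stopifnot(inherits(model, "wright_factor_model"))
  data <- as.matrix(data)
  if (ncol(data) != length(model$g))
    stop("data has ", ncol(data), " columns; model has ", length(model$g),
         " variables")
  sc <- as.vector(data %*% model$g) / sum(model$g^2)
  if (rescale && sd(sc) > 0) sc <- sc / sd(sc)
  sc
}
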