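# Time-normalized independent contrasts on shape coordinates, with either a
# single grand-mean registration or a per-contrast recentered J-matrix, plus
# relative warps of contrasts and the RW-winnowing neutrality scan.

# postorder Felsenstein recursion on an n_tip x q matrix of tip values.
# Returns contrasts (one per internal node), durations (sum of extended
# daughter branches), and reconstructed node values.
pic_recursion <- function(tree, X) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  q <- ncol(X)
  val <- matrix(NA_real_, ntip + nnode, q)
  val[seq_len(ntip), ] <- X
  elen <- tree$edge.length
  # extended branch lengths, indexed by node
  vlen <- numeric(ntip + nnode)
  vlen[tree$edge[, 2]] <- elen
  contrasts <- matrix(NA_real_, nnode, q)
  durations <- numeric(nnode)
  children <- matrix(NA_integer_, nnode, 2)
  # postorder edges come in daughter pairs per node
  for (e in seq(1, nrow(tree$edge), by = 2)) {
    nd <- tree$edge[e, 1]
    c1 <- tree$edge[e, 2]; c2 <- tree$edge[e + 1, 2]
    if (tree$edge[e + 1, 1] != nd) stop("tree is not fully bifurcating")
    v1 <- vlen[c1]; v2 <- vlen[c2]
    i <- nd - ntip
    contrasts[i, ] <- val[c1, ] - val[c2, ]
    durations[i] <- v1 + v2
    children[i, ] <- c(c1, c2)
    val[nd, ] <- (v2 * val[c1, ] + v1 * val[c2, ]) / (v1 + v2)
    vlen[nd] <- vlen[nd] + v1 * v2 / (v1 + v2)
  }
  list(contrasts = contrasts, durations = durations, node_values = val,
       children = children, ntip = ntip)
}

#' Independent contrasts of shape coordinates on a phylogeny
#'
#' Runs the Felsenstein recursion coordinate by coordinate on superimposed
#' shape data: each contrast is the difference of the two daughter values,
#' its duration the sum of the (extended) daughter branch lengths, the
#' ancestral value the branch-length-weighted average, and each contrast is
#' divided by the square root of its duration.  With `recenter = TRUE` the
#' two endpoint forms of every contrast are re-projected through the J
#' matrix of their own pairwise mean before differencing (the local
#' registration that keeps a divergent pair from being measured in a frame
#' centered far from both), and that J is stored per contrast.
#'
#' @param tree rooted, bifurcating [ape::phylo] with branch lengths; tip
#'   labels must match the sample's specimen ids.
#' @param sample a [landmark_sample()] of tip configurations.
#' @param recenter logical: per-contrast recentered J projection?
#' @param align `"gpa"` (superimpose first, the default) or `"none"`
#'   (treat the stored coordinates as already superimposed).
#' @return object of class `shape_contrasts`: `contrasts`
#'   ((ntip-1) x dk matrix, time-normalized), `durations`, `node_means`
#'   (reconstructed internal-node coordinate rows), `per_contrast_J` (list
#'   of `mean_form` or NULL), `grand_reference`, `tree`, `normalized = TRUE`.
#' @export
shape_contrasts <- function(tree, sample, recenter = FALSE,
                            align = c("gpa", "none")) {
  align <- match.arg(align)
  tree <- validate_tree(tree)
  stopifnot(inherits(sample, "landmark_sample"))
  ntip <- length(tree$tip.label)
  if (ntip != length(sample)) stop("tree has ", ntip, " tips but sample has ",
                                   length(sample), " specimens")
  idx <- match(tree$tip.label, sample$specimen_ids)
  if (any(is.na(idx)))
    stop("tip name(s) missing from sample: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  d <- n_dim(sample)
  if (align == "gpa") {
    fit <- gpa(sample, scale = TRUE)
    X <- fit$coords[idx, , drop = FALSE]
    ref <- fit$reference
  } else {
    X <- sample_to_matrix(sample)[idx, , drop = FALSE]
    ref <- standardize_mean(vec_to_config(colMeans(X), d = d,
                                          labels = sample$labels))
  }
  rec <- pic_recursion(tree, X)
  contrasts <- rec$contrasts
  perJ <- vector("list", nrow(contrasts))
  if (recenter) {
    for (i in seq_len(nrow(contrasts))) {
      ch <- rec$children[i, ]
      a <- vec_to_config(rec$node_values[ch[1], ], d = d, labels = sample$labels)
      b <- vec_to_config(rec$node_values[ch[2], ], d = d, labels = sample$labels)
      A <- unit_config(a)
      B <- unit_config(b)
      B <- B %*% kabsch(B, A)
      M <- unit_config((A + B) / 2)
      refi <- standardize_mean(landmark_config(M, labels = sample$labels))
      # express both endpoints in the pairwise frame before differencing
      Av <- project_to_shape_space(as.vector(t(A %*% kabsch(A, M))), refi)
      Bv <- project_to_shape_space(as.vector(t(B %*% kabsch(B, M))), refi)
      contrasts[i, ] <- Av - Bv
      perJ[[i]] <- refi
    }
  }
  contrasts <- contrasts / sqrt(rec$durations)
  rownames(contrasts) <- paste0("node", seq_len(nrow(contrasts)) + rec$ntip)
  structure(list(contrasts = contrasts, durations = rec$durations,
                 node_means = rec$node_values, per_contrast_J = perJ,
                 grand_reference = ref, tip_coords = X, tree = tree,
                 recentered = recenter, normalized = TRUE,
                 labels = sample$labels, d = d),
            class = "shape_contrasts")
}

#' @export
print.shape_contrasts <- function(x, ...) {
  cat("Shape contrasts:", nrow(x$contrasts), "contrasts,",
      ncol(x$contrasts), "coordinates;",
      if (x$recentered) "per-contrast recentered J" else "grand-mean registration",
      "\n")
  invisible(x)
}

#' Relative warps of contrasts
#'
#' Principal axes of the time-normalized contrast matrix.  Contrasts have
#' expectation zero under Brownian motion, so no further centering is
#' applied.  Tip scores are reconstructed by projecting the tip shape
#' coordinates (grand-mean frame, centered on their mean) onto the axes.
#'
#' @param contrasts a [shape_contrasts()] object.
#' @param n_axes number of axes to return.
#' @return list with `axes` (dk x n_axes orthonormal columns),
#'   `singular_values`, `contrast_scores`, `tip_scores`.
#' @export
contrast_relative_warps <- function(contrasts, n_axes = 2) {
  stopifnot(inherits(contrasts, "shape_contrasts"))
  C <- contrasts$contrasts
  if (nrow(C) < 2) stop("need >= 2 contrasts")
  s <- svd(C)
  rank <- sum(s$d > max(s$d) * 1e-10)
  if (n_axes > rank) stop("n_axes = ", n_axes, " exceeds contrast rank ", rank)
  axes <- apply(s$v[, seq_len(n_axes), drop = FALSE], 2, canon_sign)
  Xc <- scale(contrasts$tip_coords, scale = FALSE)
  list(axes = axes,
       singular_values = s$d[seq_len(n_axes)],
       contrast_scores = C %*% axes,
       tip_scores = Xc %*% axes)
}

#' Neutrality scan by winnowing relative warps of contrasts
#'
#' Under neutral (Brownian) evolution, morphological distance grows roughly
#' with the square root of patristic distance.  Strongly canalized or
#' functional directions break that proportionality; this scan removes the
#' first r = 0, 1, ..., `max_removed` relative warps of the contrasts,
#' recomputes all pairwise tip shape distances in the orthocomplement, and
#' pairs them with patristic distances, with a lowess smooth per level.
#'
#' @param contrasts a [shape_contrasts()] object.
#' @param max_removed largest number of leading contrast-RW axes to remove.
#' @param cap optional patristic-distance cap: pairs farther apart are
#'   dropped (default `Inf` = off).
#' @param lowess_f,lowess_iter lowess span and robustness iterations.
#' @return object of class `neutrality_scan`: list of per-level entries,
#'   each with `r`, `pairs` (data.frame: tip_i, tip_j, patristic,
#'   shape_distance), `smooth` (lowess x/y).
#' @export
neutrality_scan <- function(contrasts, max_removed = 5, cap = Inf,
                            lowess_f = 2/3, lowess_iter = 3) {
  stopifnot(inherits(contrasts, "shape_contrasts"))
  C <- contrasts$contrasts
  s <- svd(C)
  rank <- sum(s$d > max(s$d) * 1e-10)
  if (max_removed >= rank)
    stop("max_removed = ", max_removed, " must be below contrast rank ", rank)
  pat <- ape::cophenetic.phylo(contrasts$tree)
  tips <- contrasts$tree$tip.label
  pat <- pat[tips, tips]
  X <- contrasts$tip_coords
  n <- nrow(X)
  ut <- which(upper.tri(pat), arr.ind = TRUE)
  keep <- pat[ut] <= cap
  ut <- ut[keep, , drop = FALSE]
  out <- vector("list", max_removed + 1)
  for (r in 0:max_removed) {
    Xr <- if (r == 0) X else {
      A <- s$v[, seq_len(r), drop = FALSE]
      X - (X %*% A) %*% t(A)
    }
    dmat <- as.matrix(dist(Xr))
    df <- data.frame(tip_i = tips[ut[, 1]], tip_j = tips[ut[, 2]],
                     patristic = pat[ut], shape_distance = dmat[ut],
                     stringsAsFactors = FALSE)
    sm <- lowess(df$patristic, df$shape_distance, f = lowess_f,
                 iter = lowess_iter)
    out[[r + 1]] <- list(r = r, pairs = df, smooth = sm)
  }
  structure(out, class = "neutrality_scan")
}

#' @export
print.neutrality_scan <- function(x, ...) {
  cat("Neutrality scan:", length(x), "winnowing levels (r = 0..",
      length(x) - 1, "), ", nrow(x[[1]]$pairs), " tip pairs per level\n",
      sep = "")
  invisible(x)
}
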