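# Shared fixtures and independent oracles, all generated in code.

# the standardized 4-point "plus" configuration: (+-1/2, 0), (0, +-1/2)
plus_config <- function() {
  landmark_config(rbind(c( 0.5, 0), c(0, 0.5), c(-0.5, 0), c(0, -0.5)),
                  labels = c("e", "n", "w", "s"), specimen_id = "plus")
}

# unit square centered at the origin
square_config <- function(half = 0.5) {
  landmark_config(rbind(c(-half, -half), c(half, -half),
                        c(half, half), c(-half, half)),
                  labels = c("sw", "se", "ne", "nw"), specimen_id = "square")
}

# apply a random similarity transform (rotation, scale, translation) to a config
similarity_jitter <- function(config, seed) {
  set.seed(seed)
  th <- runif(1, 0, 2 * pi); s <- exp(runif(1, -1, 1))
  t2 <- runif(2, -5, 5)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  landmark_config(sweep(unclass(config) %*% R * s, 2, -t2),
                  labels = rownames(config),
                  specimen_id = attr(config, "specimen_id"))
}

# independent brute-force oracle: full Procrustes distance by numerical
# minimization of |A0 - s R(theta) B0 - t| over scale, rotation, translation,
# with A0 the centered, unit-centroid-size version of a
brute_force_procrustes <- function(a, b) {
  norm01 <- function(m) {
    m <- scale(unclass(as.matrix(m)), scale = FALSE)
    m / sqrt(sum(m^2))
  }
  A <- norm01(a); B <- norm01(b)
  obj <- function(p) {
    s <- exp(p[1]); th <- p[2]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum((A - sweep(s * B %*% R, 2, -p[3:4]))^2)
  }
  best <- Inf
  for (th0 in seq(0, 2 * pi, length.out = 5)[-5]) {
    o <- optim(c(0, th0, 0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  sqrt(best)
}

# independent bending-energy oracle: restrict the kernel to the complement of
# the affine functions and invert there (no bordered system)
bending_energy_nullspace_oracle <- function(P) {
  k <- nrow(P)
  U <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  K <- U(as.matrix(dist(P)))
  Q <- cbind(1, P)
  N <- qr.Q(qr(Q), complete = TRUE)[, (ncol(Q) + 1):k, drop = FALSE]
  B <- N %*% solve(t(N) %*% K %*% N) %*% t(N)
  (B + t(B)) / 2
}

expect_samples_equal <- function(s1, s2, tol = 1e-12, labels = TRUE) {
  expect_equal(length(s1), length(s2))
  if (labels) expect_identical(s1$labels, s2$labels)  # TPS stores no labels
  expect_lt(max(abs(s1$coords - s2$coords)), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
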