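test_that("standardize_mean enforces all four constraints and the printed J rows", {
  ref <- standardize_mean(plus_config())
  # the plus is already standardized; with k = 4 the printed rows are forced
  expect_equal(ref$J[1, ], rep(c(0.5, 0), 4), ignore_attr = TRUE)
  expect_equal(ref$J[4, ], c(0.5, 0, 0, 0.5, -0.5, 0, 0, -0.5),
               ignore_attr = TRUE)
  # postcondition identities on arbitrary input
  for (seed in 1:5) {
    ref <- standardize_mean(polygon_config(10, seed = seed))
    m <- matrix(ref$mu, ncol = 2, byrow = TRUE)
    expect_equal(sum(m[, 1]), 0, tolerance = 1e-12)
    expect_equal(sum(m[, 2]), 0, tolerance = 1e-12)
    expect_equal(sum(m[, 1] * m[, 2]), 0, tolerance = 1e-12)
    expect_equal(sum(m^2), 1, tolerance = 1e-12)
    expect_lt(max(abs(ref$J %*% t(ref$J) - diag(4))), 1e-10)
  }
  collinear <- landmark_config(cbind(1:4, 2 * (1:4)))
  expect_error(standardize_mean(collinear), "collinear")
})

test_that("J-projection annihilates the mean, is idempotent and translation-invariant", {
  ref <- standardize_mean(polygon_config(8, seed = 2))
  expect_lt(max(abs(project_to_shape_space(ref$mu, ref))), 1e-12)
  set.seed(4)
  C <- rnorm(16)
  p1 <- project_to_shape_space(C, ref)
  expect_equal(project_to_shape_space(p1, ref), p1, tolerance = 1e-12)
  shift <- rep(c(0.7, -1.3), 8)
  expect_equal(project_to_shape_space(C + shift, ref), p1, tolerance = 1e-12)
  expect_error(project_to_shape_space(C[-1], ref), "dimension")
})

test_that("centroid size: root convention, homogeneity, closed form", {
  ref <- standardize_mean(polygon_config(7, seed = 3))
  expect_equal(centroid_size(mean_form_config(ref)), 1, tolerance = 1e-12)
  sq <- square_config()
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(landmark_config(2 * unclass(sq))),
               2 * sqrt(2), tolerance = 1e-12)
  expect_error(centroid_size(landmark_config(matrix(1, 3, 2))), "zero")
})

test_that("GPA recovers an exact-fit sample and matches J-projection to second order", {
  base <- polygon_config(6, seed = 9)
  copies <- lapply(1:5, function(i) similarity_jitter(base, seed = 100 + i))
  fit <- gpa(landmark_sample(copies), scale = TRUE)
  # every aligned configuration equals the standardized form
  ref_row <- fit$reference$mu
  resid <- sweep(fit$coords, 2, ref_row)
  expect_lt(mean(resid^2), 1e-18)
  expect_lt(max(abs(fit$shape_coords)), 1e-9)

  # small-noise sample: GPA coords agree with one-step J-projection about the
  # true mean to first order (discrepancy O(sigma^2))
  mu <- standardize_mean(polygon_config(8, seed = 10))
  sigma <- 0.001
  s <- sample_isotropic(mu, 50, sigma, seed = 77)
  fit <- gpa(s, scale = TRUE)
  V <- t(apply(s$coords, 3, function(m) as.vector(t(m))))
  # one-step: normalize each and project through the true mean's J
  one_step <- t(apply(V, 1, function(v) {
    m <- matrix(v, ncol = 2, byrow = TRUE)
    m <- scale(m, scale = FALSE); m <- m / sqrt(sum(m^2))
    project_to_shape_space(as.vector(t(m)), mu)
  }))
  # compare shape residuals in the same frame (both are J-projected deviations)
  gpa_proj <- t(apply(fit$coords, 1, function(v)
    project_to_shape_space(v, mu)))
  expect_lt(max(abs(gpa_proj - one_step)), 50 * sigma^2)
})

test_that("Boas fit preserves centroid size and annihilates only rows 1-3", {
  base <- polygon_config(6, seed = 12)
  s <- sample_isotropic(base, 10, sigma = 0.05, seed = 13)
  fit <- gpa(s, scale = FALSE)
  insizes <- vapply(1:10, function(i) centroid_size(s[[i]]), 0)
  outsizes <- vapply(seq_len(nrow(fit$coords)), function(i)
    centroid_size(landmark_config(
      matrix(fit$coords[i, ], ncol = 2, byrow = TRUE))), 0)
  expect_equal(outsizes, insizes, tolerance = 1e-10)
  J <- fit$reference$J
  expect_lt(max(abs(fit$shape_coords %*% t(J[1:3, ]))), 1e-8)
  # scaled fit annihilates all four rows of its own reference's J
  fit2 <- gpa(s, scale = TRUE)
  expect_lt(max(abs(fit2$shape_coords %*% t(fit2$reference$J))), 1e-8)
})

test_that("Procrustes distance: identity, symmetry, oracle agreement", {
  a <- polygon_config(7, seed = 20)
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  s <- sample_isotropic(a, 2, sigma = 0.01, seed = 21)
  d_ab <- procrustes_distance(s[[1]], s[[2]])
  d_ba <- procrustes_distance(s[[2]], s[[1]])
  expect_equal(d_ab, d_ba, tolerance = 1e-12)
  # brute-force similarity-minimization oracle on small-variation pairs
  for (seed in 1:5) {
    p <- sample_isotropic(a, 2, sigma = 0.005, seed = 300 + seed)
    d_proj <- procrustes_distance(p[[1]], p[[2]], mode = "local")
    d_brute <- brute_force_procrustes(p[[1]], p[[2]])
    expect_lt(abs(d_proj - d_brute) / d_brute, 1e-3)
  }
  ref <- standardize_mean(a)
  expect_error(procrustes_distance(s[[1]], s[[2]], mode = "reference"), "ref")
  expect_gte(procrustes_distance(s[[1]], s[[2]], mode = "reference", ref = ref), 0)
})

test_that("Boas allometry recovers radial growth and injected tangential components", {
  mu <- standardize_mean(polygon_config(8, seed = 30))
  mu_m <- matrix(mu$mu, ncol = 2, byrow = TRUE)
  # exact isotropic growth: every form c * mu
  cs <- seq(0.5, 2, length.out = 20)
  configs <- lapply(seq_along(cs), function(i)
    landmark_config(cs[i] * mu_m, labels = mu$labels,
                    specimen_id = paste0("g", i)))
  fit <- gpa(landmark_sample(configs), scale = FALSE)
  al <- boas_allometry(fit)
  expect_lt(max(al$misalign_deg), 1e-4)
  # slopes proportional to distance from centroid
  r <- sqrt(rowSums(mu_m^2))
  expect_equal(al$slope_norm / r, rep(al$slope_norm[1] / r[1], 8),
               tolerance = 1e-6)

  # inject a tangential growth component at landmark 1 and recover its angle
  ang_inj <- 25 * pi / 180
  tang <- cbind(-mu_m[, 2], mu_m[, 1]) / sqrt(rowSums(mu_m^2))
  rad  <- mu_m / sqrt(rowSums(mu_m^2))
  growth_dir <- rad
  growth_dir[1, ] <- cos(ang_inj) * rad[1, ] + sin(ang_inj) * tang[1, ]
  set.seed(41)
  n <- 200; sigma <- 0.005
  sizes <- exp(runif(n, -0.3, 0.3))
  configs <- lapply(seq_len(n), function(i) {
    m <- mu_m + (sizes[i] - 1) * growth_dir * sqrt(rowSums(mu_m^2)) +
      matrix(rnorm(16, sd = sigma), 8, 2)
    landmark_config(m, labels = mu$labels, specimen_id = paste0("s", i))
  })
  fit <- gpa(landmark_sample(configs), scale = FALSE)
  al <- boas_allometry(fit, size_var = sizes)
  expect_equal(al$misalign_deg[1], 25, tolerance = 2)
  # permuted size variable: slopes collapse toward zero
  al_perm <- boas_allometry(fit, size_var = sample(sizes))
  expect_lt(median(al_perm$slope_norm), 0.1 * median(al$slope_norm))
})

test_that("distance gradient is a J-orthogonal unit direction with the right derivative", {
  mu <- standardize_mean(polygon_config(9, seed = 50))
  g <- distance_gradient(mu, c("p1", "p4"))
  expect_equal(sum(g^2), 1, tolerance = 1e-12)
  expect_lt(max(abs(mu$J %*% g)), 1e-12)
  # central difference: moving along g changes the interlandmark distance at
  # rate raw_norm (the norm of the projected raw gradient)
  ild <- function(v) {
    m <- matrix(v, ncol = 2, byrow = TRUE)
    sqrt(sum((m[1, ] - m[4, ])^2))
  }
  eps <- 1e-6
  deriv <- (ild(mu$mu + eps * g) - ild(mu$mu - eps * g)) / (2 * eps)
  expect_equal(deriv, attr(g, "raw_norm"), tolerance = 1e-5)
  expect_gt(deriv, 0)
  # swapping the two landmark labels flips the direction
  g2 <- distance_gradient(mu, c("p4", "p1"))
  expect_equal(as.vector(g2), as.vector(g), tolerance = 1e-12)
  expect_error(distance_gradient(mu, c("p1", "p1")), "distinct")
})
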