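test_that("deflated samples live in the nonuniform shape subspace with the right variances", {
  ref <- standardize_mean(grid_config(5, 5))
  basis <- partial_warp_basis(ref)
  s <- sample_deflated(ref, 100, sigma = 0.02, seed = 3, basis = basis)
  V <- t(apply(s$coords, 3, function(m) as.vector(t(m))))
  dev <- sweep(V, 2, ref$mu)
  expect_lt(max(abs(dev %*% t(ref$J))), 1e-10)
  expect_lt(max(abs(dev %*% basis$uniform_basis)), 1e-10)

  # per-warp variance ratio to sigma^2 / lambda within chi-square bounds
  n <- 10000
  s2 <- sample_deflated(ref, n, sigma = 0.02, seed = 4, basis = basis)
  tab <- be_pwv_table(s2, ref, basis)
  expected <- 2 * 0.02^2 / basis$eigenvalues      # summed over d = 2 axes
  ratio <- tab$table$pw_variance / expected
  expect_lt(max(abs(ratio - 1)), 3 * sqrt(2 / (n * 2)) * 3)

  # determinism: identical seed gives identical samples bit for bit
  s3 <- sample_deflated(ref, 100, sigma = 0.02, seed = 3, basis = basis)
  expect_identical(s$coords, s3$coords)
})

test_that("BE-PWV slope is -1 for deflated and 0 for isotropic samples", {
  ref <- standardize_mean(grid_config(5, 5))
  basis <- partial_warp_basis(ref)
  tab_d <- be_pwv_table(sample_deflated(ref, 5000, 0.02, seed = 9, basis = basis),
                        ref, basis)
  expect_equal(tab_d$slope, -1, tolerance = 0.05)
  tab_i <- be_pwv_table(sample_isotropic(ref, 5000, 0.002, seed = 10), ref, basis)
  expect_equal(tab_i$slope, 0, tolerance = 0.05)
  expect_error(be_pwv_table(sample_isotropic(ref, 2, 0.01, seed = 1), ref, basis),
               "n >= 3")
})

test_that("integration verdicts track the construction slope", {
  ref <- standardize_mean(grid_config(5, 5))
  basis <- partial_warp_basis(ref)
  # variance ~ 1/lambda^2 (slope -2): integrated
  m <- length(basis$eigenvalues)
  make_sample <- function(power, n, seed) {
    sdv <- 0.02 / basis$eigenvalues^(power / 2)
    rng_mat <- function(seed) {
      set.seed(seed); matrix(rnorm(n * m), n, m)
    }
    V <- matrix(rep(ref$mu, n), nrow = n, byrow = TRUE)
    for (a in 1:2) {
      W <- warp_directions(basis, a)
      V <- V + (rng_mat(seed + a) * rep(sdv, each = n)) %*% t(W)
    }
    lapply(seq_len(n), function(i)
      landmark_config(matrix(V[i, ], ncol = 2, byrow = TRUE),
                      labels = ref$labels, specimen_id = paste0("s", i)))
  }
  s_int <- landmark_sample(make_sample(2, 300, seed = 500))
  v_int <- integration_test(s_int, ref, n_boot = 300, seed = 1, basis = basis)
  expect_equal(v_int$verdict, "integrated")
  # isotropic scores (slope 0): disintegrated
  s_dis <- landmark_sample(make_sample(0, 300, seed = 600))
  v_dis <- integration_test(s_dis, ref, n_boot = 300, seed = 1, basis = basis)
  expect_equal(v_dis$verdict, "disintegrated")
  # deflated (slope -1): self-similar
  s_def <- sample_deflated(ref, 300, 0.02, seed = 700, basis = basis)
  v_def <- integration_test(s_def, ref, n_boot = 300, seed = 1, basis = basis)
  expect_equal(v_def$verdict, "self-similar/indeterminate")
  expect_warning(integration_test(s_def, ref, n_boot = 50, seed = 1,
                                  basis = basis), "n_boot")
})

test_that("scaling-regime fits find the right number of segments and the knee", {
  ref <- standardize_mean(grid_config(5, 5))
  basis <- partial_warp_basis(ref)
  tab <- be_pwv_table(sample_deflated(ref, 4000, 0.02, seed = 20, basis = basis),
                      ref, basis)
  one <- fit_scaling_regimes(tab, max_regimes = 2)
  expect_equal(one$n_regimes, 1L)
  expect_equal(one$segments$slope[1], -1, tolerance = 0.05)

  # synthetic two-regime table: slope 0 below the knee, -1 above, noise 0.1
  tab2 <- tab
  o <- order(tab2$table$log_be)
  nlow <- 10
  lbe <- tab2$table$log_be
  knee <- sort(lbe)[nlow]
  set.seed(21)
  tab2$table$log_pwv <- ifelse(lbe <= knee, 0, -(lbe - knee)) +
    rnorm(nrow(tab2$table), sd = 0.1)
  tab2$table$pw_variance <- exp(tab2$table$log_pwv)
  two <- fit_scaling_regimes(tab2, max_regimes = 2)
  expect_equal(two$n_regimes, 2L)
  # knee recovered within one warp position on the sorted BE axis
  rank_break <- sum(sort(lbe) < two$breaks[1])
  expect_lte(abs(rank_break - nlow), 1)
  expect_equal(two$segments$slope[1], 0, tolerance = 0.15)
  expect_equal(two$segments$slope[2], -1, tolerance = 0.15)

  # degenerate abscissa
  tab3 <- tab
  tab3$table$log_be <- rep(1, nrow(tab3$table))
  expect_error(fit_scaling_regimes(tab3, max_regimes = 2), "degenerate")
})

test_that("self-similarity: sub-square nonuniform distributions agree across scales", {
  # smaller-scale version of the flagship check (the acceptance suite runs the
  # full 7x7, n = 20000 version): three nested squares of a 5x5 grid
  ref <- standardize_mean(grid_config(5, 5))
  basis <- partial_warp_basis(ref)
  n <- 8000
  s1 <- sample_deflated(ref, n, 0.02, seed = 31, basis = basis)
  s2 <- sample_deflated(ref, n, 0.02, seed = 32, basis = basis)
  squares <- list(c("r1c1", "r1c2", "r2c2", "r2c1"),
                  c("r1c1", "r1c3", "r3c3", "r3c1"),
                  c("r1c1", "r1c5", "r5c5", "r5c1"))
  covs1 <- lapply(squares, function(sq) cov(nonuniform_component_scores(s1, sq)))
  covs2 <- lapply(squares, function(sq) cov(nonuniform_component_scores(s2, sq)))
  cross <- c(covariance_distance(covs1[[1]], covs1[[2]]),
             covariance_distance(covs1[[1]], covs1[[3]]),
             covariance_distance(covs1[[2]], covs1[[3]]))
  repl <- vapply(1:3, function(i)
    covariance_distance(covs1[[i]], covs2[[i]]), 0)
  expect_lt(max(cross), max(repl) * 2.5)
})
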