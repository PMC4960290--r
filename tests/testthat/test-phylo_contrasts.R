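test_that("two-tip trees give the closed-form contrast and ancestral mean", {
  tr <- read_tree(text = "(A:2,B:3);")
  root <- polygon_config(5, seed = 1)
  s <- sample_isotropic(root, 2, sigma = 0.05, seed = 2)
  s$specimen_ids <- c("A", "B")
  dimnames(s$coords)[[3]] <- c("A", "B")
  sc <- shape_contrasts(tr, s, recenter = FALSE, align = "none")
  XA <- as.vector(t(s$coords[, , "A"])); XB <- as.vector(t(s$coords[, , "B"]))
  expect_equal(nrow(sc$contrasts), 1L)
  expect_equal(sc$durations, 5)
  expect_equal(sc$contrasts[1, ], (XA - XB) / sqrt(5), ignore_attr = TRUE)
  # ancestral value: branch-length-weighted average
  expect_equal(sc$node_means[3, ], (3 * XA + 2 * XB) / 5, ignore_attr = TRUE)
})

test_that("contrasts and durations match the ape::pic oracle and the GLS root", {
  tr <- random_tree(8, seed = 3)
  root <- polygon_config(6, seed = 2)
  s <- brownian_tree_shapes(tr, root, rate = 1e-4, seed = 5)
  sc <- shape_contrasts(tr, s, recenter = FALSE, align = "none")
  X <- sample_to_matrix(s)
  rownames(X) <- s$specimen_ids
  X <- X[tr$tip.label, ]
  for (j in c(1, 5, 12)) {
    p <- ape::pic(setNames(X[, j], tr$tip.label), tr, var.contrasts = TRUE)
    ours <- sc$contrasts[paste0("node", rownames(p)), j]
    expect_equal(abs(ours), abs(p[, 1]), tolerance = 1e-9, ignore_attr = TRUE)
    durs <- sc$durations[match(paste0("node", rownames(p)),
                               rownames(sc$contrasts))]
    expect_equal(durs, p[, 2], tolerance = 1e-9, ignore_attr = TRUE)
  }
  # root reconstruction equals the Brownian GLS estimate
  V <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  Vi <- solve(V); one <- rep(1, 8)
  gls_root <- as.vector((t(one) %*% Vi %*% X) / as.numeric(t(one) %*% Vi %*% one))
  expect_equal(sc$node_means[9, ], gls_root, tolerance = 1e-9,
               ignore_attr = TRUE)
  # name mismatches are caught
  s_bad <- s; s_bad$specimen_ids[1] <- "zzz"
  dimnames(s_bad$coords)[[3]][1] <- "zzz"
  expect_error(shape_contrasts(tr, s_bad), "missing")
})

test_that("recentered contrasts agree with conventional ones in the small-variation limit", {
  tr <- random_tree(12, seed = 7)
  root <- standardize_mean(polygon_config(7, seed = 8))
  s <- brownian_tree_shapes(tr, root, rate = 1e-6, seed = 9)
  c0 <- shape_contrasts(tr, s, recenter = FALSE)
  c1 <- shape_contrasts(tr, s, recenter = TRUE)
  scale0 <- sqrt(mean(c0$contrasts^2))
  expect_lt(max(abs(c1$contrasts - c0$contrasts)) / scale0, 0.05)
  expect_length(c1$per_contrast_J, 11)
  expect_s3_class(c1$per_contrast_J[[1]], "mean_form")
  # identical tips: both kinds of contrasts vanish identically
  same <- landmark_sample(rep(list(mean_form_config(root)), 12),
                          specimen_ids = tr$tip.label)
  cz <- shape_contrasts(tr, same, recenter = TRUE, align = "none")
  expect_lt(max(abs(cz$contrasts)), 1e-12)
})

test_that("relative warps of contrasts recover dominant directions of evolution", {
  tr <- random_tree(10, seed = 11)
  root <- standardize_mean(polygon_config(6, seed = 12))
  # contrasts all proportional to one vector: single nonzero axis
  v <- pattern_field(root, "random", amplitude = 1, seed = 13)
  sc <- shape_contrasts(tr, brownian_tree_shapes(tr, root, 1e-8, seed = 1),
                        align = "none")
  set.seed(14)
  sc$contrasts <- outer(rnorm(nrow(sc$contrasts)), v)
  rw <- contrast_relative_warps(sc, n_axes = 1)
  expect_equal(abs(sum(rw$axes[, 1] * v)), 1, tolerance = 1e-9)
  expect_error(contrast_relative_warps(sc, n_axes = 2), "rank")

  # anisotropic Brownian rates: RW1 aligns with the high-rate direction
  tr64 <- random_tree(64, seed = 15)
  u <- pattern_field(root, "random", amplitude = 1, seed = 16)
  q <- length(root$mu)
  rate <- 1e-6 * (diag(q) + 9 * outer(u, u))    # 10:1 anisotropy along u
  s64 <- brownian_tree_shapes(tr64, root, rate, seed = 17)
  sc64 <- shape_contrasts(tr64, s64, recenter = FALSE)
  rw64 <- contrast_relative_warps(sc64, n_axes = 2)
  expect_gt(abs(sum(rw64$axes[, 1] * u)), 0.95)
  # axes orthonormal, contrast scores uncorrelated
  expect_lt(max(abs(crossprod(rw64$axes) - diag(2))), 1e-10)
  cs <- crossprod(rw64$contrast_scores)
  expect_lt(abs(cs[1, 2]) / sqrt(cs[1, 1] * cs[2, 2]), 1e-8)
})

test_that("neutrality scan: r = 0 gives plain distances, Brownian scaling is linear", {
  tr <- random_tree(64, seed = 21)
  root <- standardize_mean(polygon_config(6, seed = 22))
  s <- brownian_tree_shapes(tr, root, rate = 1e-6, seed = 23)
  sc <- shape_contrasts(tr, s, recenter = FALSE)
  scan <- neutrality_scan(sc, max_removed = 2)
  expect_length(scan, 3)
  d0 <- as.matrix(dist(sc$tip_coords))
  i <- match(scan[[1]]$pairs$tip_i, tr$tip.label)
  j <- match(scan[[1]]$pairs$tip_j, tr$tip.label)
  expect_equal(scan[[1]]$pairs$shape_distance,
               d0[cbind(i, j)], tolerance = 1e-12)
  # squared distance grows linearly with patristic distance through the origin
  ft <- lm(I(shape_distance^2) ~ 0 + patristic, data = scan[[1]]$pairs)
  r2 <- 1 - sum(ft$residuals^2) /
    sum((scan[[1]]$pairs$shape_distance^2)^2)
  expect_gt(r2, 0.5)
  expect_error(neutrality_scan(sc, max_removed = 1000), "rank")
  # patristic cap drops distant pairs
  cap <- median(scan[[1]]$pairs$patristic)
  scan_cap <- neutrality_scan(sc, max_removed = 0, cap = cap)
  expect_true(all(scan_cap[[1]]$pairs$patristic <= cap))
  expect_lt(nrow(scan_cap[[1]]$pairs), nrow(scan[[1]]$pairs))
})
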