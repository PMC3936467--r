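test_that("one-sample t map matches hand arithmetic and masks degeneracies", {
  grid <- test_grid(); V <- prod(grid$dims)
  Z <- matrix(rnorm_seeded(3 * V, 1), 3, V)
  Z[, 1] <- c(1, 2, 3)        # t = 2 / (1/sqrt(3)) = 3.4641
  Z[, 2] <- 5                 # zero variance -> masked out
  sm <- one_sample_map(Z, rep(TRUE, V), grid)
  expect_equal(sm$values[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_false(sm$mask[2])
  expect_equal(sm$df, 2)
  expect_error(one_sample_map(Z[1, , drop = FALSE], rep(TRUE, V), grid),
               "sample-size")
})

test_that("one-sample null maps exceed the two-tailed threshold at rate p", {
  grid <- test_grid(); V <- prod(grid$dims)
  Z <- matrix(rnorm_seeded(22 * V, 17), 22, V)
  sm <- one_sample_map(Z, rep(TRUE, V), grid)
  thr <- stat_threshold_from_p(0.05, 21, "t")
  frac <- mean(abs(sm$values) >= thr)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / V))
})

test_that("two-group F map equals squared pooled t, designs validated", {
  grid <- test_grid(); V <- prod(grid$dims)
  labs <- factor(rep(c("relapse", "nonrelapse"), c(10, 9)),
                 levels = c("relapse", "nonrelapse"))
  Z <- matrix(rnorm_seeded(19 * V, 23), 19, V)
  sm <- group_contrast_map(Z, labs, mask = rep(TRUE, V), grid = grid)
  # pooled-variance two-sample t, computed independently
  g1 <- Z[labs == "relapse", ]; g2 <- Z[labs == "nonrelapse", ]
  n1 <- nrow(g1); n2 <- nrow(g2)
  sp2 <- ((n1 - 1) * apply(g1, 2, var) + (n2 - 1) * apply(g2, 2, var)) /
    (n1 + n2 - 2)
  tt <- (colMeans(g1) - colMeans(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_lt(max(abs(sm$values - tt^2)), 1e-8)
  expect_equal(sm$df, c(1, 17))
  expect_equal(sm$sign, sign(colMeans(g1) - colMeans(g2)))
  # covariate identical to the group indicator is confounded
  expect_error(group_contrast_map(Z, labs,
    covariates = as.numeric(labs == "relapse"),
    mask = rep(TRUE, V), grid = grid), "design error")
  expect_error(group_contrast_map(Z, labs, covariates = rep(1, 19),
    mask = rep(TRUE, V), grid = grid), "constant covariate")
})

test_that("a covariate orthogonal to group and data rescales F only by df", {
  grid <- test_grid(); V <- prod(grid$dims)
  labs <- factor(rep(c("relapse", "nonrelapse"), each = 8))
  Z <- matrix(rnorm_seeded(16 * V, 31), 16, V)
  g <- as.numeric(labs == "relapse")
  cov0 <- rnorm_seeded(16, 32)
  Q <- qr.Q(qr(cbind(1, g, Z[, 1:13])))
  cov_orth <- cov0 - drop(Q %*% crossprod(Q, cov0))  # orthogonal to all
  m <- rep(FALSE, V); m[1:13] <- TRUE
  f0 <- group_contrast_map(Z, labs, mask = m, grid = grid)
  f1 <- group_contrast_map(Z, labs, covariates = cov_orth, mask = m,
                           grid = grid)
  ratio <- f1$values[1:13] / f0$values[1:13]
  expect_equal(ratio, rep(13 / 14, 13), tolerance = 1e-8)
})

test_that("voxel thresholds reproduce standard quantiles", {
  expect_equal(stat_threshold_from_p(0.05, Inf, "t"), 1.959964,
               tolerance = 1e-6)
  expect_equal(stat_threshold_from_p(0.001, 21, "t"), 3.82, tolerance = 0.01)
  expect_gt(stat_threshold_from_p(0.001, 21, "t"),
            stat_threshold_from_p(0.01, 21, "t"))
  expect_equal(stat_threshold_from_p(0.005, c(1, 43), "F"),
               qf(0.995, 1, 43), tolerance = 1e-12)
})

test_that("covariate association: identities, brute force, partialling", {
  v <- c(0.2, 0.5, 0.9, 1.4, 0.1, 0.7)
  expect_equal(covariate_association(v, v)$estimate, 1, tolerance = 1e-12)
  # 4-point set against the covariance formula
  x <- c(0, 1, 2, 3); y <- c(0, 1, 0, 1)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- covariate_association(y, x)
  expect_equal(got$estimate, r_oracle, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_error(covariate_association(v, v, control = v), "collinear")
  expect_error(covariate_association(v, rep(2, 6)), "zero-variance")
  # binary covariate -> pooled two-sample t
  grp <- c(0, 0, 0, 1, 1, 1)
  ours <- covariate_association(v, grp)
  ref <- t.test(v[grp == 0], v[grp == 1], var.equal = TRUE)
  expect_equal(ours$estimate, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  # partial correlation loses one df
  z <- c(1, 3, 2, 5, 4, 6)
  expect_equal(covariate_association(v, z, control = grp)$df, 3)
})

test_that("bonferroni adjustment follows alpha/m", {
  expect_equal(round(bonferroni_adjust(0.05, 3), 3), 0.017)
  expect_identical(bonferroni_adjust(0.05, 1), 0.05)
  expect_identical(bonferroni_adjust(0.05, 5), 0.01)
  expect_error(bonferroni_adjust(0.05, 0), "m must be")
})
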