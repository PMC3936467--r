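test_that("neighbourhood rule semantics: corner contact", {
  m <- array(FALSE, c(5, 5, 5))
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE   # touch only at a corner
  expect_length(label_clusters(m, 26)$sizes, 1)
  expect_length(label_clusters(m, 6)$sizes, 2)
  # edge contact joins under 18 but not 6
  m2 <- array(FALSE, c(5, 5, 5))
  m2[2, 2, 2] <- TRUE; m2[3, 3, 2] <- TRUE
  expect_length(label_clusters(m2, 18)$sizes, 1)
  expect_length(label_clusters(m2, 6)$sizes, 2)
  # empty mask
  e <- label_clusters(array(FALSE, c(4, 4, 4)))
  expect_identical(e$sizes, integer(0))
  expect_true(all(e$labels == 0L))
})

test_that("component partitions match the brute-force flood-fill oracle", {
  for (trial in 1:12) {
    for (conn in c(26, 6)) {
      m <- array(runif_seeded(12^3, 100 + trial) < 0.1, c(12, 12, 12))
      got <- label_clusters(m, conn)
      want <- flood_fill_oracle(m, conn)
      expect_identical(partition_sets(got$labels),
                       partition_sets(want$labels))
      expect_identical(sort(got$sizes, decreasing = TRUE), got$sizes)
    }
  }
})

test_that("extract_clusters reports peaks, directions and ordering", {
  grid <- test_grid(); V <- prod(grid$dims)
  vals <- rep(0, V)
  m <- array(FALSE, grid$dims)
  # planted positive cluster of 4 voxels with a peak, negative singleton
  pos <- c(ijk_to_lin_test(grid, c(3, 3, 3)), ijk_to_lin_test(grid, c(4, 3, 3)),
           ijk_to_lin_test(grid, c(3, 4, 3)), ijk_to_lin_test(grid, c(3, 3, 4)))
  neg <- ijk_to_lin_test(grid, c(9, 9, 8))
  vals[pos] <- c(4, 5, 4.5, 4.2); vals[neg] <- -6
  smap <- seedrsfc:::stat_map(vals, "t", 40, rep(TRUE, V), grid,
                              sign = sign(vals), contrast = "toy")
  cl <- extract_clusters(smap, voxel_p = 0.001, connectivity = 26)
  expect_length(cl, 2)
  expect_identical(cl[[1]]$size, 4L)
  expect_equal(cl[[1]]$peak_stat, 5)
  expect_identical(cl[[1]]$direction, 1)
  expect_equal(cl[[1]]$peak_ijk, c(4, 3, 3))
  expect_equal(cl[[1]]$peak_mm,
               drop(voxel_to_mm(grid, matrix(c(4, 3, 3), 1))))
  expect_identical(cl[[2]]$direction, -1)
})

test_that("cluster report filters on minimum extent", {
  grid <- test_grid(); V <- prod(grid$dims)
  vals <- rep(0, V)
  vals[1:100] <- 8    # a 100-voxel block (linear indices are contiguous in x)
  smap <- seedrsfc:::stat_map(vals, "t", 40, rep(TRUE, V), grid,
                              sign = sign(vals), contrast = "planted")
  expect_identical(nrow(cluster_report(smap, k_min = 55, voxel_p = 0.005)), 1L)
  vals2 <- rep(0, V); vals2[1:40] <- 8
  smap2 <- seedrsfc:::stat_map(vals2, "t", 40, rep(TRUE, V), grid,
                               sign = sign(vals2), contrast = "planted")
  expect_identical(nrow(cluster_report(smap2, k_min = 55, voxel_p = 0.005)), 0L)
  expect_identical(nrow(cluster_report(smap2, k_min = 40, voxel_p = 0.005)), 1L)
})

test_that("monte-carlo cluster threshold: limits, monotonicity, resolution", {
  grid <- test_grid()
  mask <- array(TRUE, grid$dims)
  # voxel p so small that no voxel survives: k_min collapses to 1
  mc0 <- mc_cluster_size_threshold(mask, grid, fwhm = 0, voxel_p = 1e-10,
                                   n_iter = 200, seed = 4)
  expect_identical(mc0$k_min, 1L)
  mc5 <- mc_cluster_size_threshold(mask, grid, fwhm = 6, voxel_p = 0.005,
                                   cluster_alpha = 0.05, n_iter = 400, seed = 9)
  mc1 <- mc_cluster_size_threshold(mask, grid, fwhm = 6, voxel_p = 0.005,
                                   cluster_alpha = 0.01, n_iter = 400, seed = 9)
  expect_identical(mc5$max_sizes, mc1$max_sizes)  # same draws (cache by seed)
  expect_gte(mc1$k_min, mc5$k_min)
  expect_error(mc_cluster_size_threshold(mask, grid, 6, 0.005,
                                         cluster_alpha = 0.001, n_iter = 200),
               "resolution error")
  # caching returns the identical object
  again <- mc_cluster_size_threshold(mask, grid, fwhm = 6, voxel_p = 0.005,
                                     cluster_alpha = 0.05, n_iter = 400,
                                     seed = 9)
  expect_identical(again$k_min, mc5$k_min)
})

test_that("smoothness estimation recovers a known kernel and clamps white noise", {
  grid <- volume_grid(c(24, 24, 18))
  V <- prod(grid$dims)
  mask <- array(TRUE, grid$dims)
  # white noise -> near-zero smoothness
  w <- matrix(rnorm_seeded(V * 4, 41), 4, V, byrow = TRUE)
  expect_lt(mean(estimate_smoothness(w, mask, grid)), 1.5)
  # 6 mm smoothed noise -> estimate within 10%
  sm <- t(vapply(1:6, function(i) as.vector(
    smooth_gaussian(matrix(rnorm_seeded(V, 50 + i), ncol = 1), 6, grid)),
    numeric(V)))
  est <- estimate_smoothness(sm, mask, grid)
  expect_true(all(abs(est - 6) / 6 < 0.1))
  # scale invariance
  expect_equal(estimate_smoothness(sm * 10, mask, grid), est,
               tolerance = 1e-10)
  expect_error(estimate_smoothness(sm, array(FALSE, grid$dims), grid),
               "estimation error")
})
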