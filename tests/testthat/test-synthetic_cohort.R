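test_that("band-limited signals have exact spectral containment and unit variance", {
  s <- make_band_limited_signal(212, 1.7, 0.01, 0.1, seed = 1)
  expect_identical(s, make_band_limited_signal(212, 1.7, 0.01, 0.1, seed = 1))
  expect_lt(abs(mean(s)), 1e-12)
  expect_lt(abs(var(s) - 1), 1e-9)
  pw <- Mod(fft(s))^2
  f <- pmin(0:211, 212 - 0:211) / (212 * 1.7)
  out_band <- f < 0.01 - 1e-9 | f > 0.1 + 1e-9
  expect_lt(max(pw[out_band]), 1e-18 * max(pw))
  expect_error(make_band_limited_signal(212, 1.7, 0.01, 0.5), "invalid-band")
})

test_that("cohort spec and truth manifest enforce their invariants", {
  expect_error(cohort_spec(n_relapse = 1), "counts")
  sp <- cohort_spec()
  expect_equal(sp$n_volumes * sp$tr, 360.4, tolerance = 0.01)
  tr <- default_truth(sp$grid)
  # region masks disjoint
  all_regions <- c(tr$seeds, tr$targets, list(tr$wm, tr$csf))
  overlap <- Reduce(`+`, lapply(all_regions, function(m) array(as.integer(m), sp$grid$dims)))
  expect_lte(max(overlap), 1L)
  expect_true(all(vapply(all_regions, function(m) all(tr$brain[m]), TRUE)))
})

test_that("synthesized subjects honour shape, determinism and group checks", {
  grid <- volume_grid(c(14, 14, 12), c(3.25, 3.25, 3))
  sp <- cohort_spec(grid_dims = grid$dims, n_volumes = 64, seed = 3)
  tr <- default_truth(sp$grid)
  s1 <- synthesize_subject(sp, tr, "relapse", seed = 7)
  expect_equal(dim(s1$bold), c(prod(grid$dims), 64))
  expect_identical(dim(s1$motion), c(64L, 6L))
  expect_identical(s1$bold, synthesize_subject(sp, tr, "relapse", seed = 7)$bold)
  expect_false(identical(s1$bold,
                         synthesize_subject(sp, tr, "relapse", seed = 8)$bold))
  expect_error(synthesize_subject(sp, tr, "remitted", seed = 1),
               "unknown group")
  # motion regressors are bounded random walks
  expect_true(all(abs(s1$motion) <= 1 + 1e-12))
})

test_that("zero coupling yields null seed-target correlation", {
  grid <- volume_grid(c(14, 14, 12), c(3.25, 3.25, 3))
  sp <- cohort_spec(grid_dims = grid$dims, n_volumes = 212, seed = 5)
  tr <- default_truth(grid,
    circuits = list(list(name = "c0", seed = "L_CMA", target = "vmpfc",
                         coupling = c(relapse = 0, nonrelapse = 0, control = 0))),
    nuisance_weights = rep(0, 8), drift_coeffs = c(0, 0, 0))
  rs <- vapply(1:8, function(i) {
    sc <- synthesize_subject(sp, tr, "relapse", seed = child_seed(5, i))
    sts <- extract_seed_timecourse(sc$bold, tr$seeds$L_CMA)
    cor(sts, colMeans(sc$bold[which(as.vector(tr$targets$vmpfc)), ]))
  }, numeric(1))
  expect_lt(mean(abs(rs)), 3 / sqrt(212))
})

test_that("planted coupling matches the closed form beta/sqrt(beta^2+sigma^2)", {
  grid <- volume_grid(c(24, 24, 18))
  sp <- cohort_spec(seed = 11)
  tr <- default_truth(grid,
    circuits = list(list(name = "c1", seed = "L_CMA", target = "vmpfc",
                         coupling = c(relapse = 1, nonrelapse = 1, control = 1))),
    nuisance_weights = rep(0, 8), drift_coeffs = c(0, 0, 0))
  tgt <- which(as.vector(tr$targets$vmpfc))
  rbar <- vapply(1:50, function(i) {
    sc <- synthesize_subject(sp, tr, "nonrelapse", seed = child_seed(11, i))
    sts <- extract_seed_timecourse(sc$bold, tr$seeds$L_CMA)
    nd <- nuisance_design(sc$motion,
                          colMeans(sc$bold[which(as.vector(tr$wm)), ]),
                          colMeans(sc$bold[which(as.vector(tr$csf)), ]))
    mean(connectivity_map(sts, sc$bold, nd, tr$targets$vmpfc)$r, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(rbar) - 1 / sqrt(2)), 0.05)
})

test_that("on-disk cohorts are complete and reproducible", {
  grid_dims <- c(12, 12, 10)
  sp <- cohort_spec(2, 2, 2, grid_dims = grid_dims, n_volumes = 24, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- synthesize_cohort(sp, out_dir = d1)
  out2 <- synthesize_cohort(sp, out_dir = d2)
  expect_length(list.files(d1, pattern = "_bold\\.nii\\.gz$"), 6)
  expect_identical(nrow(out1$cohort), 6L)
  expect_identical(readLines(file.path(d1, "truth_manifest.json")),
                   readLines(file.path(d2, "truth_manifest.json")))
  expect_identical(readLines(file.path(d1, "cohort.tsv")),
                   readLines(file.path(d2, "cohort.tsv")))
  grid <- volume_grid(grid_dims)
  v1 <- read_volume(file.path(d1, "sub-001_bold.nii.gz"), grid)
  v2 <- read_volume(file.path(d2, "sub-001_bold.nii.gz"), grid)
  expect_identical(as.vector(v1$values), as.vector(v2$values))
  expect_identical(dim(v1$values)[4], 24L)
  # probabilistic maps + segmentation reproduce the true seed regions
  truth <- out1$truth
  seg <- read_mask(file.path(d1, "masks", "segmentation.nii.gz"), grid)
  pm <- read_volume(file.path(d1, "masks", "prob_L_BLA.nii.gz"), grid)$values
  expect_identical(build_seed_mask(pm, 0.5, seg), truth$seeds$L_BLA)
  cm <- read_volume(file.path(d1, "masks", "prob_L_CMA_centromedial.nii.gz"), grid)$values
  sf <- read_volume(file.path(d1, "masks", "prob_L_CMA_superficial.nii.gz"), grid)$values
  expect_identical(combine_cma(build_seed_mask(cm, 0.5, seg),
                               build_seed_mask(sf, 0.5, seg)),
                   truth$seeds$L_CMA)
})
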