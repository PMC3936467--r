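make_zmap_cohort <- function(n_rel = 10, n_non = 10, effect = 0.5,
                             noise = 0.15, seed = 77, grid = test_grid()) {
  V <- prod(grid$dims)
  n <- n_rel + n_non
  labs <- factor(rep(c("relapse", "nonrelapse"), c(n_rel, n_non)),
                 levels = c("relapse", "nonrelapse"))
  target <- array(FALSE, grid$dims); target[4:7, 4:7, 4:6] <- TRUE
  Z <- matrix(rnorm_seeded(n * V, seed), n, V) * noise
  Z[labs == "nonrelapse", which(target)] <-
    Z[labs == "nonrelapse", which(target)] + effect
  list(Z = Z, labs = labs, grid = grid, mask = rep(TRUE, V), target = target,
       covs = data.frame(years_education = round(rnorm_seeded(n, seed + 1) * 2 + 12),
                         years_smoking = round(rnorm_seeded(n, seed + 2) * 5 + 20)))
}

loocv_settings <- function(fx, k_min = 10) {
  list(mask = fx$mask, grid = fx$grid, voxel_p = 0.005, k_min = k_min,
       connectivity = 26)
}

test_that("classification metrics reproduce published worked examples", {
  m <- classification_metrics(confusion_table(19, 5, 7, 14))
  expect_equal(round(m$sensitivity, 1), 79.2)
  expect_equal(round(m$specificity, 1), 66.7)
  expect_equal(round(m$accuracy, 1), 73.3)
  expect_equal(round(classification_metrics(
    confusion_table(17, 7, 11, 10))$accuracy, 1), 60.0)
  all_right <- classification_metrics(confusion_table(24, 0, 0, 21))
  expect_equal(unlist(all_right), c(sensitivity = 100, specificity = 100,
                                    accuracy = 100))
  expect_error(classification_metrics(confusion_table(0, 0, 7, 14)),
               "undefined metric")
  # identity: accuracy * n = 100 * (tp + tn)
  cf <- confusion_table(13, 11, 6, 15)
  expect_equal(classification_metrics(cf)$accuracy * 45,
               100 * (cf$tp + cf$tn))
})

test_that("chi-square against chance matches the hand formula", {
  cf <- confusion_table(19, 5, 7, 14)
  got <- chisq_vs_chance(cf)
  n <- 45
  hand <- n * (19 * 14 - 5 * 7)^2 / (24 * 21 * 26 * 19)
  expect_equal(got$chisq, hand, tolerance = 1e-12)
  expect_identical(got$df, 1)
  expect_equal(got$p, pchisq(hand, 1, lower.tail = FALSE), tolerance = 1e-12)
  # predicted split independent of actual -> 0
  expect_equal(chisq_vs_chance(confusion_table(12, 12, 6, 6))$chisq, 0,
               tolerance = 1e-12)
  expect_error(chisq_vs_chance(confusion_table(0, 0, 5, 5)),
               "degenerate-table")
})

test_that("confusion tables reconstruct from printed rates", {
  cf <- confusion_from_rates(79.2, 66.7, 24, 21)
  expect_identical(unlist(cf), c(tp = 19, fn = 5, fp = 7, tn = 14))
  cf1 <- confusion_from_rates(70.8, 47.6, 24, 21)
  expect_identical(unlist(cf1), c(tp = 17, fn = 7, fp = 11, tn = 10))
})

test_that("logistic fits: symmetry, IRLS oracle, separation", {
  x <- c(0.3, 1.2, -0.5, -0.3, -1.2, 0.5)
  y <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_logistic(matrix(x, ncol = 1), y)
  expect_lt(abs(fit$coef[1]), 1e-6)
  expect_false(fit$separated)
  # oracle equivalence on an 8-point dataset (overlapping classes)
  X8 <- cbind(c(0.2, 1.4, 0.9, -0.3, -1.1, 0.4, 2.0, -0.6),
              c(1, 0, 1, 1, 0, 1, 1, 0))
  y8 <- c(1, 1, 0, 1, 0, 0, 1, 0)
  fit8 <- fit_logistic(X8, y8)
  expect_equal(unname(fit8$coef), irls_logistic_oracle(X8, y8),
               tolerance = 1e-6)
  # perfect separation is flagged
  sep <- fit_logistic(matrix(c(1, 2, 3, 10, 11, 12), ncol = 1),
                      c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separated)
  expect_error(fit_logistic(matrix(rep(1, 6), ncol = 1), y), "constant")
  expect_error(fit_logistic(matrix(1:2, ncol = 1), c(0, 1)), "sample-size")
})

test_that("cluster matching picks the largest overlap with sensible fallbacks", {
  ref <- list(voxels = 1:10, peak_mm = c(0, 0, 0))
  cl_a <- list(voxels = 8:20, size = 13L, peak_stat = 5,
               peak_mm = c(3, 0, 0))   # overlap 3
  cl_b <- list(voxels = 5:9, size = 5L, peak_stat = 4,
               peak_mm = c(6, 0, 0))   # overlap 5
  got <- seedrsfc:::match_cluster(list(cl_a, cl_b), ref, k_min = 2)
  expect_identical(got$voxels, 5:9)
  expect_identical(got$overlap, 5)
  expect_identical(got$fallback, "none")
  # identity: fold cluster equal to the reference overlaps by its own size
  cl_id <- list(voxels = 1:10, size = 10L, peak_stat = 6, peak_mm = c(0, 0, 0))
  got_id <- seedrsfc:::match_cluster(list(cl_id, cl_b), ref, k_min = 2)
  expect_identical(got_id$overlap, 10)
  # below k_min, overlapping clusters are still used (flagged fallback)
  got_sub <- seedrsfc:::match_cluster(list(cl_b), ref, k_min = 50)
  expect_identical(got_sub$fallback, "subthreshold-extent")
  # zero overlap anywhere -> nearest peak
  cl_far <- list(voxels = 100:105, size = 6L, peak_stat = 4,
                 peak_mm = c(30, 0, 0))
  cl_near <- list(voxels = 200:202, size = 3L, peak_stat = 3,
                  peak_mm = c(3, 3, 0))
  got_np <- seedrsfc:::match_cluster(list(cl_far, cl_near), ref, k_min = 2)
  expect_identical(got_np$fallback, "nearest-peak")
  expect_identical(got_np$voxels, 200:202)
  expect_null(seedrsfc:::match_cluster(list(), ref, k_min = 2))
})

test_that("the held-out subject cannot influence its fold", {
  fx <- make_zmap_cohort()
  st <- loocv_settings(fx)
  full <- group_contrast_map(fx$Z, fx$labs, mask = fx$mask, grid = fx$grid)
  ref <- find_reference_cluster(full, st$voxel_p, st$k_min, st$connectivity)
  spec <- predictor_spec(list(list(name = "c1", seed = "s1", reference = ref)))
  zm <- list(s1 = fx$Z)
  f1 <- run_fold(zm, fx$labs, fx$covs, spec, left_out = 3, st)
  # scramble the held-out subject's map: nothing upstream of prediction moves
  zm2 <- zm
  zm2$s1[3, ] <- zm2$s1[3, order(runif_seeded(ncol(zm2$s1), 1))]
  f2 <- run_fold(zm2, fx$labs, fx$covs, spec, left_out = 3, st)
  expect_identical(f1$clusters$c1$voxels, f2$clusters$c1$voxels)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  # the held-out subject's own predictor does move
  expect_false(isTRUE(all.equal(f1$predictors[3, 1], f2$predictors[3, 1])))
})

test_that("LOOCV aggregates folds and separates strong group differences", {
  fx <- make_zmap_cohort()
  st <- loocv_settings(fx)
  full <- group_contrast_map(fx$Z, fx$labs, mask = fx$mask, grid = fx$grid)
  ref <- find_reference_cluster(full, st$voxel_p, st$k_min, st$connectivity)
  spec <- predictor_spec(list(list(name = "c1", seed = "s1", reference = ref)))
  rep1 <- run_loocv(list(s1 = fx$Z), fx$labs, fx$covs, spec, st,
                    model_name = "rsfc")
  expect_length(rep1$folds, 20)
  cf <- rep1$confusion
  expect_identical(cf$tp + cf$fn, sum(fx$labs == "relapse"))
  expect_identical(cf$fp + cf$tn, sum(fx$labs == "nonrelapse"))
  expect_gt(rep1$metrics$accuracy, 80)
  # same machinery with an added covariate
  spec2 <- predictor_spec(list(list(name = "c1", seed = "s1", reference = ref)),
                          covariates = "years_education")
  rep2 <- run_loocv(list(s1 = fx$Z), fx$labs, fx$covs, spec2, st,
                    model_name = "rsfc+edu")
  expect_length(rep2$folds, 20)
  expect_identical(rep2$confusion$tp + rep2$confusion$fn,
                   sum(fx$labs == "relapse"))
  # covariate-only model needs no contrast at all
  spec3 <- predictor_spec(covariates = c("years_education", "years_smoking"))
  rep3 <- run_loocv(list(), fx$labs, fx$covs, spec3, st, model_name = "covs")
  expect_length(rep3$folds, 20)
})
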