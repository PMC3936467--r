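#' Confusion table (relapse = positive class)
#'
#' @param tp,fn,fp,tn non-negative counts; rows of the underlying 2x2 table
#'   are actual class, columns predicted class.
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("validation error: negative counts")
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(actual = c("relapse", "nonrelapse"),
                              predicted = c("relapse", "nonrelapse")))
  print(m)
  invisible(x)
}

#' Reconstruct a confusion table from reported sensitivity/specificity
#'
#' Given published sensitivity and specificity percentages and the group
#' sizes, recovers the integer 2x2 predicted-vs-actual counts.
#'
#' @param sensitivity_pct,specificity_pct percentages.
#' @param n_pos,n_neg actual positive (relapse) and negative (non-relapse)
#'   group sizes.
#' @return a [confusion_table()].
#' @export
confusion_from_rates <- function(sensitivity_pct, specificity_pct,
                                 n_pos, n_neg) {
  tp <- round(sensitivity_pct / 100 * n_pos)
  tn <- round(specificity_pct / 100 * n_neg)
  confusion_table(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
}

#' Classification metrics from a confusion table
#'
#' @param conf a [confusion_table()].
#' @return list with `sensitivity`, `specificity`, `accuracy` in percent
#'   (unrounded; reports display 1 decimal).
#' @export
classification_metrics <- function(conf) {
  stopifnot(inherits(conf, "confusion_table"))
  n_pos <- conf$tp + conf$fn; n_neg <- conf$fp + conf$tn
  if (n_pos == 0 || n_neg == 0)
    stop("undefined metric error: empty positive or negative class")
  list(sensitivity = 100 * conf$tp / n_pos,
       specificity = 100 * conf$tn / n_neg,
       accuracy = 100 * (conf$tp + conf$tn) / (n_pos + n_neg))
}

#' Chi-square test of classification against chance
#'
#' Pearson chi-square (no continuity correction, df = 1) on the 2x2
#' predicted-vs-actual table.
#'
#' @param conf a [confusion_table()].
#' @return list with `chisq`, `df`, `p`.
#' @export
chisq_vs_chance <- function(conf) {
  m <- matrix(c(conf$tp, conf$fn, conf$fp, conf$tn), 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate-table error: zero margin")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chisq = unname(ct$statistic), df = 1, p = unname(ct$p.value))
}

#' Maximum-likelihood logistic regression with separation flagging
#'
#' Fits `y ~ intercept + predictors` by iteratively reweighted least squares
#' (via `stats::glm`, binomial family, tolerance 1e-8, at most 100
#' iterations).  Complete separation is flagged (fitted probabilities
#' numerically 0/1), in which case coefficients are at their divergent
#' limiting values and predictions follow the limiting rule.
#'
#' @param predictors n x k numeric matrix or data.frame.
#' @param labels binary outcome (logical, 0/1, or 2-level factor with the
#'   positive class first).
#' @return list with `coef`, `fitted`, `converged`, `separated`.
#' @export
fit_logistic <- function(predictors, labels) {
  X <- as.matrix(predictors)
  y <- as_binary01(labels)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1) stop("sample-size error: need n > k + 1")
  if (any(apply(X, 2, sd) == 0))
    stop("design error: constant predictor")
  dat <- data.frame(y = y, X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  separated <- sep_warn &&
    all(abs(fit$fitted.values - y) < 1e-6)
  if (!fit$converged && !sep_warn)
    stop("fit error: logistic regression did not converge")
  list(coef = coef(fit), fitted = fit$fitted.values,
       converged = fit$converged, separated = separated, model = fit)
}

as_binary01 <- function(labels) {
  if (is.factor(labels)) as.numeric(labels == levels(labels)[1])
  else if (is.logical(labels)) as.numeric(labels)
  else if (all(labels %in% c(0, 1))) as.numeric(labels)
  else stop("validation error: labels must be binary")
}

predict_logistic <- function(coefs, x) {
  stats::plogis(drop(cbind(1, rbind(x)) %*% coefs))
}

#' Predictor specification for the cross-validated classifier
#'
#' @param circuits list of circuits; each is `list(name, seed, reference)`
#'   where `reference` is a full-sample cluster (from
#'   [extract_clusters()]) used only to identify the matching fold cluster,
#'   never as a mask.
#' @param covariates character vector of cohort covariate column names
#'   (e.g. `"years_education"`).
#' @return object of class `predictor_spec`.
#' @export
predictor_spec <- function(circuits = list(), covariates = character(0)) {
  if (length(circuits) + length(covariates) < 1)
    stop("validation error: need at least one predictor")
  for (cc in circuits)
    stopifnot(!is.null(cc$seed), !is.null(cc$reference$voxels))
  structure(list(circuits = circuits, covariates = covariates),
            class = "predictor_spec")
}

match_cluster <- function(fold_clusters, reference, k_min) {
  if (!length(fold_clusters)) return(NULL)
  overlaps <- vapply(fold_clusters, function(cl)
    length(intersect(cl$voxels, reference$voxels)), 0)
  sizes <- vapply(fold_clusters, `[[`, 0, "size")
  peaks <- vapply(fold_clusters, function(cl) abs(cl$peak_stat), 0)
  pick_best <- function(cand) {
    cand[order(-overlaps[cand], -sizes[cand], -peaks[cand])][1]
  }
  big <- which(sizes >= k_min & overlaps > 0)
  if (length(big)) {
    i <- pick_best(big)
    return(c(fold_clusters[[i]], list(overlap = overlaps[i], fallback = "none")))
  }
  any_overlap <- which(overlaps > 0)
  if (length(any_overlap)) {
    i <- pick_best(any_overlap)
    return(c(fold_clusters[[i]],
             list(overlap = overlaps[i], fallback = "subthreshold-extent")))
  }
  # zero overlap anywhere: nearest peak in mm
  dist <- vapply(fold_clusters, function(cl)
    sqrt(sum((cl$peak_mm - reference$peak_mm)^2)), 0)
  i <- which.min(dist)
  c(fold_clusters[[i]], list(overlap = 0, fallback = "nearest-peak"))
}

#' One leave-one-out fold
#'
#' Recomputes the group contrast without the held-out subject, re-identifies
#' each circuit's cluster as the fold cluster with the largest voxel overlap
#' with the full-sample reference (ties: larger extent, then higher peak;
#' zero overlap falls back to suprathreshold extent, then nearest peak),
#' extracts cluster-mean connectivity for all subjects, fits the logistic
#' model on the training subjects only, and classifies the held-out subject
#' at cutoff 0.5.
#'
#' @param zmaps named list: seed name -> n x V Fisher-z matrix (cocaine
#'   subjects only).
#' @param labels length-n factor with levels `relapse`, `nonrelapse`.
#' @param covariates data.frame of per-subject covariates (may be NULL).
#' @param spec a [predictor_spec()].
#' @param left_out index of the held-out subject.
#' @param settings list with `mask`, `grid`, `voxel_p`, `k_min`,
#'   `connectivity`.
#' @return a fold result list, or NULL if no fold cluster exists for some
#'   circuit.
#' @export
run_fold <- function(zmaps, labels, covariates, spec, left_out, settings) {
  n <- length(labels)
  train <- setdiff(seq_len(n), left_out)
  if (any(table(droplevels(factor(labels[train]))) < 2))
    stop("sample-size error: training groups too small")
  preds <- matrix(NA_real_, n, 0)
  matched <- list()
  seeds_needed <- unique(vapply(spec$circuits, `[[`, "", "seed"))
  fold_cl <- list()
  for (sd_name in seeds_needed) {
    smap <- group_contrast_map(zmaps[[sd_name]][train, , drop = FALSE],
                               labels[train], mask = settings$mask,
                               grid = settings$grid)
    fold_cl[[sd_name]] <- extract_clusters(smap, settings$voxel_p,
                                           settings$connectivity)
  }
  for (cc in spec$circuits) {
    m <- match_cluster(fold_cl[[cc$seed]], cc$reference, settings$k_min)
    if (is.null(m)) {
      warning("fold ", left_out, ": no cluster available for circuit ",
              cc$name)
      return(NULL)
    }
    matched[[cc$name]] <- m
    preds <- cbind(preds, rowMeans(zmaps[[cc$seed]][, m$voxels, drop = FALSE]))
    colnames(preds)[ncol(preds)] <- cc$name
  }
  if (length(spec$covariates)) {
    preds <- cbind(preds, as.matrix(covariates[, spec$covariates, drop = FALSE]))
  }
  fit <- fit_logistic(preds[train, , drop = FALSE],
                      factor(labels[train], levels = c("relapse", "nonrelapse")))
  prob <- predict_logistic(fit$coef, preds[left_out, ])
  list(left_out = left_out, clusters = matched,
       predictors = preds, coef = fit$coef, separated = fit$separated,
       prob = unname(prob), predicted = unname(prob >= 0.5))
}

#' Leave-one-out cross-validated classification
#'
#' Runs one fold per subject and aggregates held-out predictions into a
#' confusion table, sensitivity/specificity/accuracy, and a chi-square test
#' against chance.  Folds whose circuits yield no cluster at all are
#' excluded with a warning.
#'
#' @inheritParams run_fold
#' @param model_name label for the report.
#' @return object of class `loocv_report`: list with `confusion`, `metrics`,
#'   `chisq`, `folds`, `n_failed`, `model`.
#' @export
run_loocv <- function(zmaps, labels, covariates = NULL, spec, settings,
                      model_name = "model") {
  labels <- factor(labels, levels = c("relapse", "nonrelapse"))
  n <- length(labels)
  folds <- lapply(seq_len(n), function(i)
    run_fold(zmaps, labels, covariates, spec, i, settings))
  ok <- !vapply(folds, is.null, TRUE)
  if (!all(ok))
    warning(sum(!ok), " fold(s) failed and were excluded")
  pred_pos <- vapply(folds[ok], `[[`, TRUE, "predicted")
  actual_pos <- labels[ok] == "relapse"
  conf <- confusion_table(tp = sum(pred_pos & actual_pos),
                          fn = sum(!pred_pos & actual_pos),
                          fp = sum(pred_pos & !actual_pos),
                          tn = sum(!pred_pos & !actual_pos))
  structure(list(confusion = conf, metrics = classification_metrics(conf),
                 chisq = chisq_vs_chance(conf), folds = folds,
                 n_failed = sum(!ok), model = model_name),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "LOOCV %s: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%, chi2(1) = %.2f, p = %.3g\n",
    x$model, m$sensitivity, m$specificity, m$accuracy, x$chisq$chisq,
    x$chisq$p))
  invisible(x)
}

#' Pick a reference cluster from the full-sample contrast
#'
#' Returns the largest cluster surviving `k_min` (rank selectable); if no
#' cluster survives, falls back to the largest suprathreshold cluster with a
#' warning.
#'
#' @param smap full-sample contrast `stat_map`.
#' @param voxel_p,k_min,connectivity thresholding settings.
#' @param rank which surviving cluster to return (1 = largest).
#' @return a cluster (as from [extract_clusters()]) or NULL if none exists.
#' @export
find_reference_cluster <- function(smap, voxel_p = 0.005, k_min = 1,
                                   connectivity = 26, rank = 1) {
  cl <- extract_clusters(smap, voxel_p, connectivity)
  if (!length(cl)) return(NULL)
  surviving <- Filter(function(x) x$size >= k_min, cl)
  if (!length(surviving)) {
    warning("no cluster survives k_min; using largest suprathreshold cluster")
    surviving <- cl
  }
  if (rank > length(surviving)) return(NULL)
  surviving[[rank]]
}
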