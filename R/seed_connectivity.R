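#' Build a binary seed mask from a probabilistic map
#'
#' Thresholds an atlas-style probabilistic map (threshold inclusive) and
#' intersects it with the subject's segmentation volume, so voxels outside
#' the segmented structure are excluded even when their atlas probability is
#' high.
#'
#' @param prob_map 3D array of probabilities in \[0, 1\].
#' @param threshold inclusion threshold in (0, 1\] (default 0.5).
#' @param segmentation logical 3D array from the subject's segmentation.
#' @return logical 3D array.
#' @export
build_seed_mask <- function(prob_map, threshold = 0.5, segmentation) {
  if (any(prob_map < -1e-9 | prob_map > 1 + 1e-9))
    stop("validation error: probabilities must lie in [0, 1]")
  if (!(threshold > 0 && threshold <= 1))
    stop("validation error: threshold must lie in (0, 1]")
  if (!identical(dim(prob_map), dim(segmentation)))
    stop("grid error: probabilistic map and segmentation dims differ")
  mask <- (prob_map >= threshold) & (segmentation != 0)
  if (!any(mask)) stop("empty-seed error: no voxel survives threshold and segmentation")
  mask
}

#' Combine centromedial and superficial components into a CMA seed
#'
#' @param centromedial,superficial logical 3D masks on the same grid.
#' @return their voxelwise union.
#' @export
combine_cma <- function(centromedial, superficial) {
  if (!identical(dim(centromedial), dim(superficial)))
    stop("grid error: component masks have different dims")
  out <- (centromedial != 0) | (superficial != 0)
  if (!any(out)) stop("empty-seed error: both CMA components are empty")
  out
}

#' Extract a seed time course
#'
#' Per-timepoint mean over seed voxels, taken from *unsmoothed* (but
#' detrended and bandpassed) data so the seed signal is not diluted by
#' neighbouring tissue.
#'
#' @param series voxels-by-time matrix (or 4D array).
#' @param mask logical seed mask (3D array or voxel-length vector).
#' @return numeric time series.
#' @export
extract_seed_timecourse <- function(series, mask) {
  m <- as.vector(mask) != 0
  x <- if (is.matrix(series)) series else matrix(series, nrow = length(m))
  if (length(m) != nrow(x)) stop("grid error: mask does not match series")
  if (!any(m)) stop("empty-seed error: empty seed mask")
  colMeans(x[m, , drop = FALSE])
}

#' Nuisance regressor design
#'
#' Assembles the T x 8 design of 6 motion parameters plus mean WM and CSF
#' signals.  When a [filter_spec()] is supplied the motion columns receive
#' the identical detrend + bandpass as the data, so regressors and data
#' occupy the same frequency band (WM/CSF means are extracted from already
#' filtered data and are passed through unchanged).
#'
#' @param motion T x 6 matrix.
#' @param wm_ts,csf_ts length-T mean tissue signals.
#' @param fspec optional [filter_spec()] applied to the motion columns.
#' @return T x 8 matrix of class `nuisance_design`.
#' @export
nuisance_design <- function(motion, wm_ts, csf_ts, fspec = NULL) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  if (length(wm_ts) != nrow(motion) || length(csf_ts) != nrow(motion))
    stop("validation error: nuisance series lengths differ")
  if (!is.null(fspec)) motion <- t(bandpass(detrend_quadratic(t(motion)), fspec))
  X <- cbind(motion, wm_ts, csf_ts)
  colnames(X) <- c(paste0("motion", 1:6), "wm", "csf")
  if (any(apply(X, 2, function(v) all(abs(v) < 1e-12))))
    stop("design error: constant-zero nuisance column")
  structure(X, class = c("nuisance_design", "matrix"))
}

#' Whole-brain nuisance-partialled seed correlation map
#'
#' Correlates the seed time course with every brain voxel's series after
#' residualising both against the 8 nuisance regressors plus an intercept
#' (partial Pearson correlation).  Voxels outside the brain mask are `NA`;
#' zero-variance voxels inside the mask are marked invalid (`NA` with a
#' count attribute).
#'
#' @param seed_ts length-T seed time course.
#' @param series voxels-by-time matrix of (smoothed) data.
#' @param nuisance a [nuisance_design()].
#' @param brain_mask logical 3D array or voxel-length vector.
#' @param return_residuals also return the nuisance-residualised voxel
#'   series (rows = in-mask voxels), mainly for diagnostics.
#' @return list with `r` (voxel-length vector, `NA` off-mask), `df`
#'   (T - 8 - 2), and `n_invalid` (plus `residuals` on request).
#' @export
connectivity_map <- function(seed_ts, series, nuisance, brain_mask,
                             return_residuals = FALSE) {
  T <- length(seed_ts)
  stopifnot(ncol(series) == T, nrow(nuisance) == T)
  k <- ncol(nuisance)
  df <- T - k - 2
  if (df <= 0) stop("design error: too few timepoints for nuisance regression")
  X <- cbind(1, unclass(nuisance))
  dec <- qr(X)
  if (dec$rank < ncol(X)) stop("design error: rank-deficient nuisance design")
  Q <- qr.Q(dec)
  m <- as.vector(brain_mask) != 0
  if (length(m) != nrow(series)) stop("grid error: mask does not match series")
  Yb <- series[m, , drop = FALSE]
  Yr <- Yb - (Yb %*% Q) %*% t(Q)
  sr <- seed_ts - drop(Q %*% crossprod(Q, seed_ts))
  snorm <- sqrt(sum(sr^2))
  if (snorm < 1e-12) stop("design error: seed time course lies in the nuisance span")
  vnorm <- sqrt(rowSums(Yr^2))
  r <- drop(Yr %*% sr) / (vnorm * snorm)
  bad <- vnorm < 1e-10
  r[bad] <- NA_real_
  out <- rep(NA_real_, nrow(series))
  out[m] <- r
  res <- list(r = out, df = df, n_invalid = sum(bad))
  if (return_residuals) res$residuals <- Yr
  res
}

#' Fisher z-transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`.  Correlations with
#' `|r| >= 1 - 1e-7` (e.g. a voxel identical to the seed) are clipped to
#' `1 - 1e-7` with a warning so z stays finite (about 8.4); `|r| > 1` is a
#' domain error.
#'
#' @param r numeric vector of correlations (NA passed through).
#' @return Fisher z values.
#' @export
fisher_z <- function(r) {
  ok <- !is.na(r)
  if (any(abs(r[ok]) > 1 + 1e-12))
    stop("domain error: |r| > 1")
  clip <- ok & abs(r) >= 1 - 1e-7
  if (any(clip)) {
    warning(sum(clip), " correlation(s) clipped to |r| = 1 - 1e-7")
    r[clip] <- sign(r[clip]) * (1 - 1e-7)
  }
  atanh(r)
}

#' Per-subject Fisher-z connectivity maps for a set of seeds
#'
#' Runs the full per-subject chain: preprocess (detrend, bandpass, nuisance
#' assembly, smoothing), seed extraction from unsmoothed data, partial
#' correlation against smoothed data, Fisher z.
#'
#' @param scan a `subject_scan`.
#' @param seed_masks named list of logical seed masks.
#' @param fspec a [filter_spec()].
#' @param fwhm smoothing FWHM in mm.
#' @return list with `z` (named list of voxel-length Fisher-z vectors) and
#'   `df`.
#' @export
subject_zmaps <- function(scan, seed_masks, fspec = filter_spec(tr = scan$tr),
                          fwhm = 6) {
  pp <- preprocess_subject(scan, fspec, fwhm)
  z <- lapply(seed_masks, function(sm) {
    ts <- extract_seed_timecourse(pp$filtered, sm)
    cm <- connectivity_map(ts, pp$smoothed, pp$nuisance, scan$masks$brain)
    suppressWarnings(fisher_z(cm$r))
  })
  list(z = z, df = ncol(scan$bold) - 10)
}
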