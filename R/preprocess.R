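#' Temporal filter specification
#'
#' Band edges for the hard discrete-Fourier bandpass applied to resting BOLD
#' series and nuisance regressors.  Defaults retain 0.01-0.1 Hz, the
#' canonical resting-state fluctuation band.
#'
#' @param f_lo,f_hi band edges in Hz.
#' @param tr repetition time in seconds.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(f_lo = 0.01, f_hi = 0.1, tr = 1.7) {
  nyquist <- 1 / (2 * tr)
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= nyquist + 1e-12))
    stop(sprintf(
      "invalid-band error: need 0 <= f_lo < f_hi <= Nyquist (%.4f Hz), got [%g, %g]",
      nyquist, f_lo, f_hi))
  structure(list(f_lo = f_lo, f_hi = f_hi, tr = tr), class = "filter_spec")
}

#' Remove a quadratic trend from time series
#'
#' Subtracts the per-series least-squares fit of an intercept, linear and
#' quadratic term.  Residuals are orthogonal to \{1, t, t^2\}.
#'
#' @param series numeric vector (one series) or matrix with one series per
#'   row and time along columns.
#' @return object of the same shape with the quadratic trend removed.
#' @export
detrend_quadratic <- function(series) {
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, nrow = 1) else series
  n <- ncol(x)
  if (n < 4) stop("detrend error: need at least 4 timepoints")
  Q <- qr.Q(qr(cbind(1, seq_len(n), seq_len(n)^2)))
  out <- x - (x %*% Q) %*% t(Q)
  if (vec) drop(out) else out
}

band_keep_bins <- function(n, spec) {
  k <- seq_len(floor(n / 2))                 # positive-frequency bins, DC excluded
  f <- k / (n * spec$tr)
  tol <- 1e-9 / (n * spec$tr)
  k[f >= spec$f_lo - tol & f <= spec$f_hi + tol]
}

band_basis <- function(n, spec) {
  keep <- band_keep_bins(n, spec)
  if (!length(keep))
    stop("invalid-band error: no Fourier bin falls inside the band")
  t0 <- 0:(n - 1)
  cols <- lapply(keep, function(k) {
    th <- 2 * pi * k * t0 / n
    if (2 * k == n) cbind(cos(th) / sqrt(n))          # Nyquist bin
    else cbind(cos(th) * sqrt(2 / n), sin(th) * sqrt(2 / n))
  })
  do.call(cbind, cols)
}

#' Hard discrete-Fourier bandpass filter
#'
#' Projects each series onto the discrete-Fourier components whose frequency
#' lies inside `[f_lo, f_hi]` (inclusive); every other bin, including DC, is
#' zeroed.  Equivalent to a hard FFT window, hence exactly idempotent and
#' bin-exact: a sinusoid at a retained bin passes unchanged, one at a
#' rejected bin is annihilated.
#'
#' @inheritParams detrend_quadratic
#' @param spec a [filter_spec()].
#' @return filtered series, same shape as the input, real-valued.
#' @export
bandpass <- function(series, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, nrow = 1) else series
  B <- band_basis(ncol(x), spec)
  out <- (x %*% B) %*% t(B)
  if (vec) drop(out) else out
}

# -- spatial smoothing --------------------------------------------------------

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

gauss_kernels <- function(grid, fwhm) {
  fwhm <- rep_len(as.double(fwhm), 3)
  sig <- fwhm_to_sigma(fwhm) / grid$voxel_size
  lapply(sig, gauss_kernel)
}

apply_smooth_kernels <- function(ks, x, grid) {
  .conv3d_sep(x, grid$dims, ks[[1]], ks[[2]], ks[[3]])
}

#' Theoretical per-voxel sd of a mask-renormalised smoothed white-noise field
#'
#' For unit-variance white noise smoothed with [smooth_gaussian()] (zero
#' padding + renormalisation by the smoothed all-ones field), the marginal
#' standard deviation at voxel (i,j,k) is separable:
#' `sqrt(ax_i ay_j az_k) / (bx_i by_j bz_k)` with `a` the within-bounds sum
#' of squared kernel weights and `b` the within-bounds kernel sum per axis.
#' Used by the synthetic generator to give its smooth noise exactly unit
#' marginal variance everywhere, edges included.
#'
#' @inheritParams smooth_gaussian
#' @return voxel-length numeric vector of standard deviations.
#' @keywords internal
smooth_noise_sd_field <- function(grid, fwhm) {
  ks <- gauss_kernels(grid, fwhm)
  axis_vecs <- function(k, n) {
    r <- (length(k) - 1) / 2
    a <- b <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- k[j - i + r + 1]
      a[i] <- sum(w^2); b[i] <- sum(w)
    }
    list(a = a, b = b)
  }
  vx <- axis_vecs(ks[[1]], grid$dims[1])
  vy <- axis_vecs(ks[[2]], grid$dims[2])
  vz <- axis_vecs(ks[[3]], grid$dims[3])
  va <- outer(outer(vx$a, vy$a), vz$a)
  vb <- outer(outer(vx$b, vy$b), vz$b)
  as.vector(sqrt(va) / vb)
}

#' Isotropic Gaussian spatial smoothing with mask renormalisation
#'
#' Convolves each volume with a separable Gaussian kernel of the stated FWHM.
#' Data are zero-padded outside the mask and the result divided by the
#' smoothed mask, so a spatially uniform field is unchanged and signal is not
#' diluted at mask edges.  `fwhm = 0` is the identity.
#'
#' @param volume 3D array, 4D array, or voxels-by-time matrix whose rows
#'   follow the grid's column-major voxel order.
#' @param fwhm kernel full width at half maximum in mm.
#' @param grid the [volume_grid()].
#' @param mask optional logical 3D array (or voxel-length vector); default all
#'   voxels.  Output is 0 outside the mask.
#' @return smoothed object with the input's shape.
#' @export
smooth_gaussian <- function(volume, fwhm, grid, mask = NULL) {
  if (any(fwhm < 0)) stop("smoothing error: fwhm must be >= 0")
  dims_in <- dim(volume)
  V <- n_voxels(grid)
  x <- if (is.matrix(volume) && nrow(volume) == V) volume
       else matrix(volume, nrow = V)
  if (nrow(x) != V || (length(dims_in) > 2 && prod(dims_in[1:3]) != V))
    stop("grid error: volume does not match the grid")
  if (all(fwhm == 0)) return(volume)
  m <- if (is.null(mask)) rep(TRUE, V) else as.logical(as.vector(mask))
  if (length(m) != V) stop("grid error: mask does not match the grid")
  ks <- gauss_kernels(grid, fwhm)
  if (!all(m)) x[!m, ] <- 0
  num <- apply_smooth_kernels(ks, x, grid)
  den <- as.numeric(apply_smooth_kernels(ks, matrix(as.double(m), ncol = 1), grid))
  keep <- m & den > 1e-12
  num[keep, ] <- num[keep, ] / den[keep]
  num[!keep, ] <- 0
  if (is.matrix(volume) && nrow(volume) == V) num
  else array(num, dim = dims_in)
}

#' Preprocess one subject's scan
#'
#' Applies the fixed order quadratic detrend -> bandpass to the BOLD series
#' and (identically) to the nuisance regressors, then spatially smooths a
#' copy of the filtered data.  Seed time courses are meant to be extracted
#' from `$filtered` (unsmoothed); voxelwise connectivity uses `$smoothed`.
#'
#' @param scan a `subject_scan` as produced by [synthesize_subject()] or
#'   assembled from [read_volume()]/[read_motion()] output: a list with
#'   `bold` (voxels x time matrix), `motion`, `masks`, `grid`, `tr`.
#' @param fspec a [filter_spec()]; its `tr` must match the scan.
#' @param fwhm smoothing kernel FWHM in mm (default 6).
#' @return list with `filtered` and `smoothed` voxels-by-time matrices and
#'   the filtered `nuisance` design (see [nuisance_design()]).
#' @export
preprocess_subject <- function(scan, fspec = filter_spec(tr = scan$tr),
                               fwhm = 6) {
  stopifnot(inherits(fspec, "filter_spec"))
  if (abs(fspec$tr - scan$tr) > 1e-4)  # allow float32 header round-off
    stop("invalid-band error: filter_spec tr differs from scan tr")
  filt <- bandpass(detrend_quadratic(scan$bold), fspec)
  nuis <- nuisance_design(scan$motion,
                          wm_ts  = colMeans(filt[as.vector(scan$masks$wm), , drop = FALSE]),
                          csf_ts = colMeans(filt[as.vector(scan$masks$csf), , drop = FALSE]),
                          fspec  = fspec)
  smoothed <- smooth_gaussian(filt, fwhm, scan$grid,
                              mask = scan$masks$brain)
  list(filtered = filt, smoothed = smoothed, nuisance = nuis)
}
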