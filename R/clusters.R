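neighbor_offsets <- function(connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  deg <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
    "6"  = off[deg == 1, , drop = FALSE],
    "18" = off[deg >= 1 & deg <= 2, , drop = FALSE],
    "26" = off[deg >= 1, , drop = FALSE],
    stop("validation error: connectivity must be 6, 18 or 26"))
  # keep one of each +/- pair; edges are undirected
  off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
        (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
}

#' Label connected suprathreshold components
#'
#' Maximal connected components of a binary 3D mask under a 6-, 18- or
#' 26-neighbourhood rule, computed from a vectorised voxel adjacency list.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces + edges +
#'   corners; default, matching common fMRI cluster software).
#' @return list with `labels` (integer array, 0 = background; components
#'   numbered by decreasing size) and `sizes` (voxel counts).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  act <- which(mask)
  labels <- array(0L, d)
  if (!length(act)) return(list(labels = labels, sizes = integer(0)))
  off <- neighbor_offsets(connectivity)
  lin0 <- act - 1L
  i <- lin0 %% d[1]; j <- (lin0 %/% d[1]) %% d[2]; k <- lin0 %/% (d[1] * d[2])
  rank_of <- integer(prod(d)); rank_of[act] <- seq_along(act)
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(off))) {
    ii <- i + off[o, 1]; jj <- j + off[o, 2]; kk <- k + off[o, 3]
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    nb <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1L
    hit <- rank_of[nb] > 0L
    from <- c(from, which(ok)[hit]); to <- c(to, rank_of[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = length(act), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  ord <- order(-sizes)
  relabel <- integer(length(sizes)); relabel[ord] <- seq_along(ord)
  labels[act] <- relabel[memb]
  list(labels = labels, sizes = sizes[ord])
}

#' Extract clusters from a statistic map
#'
#' Thresholds the map two-tailed at the stated voxelwise p, clusters
#' positive- and negative-direction suprathreshold voxels separately
#' (bi-sided clustering), and returns per-cluster size, peak statistic and
#' peak mm coordinate, sorted by size (ties: larger peak).
#'
#' @param smap a `stat_map` from [group_contrast_map()] or
#'   [one_sample_map()].
#' @param voxel_p two-tailed voxelwise probability (default 0.005).
#' @param connectivity neighbourhood rule (default 26).
#' @return list of clusters; each has `voxels` (linear indices), `size`,
#'   `peak_stat`, `peak_ijk`, `peak_mm`, `direction` (+1/-1).
#' @export
extract_clusters <- function(smap, voxel_p = 0.005, connectivity = 26) {
  thr <- stat_threshold_from_p(voxel_p, smap$df, smap$type)
  vals <- smap$values
  m <- as.vector(smap$mask)
  supra <- !is.na(vals) & m &
    (if (smap$type == "t") abs(vals) >= thr else vals >= thr)
  sgn <- if (smap$type == "t") sign(vals) else smap$sign
  out <- list()
  for (dir in c(1, -1)) {
    sel <- supra & !is.na(sgn) & sgn == dir
    if (!any(sel)) next
    lab <- label_clusters(array(sel, smap$grid$dims), connectivity)
    for (cl in seq_along(lab$sizes)) {
      vox <- which(as.vector(lab$labels) == cl)
      stat_v <- vals[vox]
      pk <- vox[which.max(abs(stat_v))]
      out[[length(out) + 1]] <- list(
        voxels = vox, size = length(vox),
        peak_stat = stat_v[which.max(abs(stat_v))],
        peak_ijk = drop(lin_to_ijk(smap$grid, pk)),
        peak_mm = drop(voxel_to_mm(smap$grid, lin_to_ijk(smap$grid, pk))),
        direction = dir)
    }
  }
  ord <- order(-vapply(out, `[[`, 0, "size"),
               -vapply(out, function(x) abs(x$peak_stat), 0))
  out[ord]
}

.kmin_cache <- new.env(parent = emptyenv())

#' Monte-Carlo cluster-size threshold for family-wise error control
#'
#' Simulates null Gaussian fields on the analysis mask, smooths them to the
#' stated FWHM, standardises within the mask, applies the same bi-sided
#' two-tailed voxel threshold as the data analysis, and records the maximum
#' cluster size per iteration.  The returned `k_min` is the smallest k whose
#' exceedance fraction is at most `cluster_alpha`, i.e. clusters of
#' `size >= k_min` control family-wise error at `cluster_alpha`.
#'
#' Results are cached per (grid, mask, FWHM, voxel_p, alpha, iterations,
#' connectivity, seed).
#'
#' @param mask logical 3D analysis mask.
#' @param grid the [volume_grid()].
#' @param fwhm assumed or estimated smoothness, mm (scalar or per-axis).
#' @param voxel_p two-tailed voxelwise probability (default 0.005).
#' @param cluster_alpha family-wise alpha (default 0.05).
#' @param n_iter Monte-Carlo iterations (default 1000; must exceed
#'   1/cluster_alpha).
#' @param connectivity neighbourhood rule (default 26).
#' @param seed stream seed for the null fields.
#' @return list with `k_min` and the per-iteration `max_sizes`.
#' @export
mc_cluster_size_threshold <- function(mask, grid, fwhm, voxel_p = 0.005,
                                      cluster_alpha = 0.05, n_iter = 1000,
                                      connectivity = 26, seed = 1) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_alpha > 0, cluster_alpha < 1)
  if (n_iter < 100 || cluster_alpha < 1 / n_iter)
    stop("resolution error: n_iter too small for cluster_alpha")
  midx <- which(as.vector(mask) != 0)
  key <- paste(c(grid$dims, signif(grid$voxel_size, 8), signif(fwhm, 6),
                 voxel_p, cluster_alpha, n_iter, connectivity, seed,
                 length(midx), sum(midx)), collapse = "_")
  hit <- .kmin_cache[[key]]
  if (!is.null(hit)) return(hit)
  max_sizes <- vapply(seq_len(n_iter), function(it) {
    f <- null_smooth_field(mask, grid, fwhm, child_seed(seed, 7001, it))
    max_null_cluster(f, midx, grid, voxel_p, connectivity)
  }, numeric(1))
  n_allow <- floor(cluster_alpha * n_iter)
  sorted <- sort(max_sizes, decreasing = TRUE)
  k_min <- as.integer(sorted[n_allow + 1] + 1)
  out <- list(k_min = k_min, max_sizes = max_sizes,
              cluster_alpha = cluster_alpha, voxel_p = voxel_p, fwhm = fwhm)
  .kmin_cache[[key]] <- out
  out
}

null_smooth_field <- function(mask, grid, fwhm, seed) {
  x <- rnorm_seeded(n_voxels(grid), seed)
  if (any(fwhm > 0))
    x <- as.vector(smooth_gaussian(matrix(x, ncol = 1), fwhm, grid,
                                   mask = mask))
  x
}

max_null_cluster <- function(field, midx, grid, voxel_p, connectivity) {
  v <- field[midx]
  v <- (v - mean(v)) / sd(v)
  zthr <- qnorm(1 - voxel_p / 2)
  mx <- 0
  for (dir in c(1, -1)) {
    sel <- dir * v >= zthr
    if (!any(sel)) next
    m <- array(FALSE, grid$dims); m[midx[sel]] <- TRUE
    sz <- label_clusters(m, connectivity)$sizes
    if (length(sz)) mx <- max(mx, sz[1])
  }
  mx
}

#' Estimate spatial smoothness from residual maps
#'
#' Per-axis FWHM from the variance of neighbour differences within the mask:
#' `FWHM = voxel * sqrt(-2 log 2 / log(1 - var_diff / (2 var)))`, the
#' standard Gaussian-autocorrelation estimator; clamped at 0 when the map is
#' no smoother than white noise.  Estimates are averaged over maps.
#'
#' @param maps a voxel-length vector, an n-by-V matrix, or list of such
#'   vectors (e.g. per-subject residual z maps).
#' @param mask logical 3D mask with at least 27 voxels.
#' @param grid the [volume_grid()].
#' @return per-axis FWHM in mm (length 3).
#' @export
estimate_smoothness <- function(maps, mask, grid) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  if (is.null(dim(maps))) maps <- matrix(maps, nrow = 1)
  m3 <- array(as.vector(mask) != 0, grid$dims)
  if (sum(m3) < 27) stop("estimation error: mask too small (< 27 voxels)")
  d <- grid$dims
  one_map <- function(v) {
    a <- array(v, d)
    gv <- var(a[m3])
    vapply(1:3, function(axis) {
      if (d[axis] < 2) return(0)
      idx1 <- slice_idx(d, axis, 2:d[axis])
      idx0 <- slice_idx(d, axis, 1:(d[axis] - 1))
      valid <- m3[idx1] & m3[idx0]
      if (sum(valid) < 8) return(0)
      vd <- var((a[idx1] - a[idx0])[valid])
      rho <- 1 - vd / (2 * gv)
      if (rho <= 0) return(0)
      grid$voxel_size[axis] * sqrt(-2 * log(2) / log(rho))
    }, numeric(1))
  }
  est <- apply(maps, 1, one_map)
  rowMeans(matrix(est, nrow = 3))
}

slice_idx <- function(d, axis, range) {
  args <- list(1:d[1], 1:d[2], 1:d[3])
  args[[axis]] <- range
  outer3 <- expand.grid(i = args[[1]], j = args[[2]], k = args[[3]])
  cbind(outer3$i, outer3$j, outer3$k)
}

#' Cluster report table
#'
#' Tabulates clusters surviving the minimum size, in the style of published
#' cluster summaries: contrast, size in voxels, peak statistic, and peak mm
#' coordinates under the grid's axis convention.
#'
#' @param smap a `stat_map`.
#' @param k_min minimum cluster extent (from
#'   [mc_cluster_size_threshold()]).
#' @param voxel_p voxelwise two-tailed threshold.
#' @param connectivity neighbourhood rule.
#' @return data.frame with columns `contrast`, `size_voxels`, `peak_stat`,
#'   `x_mm`, `y_mm`, `z_mm`, `direction`.
#' @export
cluster_report <- function(smap, k_min, voxel_p = 0.005, connectivity = 26) {
  cl <- extract_clusters(smap, voxel_p, connectivity)
  cl <- Filter(function(x) x$size >= k_min, cl)
  if (!length(cl))
    return(data.frame(contrast = character(0), size_voxels = integer(0),
                      peak_stat = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      direction = integer(0)))
  data.frame(
    contrast = smap$contrast,
    size_voxels = vapply(cl, `[[`, 0, "size"),
    peak_stat = vapply(cl, `[[`, 0, "peak_stat"),
    x_mm = vapply(cl, function(x) x$peak_mm[1], 0),
    y_mm = vapply(cl, function(x) x$peak_mm[2], 0),
    z_mm = vapply(cl, function(x) x$peak_mm[3], 0),
    direction = as.integer(vapply(cl, `[[`, 0, "direction")))
}
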