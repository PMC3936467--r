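#' Define the analysis grid
#'
#' All volumes, masks and maps in a run live on one common grid; modules
#' reject grid-incompatible inputs at load time.  Peak coordinates are
#' reported in mm under an axis-label convention (default `"LPI"`: positive
#' values run Left, Posterior, Inferior), configurable because published
#' coordinate tables differ in sign convention.
#'
#' @param dims integer vector of 3 voxel counts.
#' @param voxel_size numeric vector of 3 voxel edge lengths in mm.
#' @param origin mm coordinate of voxel (1,1,1); defaults to centring the
#'   grid on 0 mm.
#' @param convention axis-label string, stored verbatim (e.g. `"LPI"`).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = c(3.25, 3.25, 3),
                        origin = NULL, convention = "LPI") {
  dims <- as.integer(dims)
  voxel_size <- as.double(voxel_size)
  if (length(dims) != 3L || any(dims < 1L))
    stop("grid error: `dims` must be 3 positive integers")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("grid error: `voxel_size` must be 3 positive mm lengths")
  if (is.null(origin)) origin <- -(dims - 1) / 2 * voxel_size
  structure(list(dims = dims, voxel_size = voxel_size,
                 origin = as.double(origin), convention = convention),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels at %s mm (%s), origin %s mm\n",
              paste(x$dims, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              x$convention, paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Number of voxels on a grid
#' @param grid a [volume_grid()].
#' @return `prod(grid$dims)`.
#' @export
n_voxels <- function(grid) prod(grid$dims)

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(a, b, what = "input") {
  if (!grids_equal(a, b))
    stop("grid error: ", what, " is not on the analysis grid")
  invisible(TRUE)
}

#' Convert voxel indices to mm coordinates
#'
#' @param grid a [volume_grid()].
#' @param ijk matrix (or vector) of 1-based voxel indices, one row per voxel.
#' @return matrix of mm coordinates in the grid's axis convention.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(as.double(ijk), ncol = 3)
  sweep(sweep(ijk - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

# linear index <-> (i,j,k) helpers (1-based, x fastest)
lin_to_ijk <- function(grid, lin) {
  d <- grid$dims
  lin0 <- lin - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_lin <- function(grid, ijk) {
  d <- grid$dims
  (ijk[, 1] - 1L) + d[1] * ((ijk[, 2] - 1L) + d[2] * (ijk[, 3] - 1L)) + 1L
}
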