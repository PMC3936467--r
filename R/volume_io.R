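#' Write a 3D or 4D volume as NIfTI-1
#'
#' Values are stored as 64-bit floats so that a write/read roundtrip is
#' value-identical.
#'
#' @param values 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid the [volume_grid()] the volume lives on.
#' @param tr repetition time in seconds for 4D series (stored in pixdim).
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, path, grid, tr = NULL) {
  nd <- length(dim(values))
  if (!nd %in% c(3L, 4L))
    stop("format error: expected a 3D or 4D array")
  if (!identical(dim(values)[1:3], grid$dims))
    stop("grid error: array dimensions do not match the grid")
  pixdim <- grid$voxel_size
  if (nd == 4L) pixdim <- c(pixdim, if (is.null(tr)) 1 else tr)
  arr <- values
  attr(arr, "pixdim") <- pixdim
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume and its grid metadata
#'
#' @param path path to a NIfTI file.
#' @param grid optional expected [volume_grid()]; a mismatch in dimensions or
#'   voxel size raises a grid error at load time.
#' @return list with `values` (array), `grid`, and `tr` (4th pixdim for 4D
#'   inputs, else `NA`).
#' @export
read_volume <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("format error: ", conditionMessage(e)))
  values <- as.array(img)
  nd <- length(dim(values))
  if (!nd %in% c(3L, 4L)) stop("format error: expected 3D or 4D NIfTI")
  pd <- RNifti::pixdim(img)
  file_grid <- volume_grid(dim(values)[1:3], abs(pd[1:3]),
                           origin = if (is.null(grid)) NULL else grid$origin,
                           convention = if (is.null(grid)) "LPI" else grid$convention)
  if (!is.null(grid)) check_same_grid(grid, file_grid, basename(path))
  tr <- if (nd == 4L && length(pd) >= 4) pd[4] else NA_real_
  list(values = values, grid = file_grid, tr = tr)
}

#' Read a binary mask
#'
#' Nonzero values are coerced to 1 (probabilistic seed maps are *not* read
#' through this function; see [build_seed_mask()] for thresholding).
#'
#' @param path NIfTI path.
#' @param grid expected [volume_grid()].
#' @return logical 3D array; attribute `empty` flags an all-zero mask, which
#'   is unusable downstream.
#' @export
read_mask <- function(path, grid) {
  v <- read_volume(path, grid)
  if (length(dim(v$values)) != 3L)
    stop("format error: mask must be 3D")
  m <- v$values != 0
  if (!any(m)) {
    warning("empty mask: ", basename(path))
    attr(m, "empty") <- TRUE
  }
  m
}

#' Write a binary mask
#' @param mask logical/numeric 3D array.
#' @inheritParams write_volume
#' @export
write_mask <- function(mask, path, grid) {
  write_volume(array(as.double(mask != 0), dim = grid$dims), path, grid)
}

#' Read a 6-column motion-parameter table
#'
#' @param path whitespace-delimited text, T rows by 6 columns
#'   (3 translations, 3 rotations).
#' @param n_volumes optional expected number of rows.
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path, n_volumes = NULL) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("format error: motion table must have 6 columns, found ", ncol(m))
  if (!is.null(n_volumes) && nrow(m) != n_volumes)
    stop("format error: motion table has ", nrow(m), " rows, expected ",
         n_volumes)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' @rdname read_motion
#' @param motion T x 6 numeric matrix to write.
#' @export
write_motion <- function(motion, path) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  write.table(format(motion, digits = 10, scientific = FALSE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

cohort_groups <- c("relapse", "nonrelapse", "control")

#' Load and validate a cohort table
#'
#' The cohort table lists one subject per row with a group label
#' (`relapse`, `nonrelapse` or `control`) and the two covariates carried
#' through the analysis (years of education, years smoking).
#'
#' @param path TSV with columns `subject_id`, `group`, `years_education`,
#'   `years_smoking`.
#' @param modeled_groups groups that must have at least 2 members.
#' @return validated data.frame.
#' @export
load_cohort <- function(path, modeled_groups = c("relapse", "nonrelapse")) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "years_education", "years_smoking")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("validation error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("validation error: duplicate subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(tab$group), cohort_groups)
  if (length(bad))
    stop("validation error: unknown group label(s): ",
         paste(bad, collapse = ", "))
  counts <- table(factor(tab$group, levels = cohort_groups))
  small <- modeled_groups[counts[modeled_groups] < 2]
  if (length(small))
    stop("validation error: modeled group(s) with < 2 members: ",
         paste(small, collapse = ", "))
  message("cohort: ", paste(sprintf("%s=%d", names(counts), counts),
                            collapse = ", "))
  tab
}

#' @rdname load_cohort
#' @param cohort cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
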