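#' Voxel grid geometry
#'
#' A grid couples an image array shape with the 4x4 voxel-to-mm affine of the
#' scan. All geometry in the package (seed placement, sphere ROIs,
#' stimulation-site lookup) goes through the affine; voxel indices are
#' 0-based and no axis is ever reordered or flipped.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param affine 4x4 numeric voxel-to-mm transform (invertible; last row
#'   `c(0,0,0,1)`).
#' @return An object of class `fmri_grid` with fields `shape`, `affine` and
#'   `voxel_size_mm` (per-axis spacing derived from the affine columns).
#' @export
fmri_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("grid shape must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine is singular")
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vox <= 0)) stop("voxel sizes derived from affine must be positive")
  structure(list(shape = shape, affine = unname(affine), voxel_size_mm = vox),
            class = "fmri_grid")
}

#' @export
print.fmri_grid <- function(x, ...) {
  cat("<fmri_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Test whether two grids describe the same sampling
#'
#' Shapes must be identical and affines must agree entrywise within `tol`
#' (registration software emits tiny float drift, so exact equality is too
#' strict).
#'
#' @param a,b `fmri_grid` objects.
#' @param tol absolute tolerance on affine entries.
#' @export
grids_match <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

stop_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grids_match(a, b))
    stop(sprintf("%s are not on the same grid (shape/affine mismatch)", what))
  invisible(TRUE)
}

#' 4D fMRI series container
#'
#' @param data 4D numeric array `(x, y, z, t)` with all values finite and at
#'   least 2 time points.
#' @param grid an [fmri_grid()].
#' @param tr_seconds repetition time in seconds (> 0).
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, grid, tr_seconds) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array")
  if (!identical(as.integer(dim(data)[1:3]), grid$shape))
    stop("data spatial dimensions do not match the grid")
  if (dim(data)[4] < 2L) stop("a 4D series needs at least 2 time points")
  if (!all(is.finite(data))) stop("data contains non-finite values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  structure(list(data = data, grid = grid, tr_seconds = as.numeric(tr_seconds)),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  cat("<volume4d> ", paste(dim(x$data)[1:3], collapse = " x "), " voxels x ",
      dim(x$data)[4], " frames, TR ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

n_timepoints <- function(vol) dim(vol$data)[4]

#' Binary mask on a voxel grid
#'
#' @param data array of 0/1 (logical or numeric) with the grid's shape.
#' @param grid an [fmri_grid()].
#' @return An object of class `binary_mask` with fields `data` (integer 0/1
#'   array), `grid`, `n_voxels`.
#' @export
binary_mask <- function(data, grid) {
  if (is.logical(data)) data <- data * 1L
  if (!all(data %in% c(0, 1))) stop("mask data must contain only 0/1")
  data <- array(as.integer(data), dim = grid$shape)
  structure(list(data = data, grid = grid, n_voxels = sum(data)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", x$n_voxels, " of ", prod(x$grid$shape), " voxels\n",
      sep = "")
  invisible(x)
}

#' @rdname binary_mask
#' @param mask object to test.
#' @export
is_binary_mask <- function(mask) inherits(mask, "binary_mask")

mask_indices <- function(mask) which(mask$data == 1L)

#' Millimeter positions of all voxel centers
#'
#' @param grid an [fmri_grid()].
#' @return `prod(shape)` x 3 matrix of mm coordinates, rows in array
#'   (column-major) order, so row `i` corresponds to linear index `i`.
#' @export
voxel_centers_mm <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape) - 1L
  t(grid$affine[1:3, 1:3] %*% t(idx) + grid$affine[1:3, 4])
}

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 0 when both masks are empty.
#'
#' @param a,b `binary_mask` objects on matching grids.
#' @export
mask_dice <- function(a, b) {
  stop_grid_mismatch(a$grid, b$grid, "masks")
  s <- a$n_voxels + b$n_voxels
  if (s == 0L) return(0)
  2 * sum(a$data == 1L & b$data == 1L) / s
}
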