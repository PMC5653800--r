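#' Read a NIfTI-1 volume
#'
#' Reads a 3D or 4D NIfTI image. Data axes are kept exactly as stored; no
#' reorientation is applied. For 4D images the repetition time is taken from
#' the header (`pixdim[4]`) and must be positive.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return For a 4D image, a [volume4d()]; for a 3D image, a list of class
#'   `volume3d` with fields `data` and `grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("not a readable NIfTI-1 image: %s (%s)",
                                 path, conditionMessage(e))))
  dims <- dim(img)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  grid <- fmri_grid(dims[1:3], aff)
  if (length(dims) == 3L) {
    return(structure(list(data = array(as.numeric(img), dims), grid = grid),
                     class = "volume3d"))
  }
  if (length(dims) != 4L)
    stop(sprintf("expected a 3D or 4D image, got %dD", length(dims)))
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0)
    stop("4D image has no repetition time: header field pixdim[4] is not positive")
  volume4d(array(as.numeric(img), dims), grid, tr)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks are written as unsigned 8-bit integers (lossless); floating-point
#' volumes as float64 so that read/write round-trips bit-exactly.
#'
#' @param vol a [volume4d()], `volume3d`, [binary_mask()], or a bare 3D array
#'   (requires `grid`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid grid for bare arrays; ignored otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, grid = NULL) {
  if (is_binary_mask(vol)) {
    data <- vol$data; grid <- vol$grid; tr <- NULL; dtype <- "uint8"
  } else if (inherits(vol, "volume4d")) {
    data <- vol$data; grid <- vol$grid; tr <- vol$tr_seconds; dtype <- "double"
  } else if (inherits(vol, "volume3d")) {
    data <- vol$data; grid <- vol$grid; tr <- NULL; dtype <- "double"
  } else if (is.array(vol) && length(dim(vol)) %in% c(3L, 4L)) {
    if (is.null(grid)) stop("grid must be supplied for bare arrays")
    data <- vol; tr <- NULL; dtype <- "double"
  } else stop("unsupported volume type")
  img <- RNifti::asNifti(data)
  pd <- grid$voxel_size_mm
  if (length(dim(data)) == 4L) pd <- c(pd, if (is.null(tr)) 1 else tr)
  RNifti::pixdim(img) <- pd
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Convert a millimeter coordinate to the nearest voxel index
#'
#' Applies the inverse affine and rounds to the nearest integer voxel
#' (0-based). Coordinates mapping outside the grid are returned unchanged
#' with attribute `out_of_grid = TRUE` rather than clamped.
#'
#' @param coord_mm numeric length-3 mm coordinate.
#' @param grid an [fmri_grid()].
#' @return integer length-3 0-based voxel index with attribute `out_of_grid`.
#' @export
mm_to_voxel <- function(coord_mm, grid) {
  stopifnot(length(coord_mm) == 3L)
  v <- solve(grid$affine, c(coord_mm, 1))[1:3]
  idx <- as.integer(round(v))
  oob <- any(idx < 0L) || any(idx > grid$shape - 1L)
  structure(idx, out_of_grid = oob)
}

#' Millimeter position of a voxel center
#'
#' @param idx integer length-3 0-based voxel index.
#' @param grid an [fmri_grid()].
#' @export
voxel_to_mm <- function(idx, grid) {
  stopifnot(length(idx) == 3L)
  as.numeric(grid$affine %*% c(idx, 1))[1:3]
}

#' Spherical ROI on a voxel grid
#'
#' The mask contains exactly the voxels whose center lies within
#' `radius_mm` of `center_mm` (closed Euclidean ball in mm space).
#'
#' @param center_mm mm coordinate of the sphere center.
#' @param radius_mm sphere radius in mm (> 0). The default 6 mm is a
#'   conventional seed size for seed-based connectivity.
#' @param grid an [fmri_grid()].
#' @return a [binary_mask()]; an error if no voxel center falls in the ball.
#' @export
make_sphere_roi <- function(center_mm, radius_mm = 6, grid) {
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("radius_mm must be > 0")
  ctr <- voxel_centers_mm(grid)
  d2 <- (ctr[, 1] - center_mm[1])^2 + (ctr[, 2] - center_mm[2])^2 +
    (ctr[, 3] - center_mm[3])^2
  inside <- d2 <= radius_mm^2
  if (!any(inside))
    stop(sprintf("empty ROI: no voxel center within %.3g mm of (%s)",
                 radius_mm, paste(signif(center_mm, 4), collapse = ", ")))
  m <- array(0L, grid$shape)
  m[inside] <- 1L
  binary_mask(m, grid)
}

#' Read a six-column rigid-body motion-parameter table
#'
#' Plain-text whitespace-delimited, one row per frame; by default the first
#' three columns are translations in mm and the last three rotations in
#' degrees.
#'
#' @param path text file path.
#' @param order `"trans_rot"` (default) or `"rot_trans"`.
#' @return a `motion_trace` list with matrices `translations_mm` and
#'   `rotations_deg`.
#' @export
read_motion_trace <- function(path, order = c("trans_rot", "rot_trans")) {
  order <- match.arg(order)
  tab <- as.matrix(utils::read.table(path))
  motion_trace(tab, order = order)
}

#' @rdname read_motion_trace
#' @param params n x 6 numeric matrix of rigid-body parameters.
#' @export
motion_trace <- function(params, order = c("trans_rot", "rot_trans")) {
  order <- match.arg(order)
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion table must have 6 columns")
  if (nrow(params) < 1L) stop("motion table is empty")
  if (!all(is.finite(params))) stop("motion parameters must be finite")
  cols <- if (order == "trans_rot") list(t = 1:3, r = 4:6) else list(t = 4:6, r = 1:3)
  structure(list(translations_mm = params[, cols$t, drop = FALSE],
                 rotations_deg = params[, cols$r, drop = FALSE]),
            class = "motion_trace")
}

#' Read a stimulation-site table
#'
#' Expected plain-text columns: `label x_mm y_mm z_mm positive` (header row
#' optional), where `positive` is 0/1.
#'
#' @param path text file path.
#' @return data frame with columns `label`, `x_mm`, `y_mm`, `z_mm`,
#'   `positive` (logical).
#' @export
read_sites_table <- function(path) {
  first <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  header <- suppressWarnings(any(is.na(as.numeric(first[-1]))))
  tab <- utils::read.table(path, header = header,
                           col.names = c("label", "x_mm", "y_mm", "z_mm", "positive"))
  tab$label <- as.character(tab$label)
  if (anyDuplicated(tab$label)) stop("site labels must be unique")
  tab$positive <- as.logical(tab$positive)
  tab
}
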