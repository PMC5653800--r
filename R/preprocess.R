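#' Discard initial frames of a series
#'
#' Scanner signal needs several repetitions to reach steady-state
#' magnetization, so the leading frames of a resting-state run are dropped
#' before any temporal processing (conventionally the first 10 of a
#' 240-frame acquisition).
#'
#' @param vol a [volume4d()].
#' @param n_discard number of leading frames to drop (>= 0; at least 2
#'   frames must remain).
#' @return the shortened [volume4d()]; grid and TR unchanged.
#' @export
discard_initial <- function(vol, n_discard = 10) {
  n_discard <- as.integer(n_discard)
  nt <- n_timepoints(vol)
  if (n_discard < 0L) stop("n_discard must be non-negative")
  if (n_discard >= nt - 1L)
    stop(sprintf("cannot discard %d of %d frames: at least 2 must remain",
                 n_discard, nt))
  if (n_discard == 0L) return(vol)
  volume4d(vol$data[, , , (n_discard + 1L):nt, drop = FALSE],
           vol$grid, vol$tr_seconds)
}

#' Screen a motion trace against exclusion limits
#'
#' A subject fails when any frame's translation exceeds `trans_limit_mm` on
#' any axis or any rotation exceeds `rot_limit_deg` (strict inequality:
#' motion of exactly the limit passes).
#'
#' @param m a `motion_trace` (see [motion_trace()]).
#' @param trans_limit_mm,rot_limit_deg exclusion limits (defaults 2 mm / 2
#'   degrees).
#' @return list with `pass` (logical) and `offending_frames` (1-based frame
#'   indices exceeding either limit).
#' @export
screen_motion <- function(m, trans_limit_mm = 2, rot_limit_deg = 2) {
  if (!inherits(m, "motion_trace")) stop("m must be a motion_trace")
  bad_t <- apply(abs(m$translations_mm) > trans_limit_mm, 1, any)
  bad_r <- apply(abs(m$rotations_deg) > rot_limit_deg, 1, any)
  off <- which(bad_t | bad_r)
  list(pass = length(off) == 0L, offending_frames = off)
}

## In-mask voxel time series as a t x v matrix; inverse writes back and
## zeroes everything outside the mask.
mask_series <- function(vol, mask) {
  stop_grid_mismatch(vol$grid, mask$grid, "volume and mask")
  idx <- mask_indices(mask)
  nt <- n_timepoints(vol)
  x <- matrix(vol$data, ncol = nt)  # voxels x t
  t(x[idx, , drop = FALSE])
}

unmask_series <- function(series, vol, mask) {
  idx <- mask_indices(mask)
  nt <- n_timepoints(vol)
  out <- matrix(0, nrow = prod(vol$grid$shape), ncol = nt)
  out[idx, ] <- t(series)
  volume4d(array(out, dim = c(vol$grid$shape, nt)), vol$grid, vol$tr_seconds)
}

#' Remove per-voxel linear trends
#'
#' For every in-mask voxel the least-squares line (intercept + slope over
#' frame index) is subtracted; out-of-mask voxels are set to zero.
#'
#' @param vol a [volume4d()].
#' @param mask analysis [binary_mask()] on the same grid (non-empty).
#' @return detrended [volume4d()].
#' @export
detrend_volume <- function(vol, mask) {
  if (mask$n_voxels == 0L) stop("mask is empty")
  y <- mask_series(vol, mask)
  nt <- nrow(y)
  x <- cbind(1, seq_len(nt))
  beta <- solve(crossprod(x), crossprod(x, y))
  unmask_series(y - x %*% beta, vol, mask)
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied to each
#' in-mask voxel series; the canonical resting-state band is 0.01-0.08 Hz.
#' Each series is demeaned before filtering (the mean is a 0 Hz component,
#' outside any pass band); out-of-mask voxels are zeroed.
#'
#' @param vol a [volume4d()].
#' @param mask analysis [binary_mask()].
#' @param low_hz,high_hz band edges in Hz; `0 <= low_hz < high_hz < 1/(2 TR)`.
#' @param filter_order Butterworth design order (the forward-backward pass
#'   doubles the effective order).
#' @return filtered [volume4d()].
#' @export
bandpass_volume <- function(vol, mask, low_hz = 0.01, high_hz = 0.08,
                            filter_order = 2) {
  nyquist <- 1 / (2 * vol$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyquist)
    stop(sprintf("high_hz (%.3g Hz) must be below the Nyquist frequency %.3g Hz",
                 high_hz, nyquist))
  if (mask$n_voxels == 0L) stop("mask is empty")
  bf <- signal::butter(filter_order, c(low_hz, high_hz) / nyquist, type = "pass")
  y <- mask_series(vol, mask)
  y <- sweep(y, 2, colMeans(y))
  for (j in seq_len(ncol(y)))
    y[, j] <- signal::filtfilt(bf, y[, j])
  unmask_series(y, vol, mask)
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

## Shift-and-add 1D convolution along one array axis, zero padding.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dim(x) <- c(d[axis], prod(d[-axis]))
  n <- nrow(x)
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(kernel)) {
    src <- seq_len(n) + (j - r - 1L)
    keep <- which(src >= 1L & src <= n)
    if (length(keep))
      out[keep, ] <- out[keep, ] + kernel[j] * x[src[keep], , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

smooth_frame <- function(frame, sigma_vox) {
  for (axis in 1:3)
    if (sigma_vox[axis] > 0)
      frame <- convolve_axis(frame, gaussian_kernel_1d(sigma_vox[axis]), axis)
  frame
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable 3D Gaussian convolution with the kernel width given
#' as full width at half maximum in millimeters
#' (`sigma = fwhm / (2 sqrt(2 ln 2))` per axis, divided by the voxel size).
#' Boundaries use constant-zero padding; the discrete kernel is normalized
#' to unit sum so interior mass is preserved.
#'
#' @param vol a [volume4d()], `volume3d`, or bare 3D array with `grid`.
#' @param fwhm_mm kernel FWHM in mm (> 0); 8 mm is the conventional
#'   single-subject resting-state choice.
#' @param grid grid for bare arrays.
#' @return same type as the input.
#' @export
smooth_volume <- function(vol, fwhm_mm = 8, grid = NULL) {
  if (!is.numeric(fwhm_mm) || fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  if (inherits(vol, "volume4d")) grid <- vol$grid
  else if (inherits(vol, "volume3d")) grid <- vol$grid
  else if (is.null(grid)) stop("grid must be supplied for bare arrays")
  sigma_vox <- fwhm_mm / (grid$voxel_size_mm * 2 * sqrt(2 * log(2)))
  if (inherits(vol, "volume4d")) {
    out <- vol$data
    for (t in seq_len(n_timepoints(vol)))
      out[, , , t] <- smooth_frame(vol$data[, , , t], sigma_vox)
    return(volume4d(out, grid, vol$tr_seconds))
  }
  data <- if (inherits(vol, "volume3d")) vol$data else vol
  sm <- smooth_frame(data, sigma_vox)
  if (inherits(vol, "volume3d")) structure(list(data = sm, grid = grid),
                                           class = "volume3d")
  else sm
}

#' Standard temporal conditioning of one subject
#'
#' Convenience composition: discard initial frames, remove linear trends,
#' band-pass, optional spatial smoothing.
#'
#' @inheritParams discard_initial
#' @inheritParams bandpass_volume
#' @param fwhm_mm smoothing FWHM in mm, or `NULL` to skip smoothing.
#' @return preprocessed [volume4d()].
#' @export
preprocess_volume <- function(vol, mask, n_discard = 10, low_hz = 0.01,
                              high_hz = 0.08, fwhm_mm = NULL) {
  vol <- discard_initial(vol, n_discard)
  vol <- detrend_volume(vol, mask)
  vol <- bandpass_volume(vol, mask, low_hz, high_hz)
  if (!is.null(fwhm_mm)) vol <- smooth_volume(vol, fwhm_mm)
  vol
}
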