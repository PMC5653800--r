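## Symmetric FastICA (logcosh contrast) after PCA whitening to `nc`
## components. Convergence is declared when every statistically
## identifiable component direction is stable: a whitened direction whose
## logcosh moment gap |E[s g(s)] - E[g'(s)]| is at the Gaussian floor
## carries no non-Gaussian structure, and ICA theory leaves any rotation of
## the Gaussian subspace equally valid, so such directions are excluded
## from the convergence test. Requested orders above the non-Gaussian
## signal rank therefore still converge instead of oscillating forever in
## the unidentifiable subspace.
fastica_sym <- function(x, nc, maxit = 1000, tol = 1e-4,
                        gauss_gap_floor = 0.02) {
  nobs <- nrow(x)
  x <- sweep(x, 2, colMeans(x))
  e <- eigen(crossprod(x) / nobs, symmetric = TRUE)
  if (e$values[nc] <= e$values[1] * 1e-12)
    stop("numerical rank of the data is below the requested order")
  K <- e$vectors[, 1:nc, drop = FALSE] %*% diag(1 / sqrt(e$values[1:nc]), nc)
  xw <- x %*% K                           # samples x nc, white
  W <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))
  ## Null sd of the per-direction gap statistic s g(s) + g(s)^2 - 1 under a
  ## standard normal is 0.9267; directions whose observed gap sits within
  ## sampling noise of zero are Gaussian-unidentifiable.
  floor_used <- max(gauss_gap_floor, 5 * 0.9267 / sqrt(nobs))
  iter <- 0L
  converged <- FALSE
  while (iter < maxit) {
    iter <- iter + 1L
    s <- xw %*% W
    gs <- tanh(s)
    w1 <- crossprod(xw, gs) / nobs - W %*% diag(1 - colMeans(gs^2), nc)
    gap <- abs(colMeans(s * gs) - (1 - colMeans(gs^2)))
    sv <- La.svd(w1)
    Wnew <- sv$u %*% sv$vt
    align <- abs(colSums(W * Wnew))
    identifiable <- gap > floor_used
    vtol <- if (any(identifiable)) 1 - min(align[identifiable]) else 0
    W <- Wnew
    if (vtol < tol) { converged <- TRUE; break }
  }
  S <- xw %*% W                           # samples x nc, unit variance
  A <- crossprod(x, S) / nobs             # variables x nc mixing
  vafs <- nobs * colSums(A^2) / sum(x^2)
  ord <- order(vafs, decreasing = TRUE)
  list(S = S[, ord, drop = FALSE], M = A[, ord, drop = FALSE],
       vafs = vafs[ord], iter = iter, converged = converged)
}

#' Spatial ICA at one model order
#'
#' Decomposes the in-mask voxel-by-time data into `order` spatially
#' independent components: PCA whitening to exactly `order` principal
#' components followed by symmetric FastICA with the logcosh contrast.
#' Each spatial map is then standardized to mean 0 / sd 1 over the mask —
#' the z-scale on which maps are thresholded and compared — and oriented so
#' its skewness is non-negative (the signed map and its time course are
#' flipped together, leaving the reconstruction unchanged). A fixed
#' `rng_seed` makes the run bit-reproducible.
#'
#' Convergence is assessed over the identifiable components only: whitened
#' directions indistinguishable from Gaussian (logcosh moment gap below
#' `gauss_gap_floor`) admit no preferred rotation, so their wander is not
#' counted as non-convergence. Components are returned in decreasing order
#' of variance accounted for.
#'
#' @param vol a [volume4d()].
#' @param mask analysis [binary_mask()].
#' @param order requested number of components (2 <= order <
#'   `min(n_timepoints, n_in_mask_voxels)`).
#' @param rng_seed integer seed for the random unmixing initialization.
#' @param maxit,tol iteration cap and convergence tolerance.
#' @param gauss_gap_floor identifiability floor on the logcosh moment gap.
#' @return a `component_set` list: `order`, `spatial_zmaps` (order x
#'   in-mask-voxel matrix), `timecourses` (n_timepoints x order), `mask`,
#'   `rng_seed`, `converged`, `iterations`, `skewness`, `vafs` (variance
#'   accounted for, per component).
#' @export
run_ica <- function(vol, mask, order, rng_seed, maxit = 1000, tol = 1e-4,
                    gauss_gap_floor = 0.02) {
  stop_grid_mismatch(vol$grid, mask$grid, "volume and mask")
  order <- as.integer(order)
  nt <- n_timepoints(vol)
  nv <- mask$n_voxels
  if (order < 2L) stop("order must be at least 2")
  if (order >= min(nt, nv))
    stop(sprintf("order %d too large: must be below min(n_timepoints = %d, n_voxels = %d)",
                 order, nt, nv))
  y <- mask_series(vol, mask)              # t x v
  x <- t(y)                                # voxels x t: rows are ICA samples
  if (stats::sd(as.numeric(x)) == 0) stop("data has zero variance")
  set.seed(as.integer(rng_seed))
  fit <- fastica_sym(x, nc = order, maxit = maxit, tol = tol,
                     gauss_gap_floor = gauss_gap_floor)
  if (!isTRUE(fit$converged))
    stop(sprintf("ICA did not converge after %d iterations (order %d, seed %d)",
                 maxit, order, as.integer(rng_seed)))
  maps <- t(fit$S)                         # order x voxels
  mu <- rowMeans(maps)
  sdv <- sqrt(rowSums((maps - mu)^2) / (ncol(maps) - 1))
  if (any(sdv == 0)) stop("degenerate (constant) component map")
  zmaps <- (maps - mu) / sdv
  skew <- rowMeans(zmaps^3)
  flip <- ifelse(skew < 0, -1, 1)
  zmaps <- zmaps * flip
  tc <- fit$M * rep(flip, each = nrow(fit$M))  # t x order mixing
  structure(list(order = order, spatial_zmaps = zmaps, timecourses = tc,
                 mask = mask, rng_seed = as.integer(rng_seed),
                 converged = fit$converged, iterations = fit$iter,
                 skewness = abs(skew), vafs = fit$vafs),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("<component_set> order ", x$order, ", ", ncol(x$spatial_zmaps),
      " in-mask voxels, seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}

#' Spatial ICA over a grid of model orders
#'
#' Runs [run_ica()] once per requested order with a deterministic per-order
#' seed (`rng_seed + order`). A per-order failure is recorded and skipped as
#' long as at least one order succeeds.
#'
#' @param vol a [volume4d()].
#' @param mask analysis [binary_mask()].
#' @param orders integer vector of model orders (scanner-scale default
#'   `c(20, 30, 40, 50, 60)`; phantom-scale grids such as `c(5, 8, 11)` are
#'   equally valid).
#' @param rng_seed base integer seed.
#' @param ... passed to [run_ica()].
#' @return named list (names = orders) of `component_set`s, with attribute
#'   `failures` (named list of error messages for orders that failed).
#' @export
multi_order_ica <- function(vol, mask, orders = c(20, 30, 40, 50, 60),
                            rng_seed, ...) {
  orders <- as.integer(orders)
  out <- list()
  failures <- list()
  for (k in orders) {
    res <- tryCatch(run_ica(vol, mask, k, rng_seed + k, ...),
                    error = function(e) e)
    if (inherits(res, "error")) failures[[as.character(k)]] <- conditionMessage(res)
    else out[[as.character(k)]] <- res
  }
  if (length(out) == 0L)
    stop(paste0("ICA failed at every model order:\n",
                paste(sprintf("  order %s: %s", names(failures),
                              unlist(failures)), collapse = "\n")))
  attr(out, "failures") <- failures
  out
}

#' Temporally concatenate a cohort for group ICA
#'
#' Each subject's in-mask voxel series is variance-normalized (unit
#' temporal sd per voxel; zero-variance voxels left at zero) and the series
#' are stacked along time.
#'
#' @param cohort list of [volume4d()] on a shared grid.
#' @param mask analysis [binary_mask()].
#' @return a [volume4d()] whose length is the sum of subject lengths, with
#'   attribute `subject_lengths`; TR is taken from the first subject.
#' @export
concat_group_data <- function(cohort, mask) {
  if (length(cohort) == 0L) stop("cohort is empty")
  for (v in cohort) stop_grid_mismatch(v$grid, mask$grid, "cohort volumes and mask")
  pieces <- lapply(cohort, function(v) {
    y <- mask_series(v, mask)
    yc <- sweep(y, 2, colMeans(y))
    sdv <- sqrt(colSums(yc^2) / (nrow(yc) - 1))
    ok <- sdv > 0
    yc[, ok] <- sweep(yc[, ok, drop = FALSE], 2, sdv[ok], "/")
    yc
  })
  stacked <- do.call(rbind, pieces)
  fake <- volume4d(array(0, c(mask$grid$shape, nrow(stacked))), mask$grid,
                   cohort[[1]]$tr_seconds)
  out <- unmask_series(stacked, fake, mask)
  attr(out, "subject_lengths") <- vapply(pieces, nrow, integer(1))
  out
}

#' Serialize a component set to NIfTI plus a sidecar table
#'
#' Spatial z-maps are written as one 4D NIfTI (components along the fourth
#' axis, zero outside the mask) and the run metadata as a whitespace
#' table (`component`, `skewness`, `vaf`) plus header comment lines.
#'
#' @param cs a `component_set`.
#' @param nifti_path,table_path output paths.
#' @export
write_component_set <- function(cs, nifti_path, table_path) {
  grid <- cs$mask$grid
  idx <- mask_indices(cs$mask)
  arr <- array(0, c(grid$shape, cs$order))
  for (i in seq_len(cs$order)) {
    frame <- array(0, grid$shape)
    frame[idx] <- cs$spatial_zmaps[i, ]
    arr[, , , i] <- frame
  }
  write_volume(volume4d(arr, grid, 1), nifti_path)
  con <- file(table_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# order %d seed %d converged %s iterations %d",
                     cs$order, cs$rng_seed, cs$converged, cs$iterations), con)
  utils::write.table(data.frame(component = seq_len(cs$order) - 1L,
                                skewness = cs$skewness, vaf = cs$vafs),
                     con, row.names = FALSE, quote = FALSE)
  invisible(nifti_path)
}
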