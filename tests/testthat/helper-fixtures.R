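# Shared small fixtures, built in code.

identity_grid <- function(shape = c(5, 5, 5)) {
  fmri_grid(shape, diag(4))
}

# 3 mm isotropic grid centered at mm (0,0,0)
centered_grid <- function(shape = c(10, 10, 10), vox = 3) {
  aff <- diag(c(rep(vox, 3), 1))
  aff[1:3, 4] <- -(shape - 1) / 2 * vox
  fmri_grid(shape, aff)
}

full_mask <- function(grid) binary_mask(array(1L, grid$shape), grid)

mask_from_indices <- function(grid, idx) {
  m <- array(0L, grid$shape)
  m[idx] <- 1L
  binary_mask(m, grid)
}

# 4D volume from a t x v matrix laid over the whole grid
volume_from_series <- function(series_tv, grid, tr = 2) {
  volume4d(array(t(series_tv), c(grid$shape, nrow(series_tv))), grid, tr)
}

# Minimal two-component phantom for fast FC tests
tiny_phantom <- function(seed = 1, noise_sd = 0.5) {
  make_phantom(phantom_config(grid_shape = c(14, 14, 14), n_timepoints = 80,
                              sources = list(
                                list(name = "A", centers_mm = matrix(c(-9, 9, 0), 1),
                                     radii_mm = 7, amplitude = 1),
                                list(name = "B", centers_mm = matrix(c(9, -9, 0), 1),
                                     radii_mm = 7, amplitude = 1)),
                              noise_sd = noise_sd, rng_seed = seed))
}

# A map plus a configurable set of positive sites at controlled distances:
# `inside` sites sit on 1-voxel centers, `near` sites a known distance from
# the nearest 1-voxel, `far` sites well beyond the radius.
site_fixture <- function(n_inside, n_near, n_far, near_mm = 9,
                         grid_shape = c(30, 30, 30)) {
  grid <- centered_grid(grid_shape, vox = 3)
  m <- array(0L, grid$shape)
  m[10:16, 10:16, 10:16] <- 1L
  map <- binary_mask(m, grid)
  on <- which(map$data == 1L)
  centers <- voxel_centers_mm(grid)
  rows <- list()
  for (i in seq_len(n_inside))
    rows[[length(rows) + 1]] <- centers[on[i], ]
  # near sites: straight out along +x from the max-x face of the block
  face_x <- max(centers[on, 1])
  for (i in seq_len(n_near))
    rows[[length(rows) + 1]] <- c(face_x + near_mm,
                                  centers[on[1], 2] + 3 * (i - 1),
                                  centers[on[1], 3])
  for (i in seq_len(n_far))
    rows[[length(rows) + 1]] <- c(face_x + 30, -30 + 3 * i, -30)
  sites <- do.call(rbind, rows)
  df <- data.frame(label = sprintf("S%02d", seq_len(nrow(sites))),
                   x_mm = sites[, 1], y_mm = sites[, 2], z_mm = sites[, 3],
                   positive = TRUE)
  list(sites = df, map = map, grid = grid)
}

# O(m^2) literal BH step-up: largest k with p_(k) <= k q / m
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  rej <- rep(FALSE, m)
  if (kmax > 0L) rej[o[seq_len(kmax)]] <- TRUE
  rej
}
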