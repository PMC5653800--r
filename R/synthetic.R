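#' Phantom configuration
#'
#' Describes a desk-scale synthetic resting-state acquisition: a voxel grid
#' with an ellipsoidal brain, a set of smooth spatial sources mixed with
#' band-limited time courses, and spatially independent AR(1) Gaussian
#' noise. Defaults emulate a reduced-scale acquisition: 24 x 28 x 24 voxels
#' at 3 mm, 150 frames at TR = 2 s, source amplitude 1 against noise sd 0.5
#' (SNR 2), AR(1) coefficient 0.3.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_timepoints number of frames.
#' @param tr_seconds repetition time in seconds.
#' @param sources list of sources, each a list with `name`, `centers_mm`
#'   (n x 3 matrix of cluster centers), `radii_mm` (per-cluster radius), and
#'   `amplitude`.
#' @param noise_sd marginal noise standard deviation (>= 0).
#' @param ar1_coefficient temporal autocorrelation of the noise, in `[0, 1)`.
#' @param overlap_budget maximum tolerated pairwise source overlap, as a
#'   fraction of the smaller source.
#' @param rng_seed integer seed; every random draw in the generator flows
#'   from it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(24, 28, 24), voxel_size_mm = 3,
                           n_timepoints = 150, tr_seconds = 2,
                           sources = default_sources(), noise_sd = 0.5,
                           ar1_coefficient = 0.3, overlap_budget = 0.05,
                           rng_seed = 1) {
  if (length(sources) < 1L) stop("at least one source is required")
  for (s in sources) {
    if (is.null(s$name) || is.null(s$centers_mm) || is.null(s$radii_mm) ||
        is.null(s$amplitude)) stop("each source needs name, centers_mm, radii_mm, amplitude")
    if (s$amplitude <= 0) stop("source amplitudes must be positive")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stop("ar1_coefficient must be in [0, 1)")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, sources = sources,
                 noise_sd = noise_sd, ar1_coefficient = ar1_coefficient,
                 overlap_budget = overlap_budget,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

## A single mid-brain blob; the minimal default topology.
default_sources <- function() {
  list(list(name = "A", centers_mm = matrix(c(0, 0, 0), 1), radii_mm = 9,
            amplitude = 1))
}

## Language-like two-cluster topology (frontal + temporal sub-networks)
## plus motor-like, visual-like and broad slow-drift confound sources, all
## placed pairwise disjoint inside the ellipsoidal brain.
language_sources <- function() {
  list(
    list(name = "language",
         centers_mm = rbind(c(-18, 21, 6), c(-21, -15, -3)),
         radii_mm = c(7.5, 7.5), amplitude = 1),
    list(name = "motor", centers_mm = matrix(c(18, -9, 15), 1),
         radii_mm = 9, amplitude = 1),
    list(name = "visual", centers_mm = matrix(c(0, -30, -6), 1),
         radii_mm = 9, amplitude = 1),
    list(name = "drift", centers_mm = matrix(c(0, 6, 0), 1),
         radii_mm = 12, amplitude = 0.6)
  )
}

phantom_grid <- function(config) {
  aff <- diag(c(rep(config$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -(config$grid_shape - 1) / 2 * config$voxel_size_mm
  fmri_grid(config$grid_shape, aff)
}

ellipsoid_brain <- function(grid, fill = 0.52) {
  extent <- grid$shape * grid$voxel_size_mm
  semi <- fill * extent
  ctr <- voxel_centers_mm(grid)
  inside <- (ctr[, 1] / semi[1])^2 + (ctr[, 2] / semi[2])^2 +
    (ctr[, 3] / semi[3])^2 <= 1
  binary_mask(array(inside, grid$shape), grid)
}

## Union of thresholded Gaussian blobs: profile exp(-d^2/(2 sigma^2)) > 0.5
## with sigma = r / sqrt(2 ln 2), i.e. a smooth profile whose half-maximum
## surface is the sphere of radius r.
source_mask <- function(src, grid) {
  ctr <- voxel_centers_mm(grid)
  inside <- rep(FALSE, nrow(ctr))
  for (j in seq_len(nrow(src$centers_mm))) {
    c_mm <- src$centers_mm[j, ]
    sigma <- src$radii_mm[j] / sqrt(2 * log(2))
    d2 <- (ctr[, 1] - c_mm[1])^2 + (ctr[, 2] - c_mm[2])^2 +
      (ctr[, 3] - c_mm[3])^2
    inside <- inside | exp(-d2 / (2 * sigma^2)) > 0.5
  }
  binary_mask(array(inside, grid$shape), grid)
}

## Band-limited, mutually orthogonal time courses: each source gets a
## disjoint random subset of the Fourier bins lying in 0.01-0.08 Hz, with
## random amplitudes and phases; distinct bins are exactly orthogonal over
## the full record, so pairwise correlations vanish.
band_limited_timecourses <- function(n_timepoints, tr_seconds, n_sources,
                                     low_hz = 0.01, high_hz = 0.08) {
  duration <- n_timepoints * tr_seconds
  bins <- seq_len(floor(n_timepoints / 2) - 1)
  freqs <- bins / duration
  band <- bins[freqs >= low_hz & freqs <= high_hz]
  if (length(band) < n_sources)
    stop("record too short: fewer in-band Fourier bins than sources")
  per <- floor(length(band) / n_sources)
  shuffled <- sample(band)
  tt <- seq_len(n_timepoints) - 1
  tc <- matrix(0, n_timepoints, n_sources)
  for (s in seq_len(n_sources)) {
    mybins <- shuffled[((s - 1) * per + 1):(s * per)]
    for (k in mybins) {
      a <- stats::runif(1, 0.5, 1)
      phi <- stats::runif(1, 0, 2 * pi)
      tc[, s] <- tc[, s] + a * sin(2 * pi * k * tt / n_timepoints + phi)
    }
    tc[, s] <- (tc[, s] - mean(tc[, s])) / stats::sd(tc[, s])
  }
  tc
}

ar1_noise <- function(n_timepoints, n_series, sd, phi) {
  if (sd == 0) return(matrix(0, n_timepoints, n_series))
  burn <- 25L
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(stats::rnorm((n_timepoints + burn) * n_series, sd = innov_sd),
              n_timepoints + burn, n_series)
  x <- apply(e, 2, function(col) stats::filter(col, phi, method = "recursive"))
  x[(burn + 1):(burn + n_timepoints), , drop = FALSE]
}

## Gentle sinusoid-plus-noise motion trace, well inside the 2 mm / 2 deg
## exclusion limits.
simulate_motion <- function(n_timepoints) {
  tt <- seq_len(n_timepoints)
  base <- function(scale) scale * sin(2 * pi * tt / n_timepoints +
                                        stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n_timepoints, sd = scale / 4)
  motion_trace(cbind(base(0.15), base(0.15), base(0.2),
                     base(0.1), base(0.1), base(0.1)))
}

#' Generate a phantom resting-state dataset
#'
#' Builds, fully deterministically from `config$rng_seed`: an ellipsoidal
#' brain filling roughly 60% of the grid; one binary mask per source (union
#' of smooth Gaussian-profile blobs thresholded at half maximum); mutually
#' orthogonal band-limited (0.01-0.08 Hz) unit-variance time courses; and
#' AR(1) Gaussian noise over the brain. The 4D volume is exactly
#' `sum_s amplitude_s * mask_s * timecourse_s + noise`.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_dataset` list: `volume` ([volume4d()]), `brain`,
#'   `source_masks` (named list of [binary_mask()]), `source_timecourses`
#'   (n_timepoints x n_sources), `amplitudes`, `motion`, `config`.
#' @export
make_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) stop("config must be a phantom_config")
  set.seed(config$rng_seed)
  grid <- phantom_grid(config)
  brain <- ellipsoid_brain(grid)
  masks <- lapply(config$sources, source_mask, grid = grid)
  names(masks) <- vapply(config$sources, `[[`, character(1), "name")
  for (i in seq_along(masks)) {
    if (masks[[i]]$n_voxels == 0L)
      stop(sprintf("source '%s' contains no voxels", names(masks)[i]))
    if (any(masks[[i]]$data == 1L & brain$data == 0L))
      stop(sprintf("source '%s' extends outside the brain", names(masks)[i]))
  }
  if (length(masks) > 1L) {
    for (i in seq_len(length(masks) - 1L)) for (j in (i + 1):length(masks)) {
      ov <- sum(masks[[i]]$data == 1L & masks[[j]]$data == 1L)
      lim <- config$overlap_budget * min(masks[[i]]$n_voxels,
                                         masks[[j]]$n_voxels)
      if (ov > lim)
        stop(sprintf("sources '%s' and '%s' overlap by %d voxels (budget %.1f)",
                     names(masks)[i], names(masks)[j], ov, lim))
    }
  }
  tc <- band_limited_timecourses(config$n_timepoints, config$tr_seconds,
                                 length(masks))
  colnames(tc) <- names(masks)
  amps <- vapply(config$sources, `[[`, numeric(1), "amplitude")
  names(amps) <- names(masks)
  nv <- prod(grid$shape)
  data <- matrix(0, nv, config$n_timepoints)
  for (i in seq_along(masks)) {
    idx <- mask_indices(masks[[i]])
    data[idx, ] <- data[idx, ] +
      amps[i] * matrix(tc[, i], length(idx), config$n_timepoints, byrow = TRUE)
  }
  bidx <- mask_indices(brain)
  noise <- ar1_noise(config$n_timepoints, length(bidx), config$noise_sd,
                     config$ar1_coefficient)
  data[bidx, ] <- data[bidx, ] + t(noise)
  vol <- volume4d(array(data, c(grid$shape, config$n_timepoints)), grid,
                  config$tr_seconds)
  motion <- simulate_motion(config$n_timepoints)
  structure(list(volume = vol, brain = brain, source_masks = masks,
                 source_timecourses = tc, amplitudes = amps, motion = motion,
                 config = config),
            class = "phantom_dataset")
}

## Dilate a binary mask by one voxel under the given connectivity.
mask_dilate <- function(mask, connectivity = 6) {
  shape <- dim(mask$data)
  sp <- shape + 2L
  pad <- array(0L, sp)
  pad[2:(sp[1] - 1), 2:(sp[2] - 1), 2:(sp[3] - 1)] <- mask$data
  out <- pad
  for (off in neighbor_offsets(sp, connectivity)) {
    idx <- which(pad == 1L) + off
    out[idx] <- 1L
  }
  binary_mask(out[2:(sp[1] - 1), 2:(sp[2] - 1), 2:(sp[3] - 1), drop = FALSE],
              mask$grid)
}

#' Generate a language-mapping phantom
#'
#' A phantom whose source topology mirrors the clinical setting: a
#' two-cluster "language" source (frontal plus temporal sub-network) among
#' motor-like, visual-like and broad slow-drift distractor sources. A
#' deliberately imperfect matching template is derived from the language
#' source by adding a random portion of its one-voxel dilation shell (false
#' positives) and randomly dropping true voxels (false negatives), emulating
#' the template-to-subject registration mismatch seen with warped group
#' templates; its Dice overlap with the true source is required to land in
#' `[0.6, 0.9]`.
#'
#' @param overrides named list of [phantom_config()] fields to override.
#' @param rng_seed integer seed.
#' @param template_dropout fraction of true source voxels randomly removed
#'   from the template.
#' @param template_shell_keep fraction of the dilation shell randomly added
#'   to the template.
#' @return a `phantom_dataset` with extra fields `template`
#'   ([binary_mask()]) and `template_dice` (its Dice against the true
#'   language source).
#' @export
make_language_phantom <- function(overrides = list(), rng_seed = 1,
                                  template_dropout = 0.1,
                                  template_shell_keep = 0.3) {
  args <- utils::modifyList(list(sources = language_sources(),
                                 rng_seed = as.integer(rng_seed)), overrides)
  config <- do.call(phantom_config, args)
  ph <- make_phantom(config)
  truth <- ph$source_masks[["language"]]
  set.seed(config$rng_seed + 999L)
  dil <- mask_dilate(truth, connectivity = 6)
  shell <- which(dil$data == 1L & truth$data == 0L)
  keep_true <- mask_indices(truth)[stats::runif(truth$n_voxels) >= template_dropout]
  keep_shell <- shell[stats::runif(length(shell)) < template_shell_keep]
  m <- array(0L, dil$grid$shape)
  m[c(keep_true, keep_shell)] <- 1L
  template <- binary_mask(m * ph$brain$data, dil$grid)
  dice <- mask_dice(template, truth)
  if (dice < 0.6 || dice > 0.9)
    stop(sprintf("template imperfection out of range: Dice %.3f not in [0.6, 0.9]",
                 dice))
  ph$template <- template
  ph$template_dice <- dice
  ph
}

#' Generate a cohort of phantoms sharing a source topology
#'
#' Subjects share the configured sources up to a small random cluster-center
#' jitter (at most one voxel per axis) and have independent time courses,
#' noise and motion; per-subject seeds are derived deterministically from
#' `rng_seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param jitter_mm maximum absolute per-axis center jitter in mm (must not
#'   exceed the voxel size).
#' @param rng_seed integer seed.
#' @param config base [phantom_config()]; defaults to the language topology.
#' @return list of `phantom_dataset`s.
#' @export
make_cohort <- function(n_subjects, jitter_mm = 2, rng_seed = 1,
                        config = NULL) {
  if (n_subjects < 2L) stop("a cohort needs at least 2 subjects")
  if (is.null(config))
    config <- phantom_config(sources = language_sources(), rng_seed = rng_seed)
  if (jitter_mm > config$voxel_size_mm)
    stop("jitter_mm must not exceed one voxel")
  lapply(seq_len(n_subjects), function(i) {
    seed_i <- config$rng_seed + 101L * i
    set.seed(seed_i)
    src <- lapply(config$sources, function(s) {
      s$centers_mm <- s$centers_mm +
        matrix(stats::runif(length(s$centers_mm), -jitter_mm, jitter_mm),
               nrow(s$centers_mm), 3)
      s
    })
    cfg <- config
    cfg$sources <- src
    cfg$rng_seed <- seed_i + 1L
    make_phantom(cfg)
  })
}

#' Write a phantom dataset to disk
#'
#' Emits the 4D volume, brain mask, per-source masks and template (if any)
#' as NIfTI, the motion trace as a six-column text table, and a manifest of
#' file names.
#'
#' @param ph a `phantom_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(volume = file.path(dir, "volume.nii.gz"),
             brain = file.path(dir, "brain_mask.nii.gz"),
             motion = file.path(dir, "motion.txt"))
  write_volume(ph$volume, paths["volume"])
  write_volume(ph$brain, paths["brain"])
  utils::write.table(cbind(ph$motion$translations_mm, ph$motion$rotations_deg),
                     paths["motion"], row.names = FALSE, col.names = FALSE)
  for (nm in names(ph$source_masks)) {
    p <- file.path(dir, sprintf("source_%s.nii.gz", nm))
    write_volume(ph$source_masks[[nm]], p)
    paths[paste0("source_", nm)] <- p
  }
  if (!is.null(ph$template)) {
    paths["template"] <- file.path(dir, "template.nii.gz")
    write_volume(ph$template, paths["template"])
  }
  writeLines(sprintf("%s\t%s", names(paths), basename(paths)),
             file.path(dir, "manifest.tsv"))
  invisible(paths)
}
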