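#' Seed-based functional connectivity map
#'
#' Correlates the mean time series of a seed region with every in-brain
#' voxel's series (Pearson r), then applies the variance-stabilizing Fisher
#' transform `z = atanh(r)` with `|r|` clipped to `1 - 1e-7` so that
#' self-correlated series stay finite. Voxels with zero temporal variance
#' get `r = 0` and are flagged.
#'
#' @param vol preprocessed [volume4d()].
#' @param seed seed [binary_mask()] (non-empty, inside `brain`).
#' @param brain analysis [binary_mask()].
#' @param seed_center_mm optional mm coordinate recorded in the result.
#' @return an `fc_map` list: 3D arrays `r` and `z` (zero outside the brain
#'   mask), `grid`, `seed_center_mm`, and `flagged` (linear indices of
#'   zero-variance voxels).
#' @export
seed_fc_map <- function(vol, seed, brain, seed_center_mm = NULL) {
  stop_grid_mismatch(vol$grid, brain$grid, "volume and brain mask")
  stop_grid_mismatch(seed$grid, brain$grid, "seed and brain mask")
  if (seed$n_voxels == 0L) stop("seed mask is empty")
  if (any(seed$data == 1L & brain$data == 0L))
    stop("seed mask must lie inside the brain mask")
  if (n_timepoints(vol) < 3L) stop("need at least 3 time points")
  y <- mask_series(vol, brain)                    # t x v
  seed_in_brain <- which(seed$data[mask_indices(brain)] == 1L)
  s <- rowMeans(y[, seed_in_brain, drop = FALSE])
  if (stats::sd(s) == 0) stop("seed mean time series has zero variance")
  sc <- s - mean(s)
  yc <- sweep(y, 2, colMeans(y))
  sds <- sqrt(colSums(yc^2))
  r <- as.numeric(crossprod(yc, sc)) / (sds * sqrt(sum(sc^2)))
  flagged_local <- which(sds == 0)
  r[flagged_local] <- 0
  rmap <- array(0, vol$grid$shape)
  idx <- mask_indices(brain)
  rmap[idx] <- r
  zmap <- array(0, vol$grid$shape)
  zmap[idx] <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  structure(list(r = rmap, z = zmap, grid = vol$grid,
                 seed_center_mm = seed_center_mm, flagged = idx[flagged_local]),
            class = "fc_map")
}

#' Voxelwise one-sample t-test over subject z-maps
#'
#' For each in-brain voxel, `t = mean(z) / (sd(z)/sqrt(n))` with
#' `df = n - 1`. The template represents positive connectivity, so the
#' default alternative is one-sided (`"greater"`); `"two.sided"` is
#' available. Zero-variance voxels are assigned `p = 1` and flagged.
#'
#' @param z_maps list of `fc_map` objects (>= 2) on a shared grid.
#' @param brain analysis [binary_mask()].
#' @param alternative `"greater"` or `"two.sided"`.
#' @return a `group_stat_map` list: 3D arrays `t` and `p`, `df`, `grid`,
#'   `flagged` indices.
#' @export
group_ttest <- function(z_maps, brain, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(z_maps) < 2L) stop("group t-test needs at least 2 subjects")
  for (m in z_maps) stop_grid_mismatch(m$grid, brain$grid, "z-maps and brain mask")
  idx <- mask_indices(brain)
  zm <- vapply(z_maps, function(m) m$z[idx], numeric(length(idx)))
  n <- length(z_maps)
  mu <- rowMeans(zm)
  sdv <- sqrt(rowSums((zm - mu)^2) / (n - 1))
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
  p <- if (alternative == "greater") stats::pt(tval, df = n - 1, lower.tail = FALSE)
       else 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE)
  flagged_local <- which(sdv == 0)
  p[flagged_local] <- 1
  tmap <- array(0, brain$grid$shape); tmap[idx] <- tval
  pmap <- array(1, brain$grid$shape); pmap[idx] <- p
  structure(list(t = tmap, p = pmap, df = n - 1L, grid = brain$grid,
                 flagged = idx[flagged_local]),
            class = "group_stat_map")
}

#' Benjamini-Hochberg step-up rejection
#'
#' Rejects the hypotheses whose p-values survive the BH step-up rule at
#' level `q`: with sorted `p(1) <= ... <= p(m)`, find the largest `k` with
#' `p(k) <= k q / m` and reject the k smallest.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return logical rejection vector aligned with `p`.
#' @export
fdr_bh <- function(p, q) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  stats::p.adjust(p, method = "BH") <= q
}

## 6/18/26-connectivity neighbor offsets on a zero-padded grid.
neighbor_offsets <- function(shape_padded, connectivity) {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  norm1 <- abs(d$dx) + abs(d$dy) + abs(d$dz)
  d <- switch(as.character(connectivity),
              "6" = d[norm1 == 1, ],
              "18" = d[norm1 <= 2, ],
              "26" = d,
              stop("connectivity must be 6, 18 or 26"))
  d$dx + d$dy * shape_padded[1] + d$dz * shape_padded[1] * shape_padded[2]
}

#' Label connected components of a 3D binary array
#'
#' Flood-fill labeling under 6-, 18- or 26-connectivity.
#'
#' @param arr 3D 0/1 array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of the same shape; 0 for background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(arr, connectivity = 26) {
  shape <- dim(arr)
  sp <- shape + 2L
  pad <- array(0L, sp)
  pad[2:(sp[1] - 1), 2:(sp[2] - 1), 2:(sp[3] - 1)] <- arr
  offs <- neighbor_offsets(sp, connectivity)
  labels <- array(0L, sp)
  fg <- which(pad == 1L)
  current <- 0L
  queue <- integer(length(fg))
  for (v in fg) {
    if (labels[v] != 0L) next
    current <- current + 1L
    labels[v] <- current
    queue[1L] <- v
    head <- 1L; tail <- 1L
    while (head <= tail) {
      u <- queue[head]; head <- head + 1L
      for (nb in u + offs) {
        if (pad[nb] == 1L && labels[nb] == 0L) {
          labels[nb] <- current
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  labels[2:(sp[1] - 1), 2:(sp[2] - 1), 2:(sp[3] - 1), drop = FALSE]
}

#' Remove suprathreshold clusters below an extent threshold
#'
#' Connected components with fewer than `k_min` voxels are deleted; larger
#' clusters are retained intact. 26-connectivity matches common SPM-style
#' cluster labeling.
#'
#' @param mask a [binary_mask()].
#' @param k_min minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @return filtered [binary_mask()].
#' @export
cluster_extent_filter <- function(mask, k_min = 20, connectivity = 26) {
  if (k_min < 1) stop("k_min must be a positive integer")
  if (mask$n_voxels == 0L) return(mask)
  lab <- label_components(mask$data, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= k_min)
  binary_mask(array(lab %in% keep, dim(lab)), mask$grid)
}

#' Cluster table of a binary map
#'
#' @param mask a [binary_mask()].
#' @param stat optional 3D array used to locate each cluster's peak.
#' @param connectivity 6, 18 or 26.
#' @return data frame: `cluster`, `size_voxels`, peak voxel indices
#'   (0-based) and peak mm coordinates.
#' @export
cluster_table <- function(mask, stat = NULL, connectivity = 26) {
  lab <- label_components(mask$data, connectivity)
  ids <- sort(unique(lab[lab > 0]))
  if (is.null(stat)) stat <- mask$data
  rows <- lapply(ids, function(id) {
    vox <- which(lab == id)
    peak <- vox[which.max(stat[vox])]
    pidx <- arrayInd(peak, dim(lab)) - 1L
    pmm <- voxel_to_mm(as.integer(pidx), mask$grid)
    data.frame(cluster = id, size_voxels = length(vox),
               peak_i = pidx[1], peak_j = pidx[2], peak_k = pidx[3],
               peak_x_mm = pmm[1], peak_y_mm = pmm[2], peak_z_mm = pmm[3])
  })
  do.call(rbind, rows)
}

#' Build a binarized network template from a cohort
#'
#' Composition of the group template pipeline: per-subject seed-based
#' correlation and Fisher z, voxelwise one-sample t-test, Benjamini-Hochberg
#' FDR over in-brain voxels at level `q`, and cluster-extent filtering at
#' `k_min` voxels.
#'
#' @param cohort list of preprocessed [volume4d()] on a shared grid.
#' @param seed_center_mm mm coordinate of the seed (default Broca's area,
#'   MNI `[-57, 15, 24]`).
#' @param brain analysis [binary_mask()].
#' @param q FDR level (default 0.001).
#' @param k_min cluster extent threshold in voxels (default 20).
#' @param seed_radius_mm seed sphere radius (default 6 mm).
#' @param connectivity cluster connectivity (default 26).
#' @param alternative t-test sidedness, see [group_ttest()].
#' @return the template [binary_mask()], with attributes `stat_map` (the
#'   `group_stat_map`) and `cluster_table`.
#' @export
build_template <- function(cohort, seed_center_mm = c(-57, 15, 24), brain,
                           q = 0.001, k_min = 20, seed_radius_mm = 6,
                           connectivity = 26,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(cohort) == 0L) stop("cohort is empty")
  if (length(cohort) < 2L) stop("template construction needs at least 2 subjects")
  for (v in cohort) stop_grid_mismatch(v$grid, brain$grid, "cohort volumes and brain mask")
  seed <- make_sphere_roi(seed_center_mm, seed_radius_mm, brain$grid)
  seed <- binary_mask(seed$data * brain$data, brain$grid)
  if (seed$n_voxels == 0L)
    stop("seed sphere does not intersect the brain mask")
  zmaps <- lapply(cohort, seed_fc_map, seed = seed, brain = brain,
                  seed_center_mm = seed_center_mm)
  gs <- group_ttest(zmaps, brain, alternative = alternative)
  idx <- mask_indices(brain)
  rej <- fdr_bh(gs$p[idx], q)
  m <- array(0L, brain$grid$shape)
  m[idx[rej]] <- 1L
  template <- cluster_extent_filter(binary_mask(m, brain$grid), k_min,
                                    connectivity)
  if (template$n_voxels == 0L)
    stop(sprintf(paste0("template is empty after FDR (q = %g) and extent ",
                        "filtering (k_min = %d); consider relaxing q or k_min"),
                 q, k_min))
  attr(template, "stat_map") <- gs
  attr(template, "cluster_table") <- cluster_table(template, gs$t, connectivity)
  template
}
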