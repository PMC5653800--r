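test_that("seed_fc_map recovers perfect, inverted and degenerate correlations", {
  grid <- identity_grid(c(3, 3, 3))
  brain <- full_mask(grid)
  seed <- mask_from_indices(grid, 1)
  nt <- 30
  set.seed(7)
  s <- rnorm(nt)
  series <- matrix(rnorm(nt * 27, sd = 0.5), nt, 27)
  series[, 1] <- s        # the seed voxel
  series[, 2] <- s        # identical to the seed series
  series[, 3] <- -s       # negated
  series[, 4] <- 7        # zero variance
  vol <- volume_from_series(series, grid)
  fc <- seed_fc_map(vol, seed, brain)
  expect_equal(fc$r[2], 1, tolerance = 1e-12)
  expect_gt(fc$z[2], 8)                      # atanh(1 - 1e-7) ~ 8.4
  expect_equal(fc$r[3], -1, tolerance = 1e-12)
  expect_equal(fc$r[4], 0)
  expect_true(4 %in% fc$flagged)
  expect_error(seed_fc_map(vol, mask_from_indices(grid, 4), brain),
               "zero variance")
})

test_that("seed FC separates in-source from background voxels on a phantom", {
  ph <- tiny_phantom(seed = 11, noise_sd = 0.5)
  src <- ph$source_masks$A
  seed <- make_sphere_roi(c(-9, 9, 0), 3, ph$volume$grid)
  seed <- binary_mask(seed$data * src$data, seed$grid)
  fc <- seed_fc_map(ph$volume, seed, ph$brain)
  idx_in <- which(src$data == 1L)
  idx_out <- which(ph$brain$data == 1L & src$data == 0L &
                     ph$source_masks$B$data == 0L)
  expect_gt(mean(fc$r[idx_in]) - mean(fc$r[idx_out]), 0.3)
})

test_that("seed FC r is invariant to positive affine rescaling of the data", {
  ph <- tiny_phantom(seed = 12)
  seed <- make_sphere_roi(c(-9, 9, 0), 3, ph$volume$grid)
  fc1 <- seed_fc_map(ph$volume, seed, ph$brain)
  scaled <- volume4d(ph$volume$data * 3.7 + 11, ph$volume$grid,
                     ph$volume$tr_seconds)
  fc2 <- seed_fc_map(scaled, seed, ph$brain)
  expect_equal(fc1$r, fc2$r, tolerance = 1e-10)
})

test_that("group_ttest matches the direct t formula and flags degeneracy", {
  grid <- identity_grid(c(2, 2, 2))
  brain <- full_mask(grid)
  n <- 4
  set.seed(8)
  zs <- lapply(1:n, function(i) {
    z <- array(0, c(2, 2, 2))
    z[1] <- 0                              # all-zero voxel
    z[2] <- 1 + rnorm(1, sd = 1e-3)        # strong consistent effect
    z[3] <- c(-1, 1, -1, 1)[i]             # symmetric about 0
    z[4] <- rnorm(1)
    structure(list(z = z, grid = grid), class = "fc_map")
  })
  gs <- group_ttest(zs, brain, alternative = "two.sided")
  expect_equal(gs$df, 3L)
  expect_true(1 %in% gs$flagged)
  expect_equal(gs$p[1], 1)
  expect_lt(gs$p[2], 0.001)
  expect_equal(gs$t[3], 0)
  expect_equal(gs$p[3], 1)
  # direct formula oracle on the random voxel
  v <- vapply(zs, function(m) m$z[4], numeric(1))
  t_oracle <- mean(v) / (sd(v) / sqrt(n))
  expect_equal(gs$t[4], t_oracle, tolerance = 1e-12)
  expect_equal(gs$p[4], 2 * pt(abs(t_oracle), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # one-sided variant halves the upper-tail probability
  gs1 <- group_ttest(zs, brain, alternative = "greater")
  expect_equal(gs1$p[4], pt(t_oracle, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(group_ttest(zs[1], brain), "at least 2")
})

test_that("fdr_bh reproduces the textbook step-up example", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569,
         0.594, 0.696, 0.762, 0.94, 0.942, 0.975, 0.986)
  # step-up: largest k with p_(k) <= k q / m; p_(6) = 0.06 = 6 * 0.25 / 25
  # sits exactly on the boundary and is rejected (<=)
  rej <- fdr_bh(p, 0.25)
  expect_identical(which(rej), 1:6)
  expect_false(any(fdr_bh(rep(1, 10), 0.05)))
  expect_true(fdr_bh(0.025, 0.05))
  expect_error(fdr_bh(numeric(0), 0.05), "empty")
  expect_error(fdr_bh(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("fdr_bh matches the quadratic step-up oracle and is monotone in q", {
  set.seed(9)
  for (i in 1:50) {
    m <- sample(1:50, 1)
    p <- round(runif(m), 3)
    q <- runif(1, 0.01, 0.4)
    expect_identical(fdr_bh(p, q), bh_oracle(p, q))
    q2 <- min(q * 2, 0.99)
    expect_true(all(!fdr_bh(p, q) | fdr_bh(p, q2)))  # rejections grow with q
  }
})

test_that("cluster_extent_filter honors extent and connectivity", {
  grid <- identity_grid(c(10, 10, 10))
  m <- array(0L, c(10, 10, 10))
  m[1:19] <- 1L                           # 19-voxel line (26-connected)
  m[, 5, 5] <- 1L                         # a 10-voxel line
  m[5:9, 6, 5] <- 1L; m[5:9, 7, 5] <- 1L  # widen to reach 20 voxels
  mask <- binary_mask(m, grid)
  lab <- label_components(mask$data, 26)
  sizes <- sort(tabulate(lab), decreasing = TRUE)
  kept <- cluster_extent_filter(mask, k_min = 20, connectivity = 26)
  expect_equal(kept$n_voxels, sum(sizes[sizes >= 20]))
  expect_true(all(kept$data <= mask$data))
  # idempotence
  expect_identical(cluster_extent_filter(kept, 20, 26)$data, kept$data)
  # k_min = 1 is the identity
  expect_identical(cluster_extent_filter(mask, 1, 26)$data, mask$data)
})

test_that("diagonal neighbors merge under 26- but not 6-connectivity", {
  grid <- identity_grid(c(4, 4, 4))
  m <- array(0L, c(4, 4, 4))
  m[2, 2, 2] <- 1L; m[3, 3, 3] <- 1L
  mask <- binary_mask(m, grid)
  expect_equal(max(label_components(m, 6)), 2)
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(cluster_extent_filter(mask, 2, 6)$n_voxels, 0L)
  expect_equal(cluster_extent_filter(mask, 2, 26)$n_voxels, 2L)
})

test_that("label_components agrees with a brute-force flood fill", {
  # oracle: repeated neighbor expansion over an explicit voxel list
  flood_oracle <- function(arr, conn) {
    d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
    n1 <- abs(d$dx) + abs(d$dy) + abs(d$dz)
    d <- if (conn == 6) d[n1 == 1, ] else if (conn == 18) d[n1 <= 2, ] else d
    vox <- which(arr == 1L, arr.ind = TRUE)
    lab <- integer(nrow(vox))
    key <- function(v) paste(v, collapse = ",")
    index <- new.env()
    for (i in seq_len(nrow(vox))) assign(key(vox[i, ]), i, envir = index)
    cur <- 0L
    for (i in seq_len(nrow(vox))) {
      if (lab[i] != 0L) next
      cur <- cur + 1L
      stack <- i
      while (length(stack) > 0) {
        v <- stack[[1]]; stack <- stack[-1]
        if (lab[v] != 0L) next
        lab[v] <- cur
        for (r in seq_len(nrow(d))) {
          nb <- vox[v, ] + unlist(d[r, ])
          j <- mget(key(nb), envir = index, ifnotfound = list(NULL))[[1]]
          if (!is.null(j) && lab[j] == 0L) stack <- c(stack, j)
        }
      }
    }
    out <- array(0L, dim(arr)); out[arr == 1L] <- lab
    out
  }
  set.seed(10)
  for (conn in c(6, 18, 26)) {
    arr <- array(as.integer(runif(125) < 0.3), c(5, 5, 5))
    got <- label_components(arr, conn)
    want <- flood_oracle(arr, conn)
    # same partition: component count and co-membership
    expect_equal(max(got), max(want))
    fg <- which(arr == 1L)
    expect_true(all(outer(got[fg], got[fg], "==") ==
                      outer(want[fg], want[fg], "==")))
  }
})

test_that("build_template recovers a shared phantom source", {
  cohort <- make_cohort(5, rng_seed = 21,
                        config = phantom_config(
                          grid_shape = c(16, 16, 16), n_timepoints = 60,
                          sources = list(list(name = "A",
                                              centers_mm = matrix(c(-6, 6, 0), 1),
                                              radii_mm = 7, amplitude = 1)),
                          rng_seed = 21))
  vols <- lapply(cohort, `[[`, "volume")
  brain <- cohort[[1]]$brain
  tmpl <- build_template(vols, c(-6, 6, 0), brain, q = 0.001, k_min = 20)
  expect_gte(mask_dice(tmpl, cohort[[1]]$source_masks$A), 0.5)
  expect_error(build_template(vols[1], c(-6, 6, 0), brain), "at least 2")
})

test_that("pure-noise cohorts yield an empty-template error", {
  noise_cfg <- function(s) phantom_config(
    grid_shape = c(12, 12, 12), n_timepoints = 40,
    sources = list(list(name = "A", centers_mm = matrix(c(0, 0, 0), 1),
                        radii_mm = 5, amplitude = 1e-8)),
    noise_sd = 1, rng_seed = s)
  failures <- vapply(1:10, function(s) {
    cohort <- lapply(s * 10 + 1:4, function(ss) make_phantom(noise_cfg(ss)))
    vols <- lapply(cohort, `[[`, "volume")
    inherits(try(build_template(vols, c(0, 0, 0), cohort[[1]]$brain,
                                q = 0.001, k_min = 20), silent = TRUE),
             "try-error")
  }, logical(1))
  expect_gte(mean(failures), 0.95)
})
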