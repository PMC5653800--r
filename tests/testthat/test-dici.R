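# 3x3x3 toy masks shared by the worked examples: template 4 voxels,
# component covers 3 of them plus 2 voxels outside.
toy_fixture <- function() {
  grid <- identity_grid(c(3, 3, 3))
  brain <- full_mask(grid)
  template <- mask_from_indices(grid, c(1, 2, 3, 4))
  component <- mask_from_indices(grid, c(1, 2, 3, 10, 11))
  list(grid = grid, brain = brain, template = template, component = component)
}

test_that("binarize_zmap uses a strict threshold within the mask", {
  grid <- identity_grid(c(3, 3, 3))
  mask <- full_mask(grid)
  expect_equal(binarize_zmap(rep(0, 27), mask, 1.96)$n_voxels, 0L)
  z <- rep(0, 27); z[5] <- 1.96; z[6] <- 1.9600001
  b <- binarize_zmap(z, mask, 1.96)
  expect_equal(which(b$data == 1L), 6L)   # exactly-at-threshold excluded
  # out-of-mask voxels never enter
  half <- mask_from_indices(grid, 1:13)
  z2 <- rep(3, 27)
  expect_equal(binarize_zmap(z2[1:13], half, 1.96)$n_voxels, 13L)
})

test_that("suprathreshold fraction of a standard-normal map is the normal tail", {
  grid <- identity_grid(c(22, 22, 22))
  mask <- mask_from_indices(grid, 1:10000)
  set.seed(51)
  z <- rnorm(10000)
  frac <- binarize_zmap(z, mask, 1.96)$n_voxels / 10000
  expect_equal(frac, 0.025, tolerance = 0.2)  # 0.025 +/- 0.005
  expect_lt(abs(frac - 0.025), 0.005)
})

test_that("hit and false-alarm rates match brute-force counts on the toy", {
  f <- toy_fixture()
  expect_equal(hit_rate(f$component, f$template, f$brain), 0.75)
  expect_equal(false_alarm_rate(f$component, f$template, f$brain), 2 / 23)
  expect_equal(hit_rate(f$template, f$template, f$brain), 1)
  expect_equal(false_alarm_rate(f$template, f$template, f$brain), 0)
  disjoint <- mask_from_indices(f$grid, 20:22)
  expect_equal(hit_rate(disjoint, f$template, f$brain), 0)
  expect_equal(false_alarm_rate(f$brain, f$template, f$brain), 1)
  expect_error(hit_rate(f$component, mask_from_indices(f$grid, integer(0)),
                        f$brain), "empty")
  expect_error(false_alarm_rate(f$component, f$brain, f$brain), "whole brain")
})

test_that("rates equal a per-voxel triple-loop oracle on random 5x5x5 masks", {
  grid <- identity_grid(c(5, 5, 5))
  set.seed(52)
  for (rep in 1:200) {
    brain_arr <- array(as.integer(runif(125) < 0.8), c(5, 5, 5))
    tmpl_arr <- array(as.integer(runif(125) < 0.3), c(5, 5, 5)) * brain_arr
    comp_arr <- array(as.integer(runif(125) < 0.3), c(5, 5, 5))
    if (sum(tmpl_arr) == 0 || sum(brain_arr) == sum(tmpl_arr)) next
    hits <- fas <- n_t <- n_b <- 0L
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      if (brain_arr[i, j, k] == 0L) next
      if (tmpl_arr[i, j, k] == 1L) {
        n_t <- n_t + 1L
        if (comp_arr[i, j, k] == 1L) hits <- hits + 1L
      } else {
        n_b <- n_b + 1L
        if (comp_arr[i, j, k] == 1L) fas <- fas + 1L
      }
    }
    brain <- binary_mask(brain_arr, grid)
    expect_identical(round(hit_rate(binary_mask(comp_arr, grid),
                                    binary_mask(tmpl_arr, grid), brain) * n_t),
                     as.double(hits))
    expect_identical(round(false_alarm_rate(binary_mask(comp_arr, grid),
                                            binary_mask(tmpl_arr, grid),
                                            brain) * n_b),
                     as.double(fas))
  }
})

test_that("dici_score matches known quantiles and stays finite at the extremes", {
  # equal rates cancel exactly
  for (x in c(0.1, 0.3, 0.5, 0.9)) expect_equal(dici_score(x, x), 0)
  # +/- 1 sigma quantiles
  expect_equal(dici_score(0.8413, 0.1587), 2.00, tolerance = 0.005)
  # degenerate rates with the continuity correction stay finite and equal
  # the clipped closed form
  n_t <- 100; n_b <- 900
  eps <- c(1 / (2 * n_t), 1 / (2 * n_b))
  got <- dici_score(1, 0, eps)
  expect_true(is.finite(got))
  expect_equal(got, qnorm(1 - eps[1]) - qnorm(eps[2]), tolerance = 1e-12)
  expect_error(dici_score(1.2, 0.5), "\\[0, 1\\]")
  expect_error(dici_score(0.5, 0.5, 0.7), "clip_epsilon")
})

test_that("dici_score is strictly monotone in each rate", {
  grid_vals <- seq(0.05, 0.95, by = 0.05)
  for (far in grid_vals) {
    d <- vapply(grid_vals, dici_score, numeric(1), far = far)
    expect_true(all(diff(d) > 0))
  }
  for (hr in grid_vals) {
    d <- vapply(grid_vals, function(f) dici_score(hr, f), numeric(1))
    expect_true(all(diff(d) < 0))
  }
})

test_that("gof_score matches a hand-looped two-mean oracle", {
  f <- toy_fixture()
  expect_equal(gof_score(rep(2, 27), f$template, f$brain), 0)
  z <- ifelse(seq_len(27) %in% 1:4, 1, -1)
  expect_equal(gof_score(z, f$template, f$brain), 2)
  set.seed(53)
  z <- rnorm(27)
  s_in <- s_out <- 0; n_in <- n_out <- 0
  for (v in 1:27) {
    if (f$template$data[v] == 1L) { s_in <- s_in + z[v]; n_in <- n_in + 1 }
    else { s_out <- s_out + z[v]; n_out <- n_out + 1 }
  }
  expect_equal(gof_score(z, f$template, f$brain), s_in / n_in - s_out / n_out,
               tolerance = 1e-12)
  expect_equal(gof_score(z, f$template, f$brain, variant = "sum"),
               s_in - s_out, tolerance = 1e-12)
})

# Construct a component set directly from given in-mask z maps.
fake_component_set <- function(zmaps, mask) {
  structure(list(order = nrow(zmaps), spatial_zmaps = zmaps,
                 timecourses = matrix(0, 10, nrow(zmaps)), mask = mask,
                 rng_seed = 0L, converged = TRUE, iterations = 0L,
                 skewness = rep(1, nrow(zmaps)), vafs = rep(0, nrow(zmaps))),
            class = "component_set")
}

test_that("adaptive threshold stops at the first overlapping level", {
  grid <- identity_grid(c(4, 4, 4))
  brain <- full_mask(grid)
  template <- mask_from_indices(grid, 1:8)

  # overlap already at 1.96
  z1 <- rep(0, 64); z1[1:4] <- 3
  sc <- adaptive_score_all(list(fake_component_set(rbind(z1), brain)),
                           template, brain)
  expect_equal(sc$threshold_used, 1.96)
  expect_false(sc$expert_review_flag)

  # template voxels peak at z = 1.0: descent must stop at 0.96
  z2 <- rep(-0.5, 64); z2[1:4] <- 1.0; z2[30:34] <- 5  # high z only outside
  sc2 <- adaptive_score_all(list(fake_component_set(rbind(z2), brain)),
                            template, brain)
  expect_equal(sc2$threshold_used, 0.96)
  expect_false(sc2$expert_review_flag)
  expect_equal(sc2$descent$threshold, c(1.96, 1.76, 1.56, 1.36, 1.16, 0.96))
  expect_gt(sc2$scores$hit_rate[1], 0)

  # no overlap even at the red line: flagged, scored at 0.8
  z3 <- rep(-0.5, 64); z3[1:8] <- 0.5; z3[40:50] <- 4
  sc3 <- adaptive_score_all(list(fake_component_set(rbind(z3), brain)),
                            template, brain)
  expect_equal(sc3$threshold_used, 0.8)
  expect_true(sc3$expert_review_flag)
  expect_equal(sc3$scores$hit_rate, 0)

  # one shared threshold across orders: overlap in one order at 1.96 pins
  # every order's scores to 1.96
  sets <- list(fake_component_set(rbind(z3), brain),
               fake_component_set(rbind(z1, z3), brain))
  sc4 <- adaptive_score_all(sets, template, brain)
  expect_equal(unique(sc4$scores$threshold_z), 1.96)
})

test_that("selection takes the per-order and cross-order d' argmax with tie rules", {
  sc <- data.frame(order = c(5, 5, 5, 8, 8),
                   component_index = c(0L, 1L, 2L, 0L, 1L),
                   threshold_z = 1.96,
                   hit_rate = 0.5, false_alarm_rate = 0.1,
                   dici = c(0.5, 2.1, 1.0, 1.7, 0.3),
                   gof = c(0.1, 0.2, 0.3, 0.4, 0.5))
  sel <- select_component(sc, top_k = 3)
  expect_equal(sel$global_best$order, 5)
  expect_equal(sel$global_best$component_index, 1L)
  expect_equal(sel$per_order_candidate$dici, c(2.1, 1.7))
  expect_equal(sel$ranked_top_k$dici, c(2.1, 1.7, 1.0))

  # exact cross-order tie: lower order wins
  sc2 <- sc
  sc2$dici[4] <- 2.1
  expect_equal(select_component(sc2)$global_best$order, 5)

  # a dominated extra component never changes the global best
  sc3 <- rbind(sc, data.frame(order = 11, component_index = 0L,
                              threshold_z = 1.96, hit_rate = 0.4,
                              false_alarm_rate = 0.2, dici = 2.0, gof = 9))
  expect_equal(select_component(sc3)$global_best$dici, 2.1)
  expect_error(select_component(sc[0, ]), "no component scores")
})

test_that("an extreme-valued off-template component fools GOF but not d'", {
  grid <- identity_grid(c(6, 6, 6))
  brain <- full_mask(grid)
  template <- mask_from_indices(grid, 1:20)
  # true network: covers the template cleanly, nothing extreme
  z_true <- rep(0, 216); z_true[1:19] <- 2.5
  # distractor: moderate template coverage, plus extreme negative voxels
  # concentrated outside the template that inflate mean-GOF
  z_bad <- rep(0, 216); z_bad[1:8] <- 2.5; z_bad[100:140] <- -8
  cs <- fake_component_set(rbind(z_true, z_bad), brain)
  sc <- adaptive_score_all(list(cs), template, brain)
  gof_rank <- order(-sc$scores$gof)
  dici_rank <- order(-sc$scores$dici)
  expect_equal(gof_rank[1], 2L)   # GOF prefers the distractor
  expect_equal(dici_rank[1], 1L)  # d' does not
})

test_that("identify_coi wires scoring and selection end to end", {
  ph <- make_phantom(phantom_config(
    grid_shape = c(14, 14, 14), n_timepoints = 80,
    sources = list(
      list(name = "A", centers_mm = matrix(c(-8, 8, 0), 1), radii_mm = 7,
           amplitude = 1),
      list(name = "B", centers_mm = matrix(c(8, -8, 0), 1), radii_mm = 7,
           amplitude = 1)),
    noise_sd = 0.5, rng_seed = 54))
  sel <- identify_coi(ph$volume, ph$brain, ph$source_masks$A,
                      orders = c(4, 6), rng_seed = 54)
  expect_s3_class(sel, "selection_result")
  m <- selected_component_map(sel)
  expect_gte(mask_dice(m$mask, ph$source_masks$A), 0.5)
  expect_false(sel$expert_review_flag)
})
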