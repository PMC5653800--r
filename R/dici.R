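#' Binarize a standardized component map
#'
#' A voxel enters the mask iff it is inside `mask` and its z-value is
#' strictly greater than `threshold_z` (z > 1.96 corresponds to p < 0.05
#' one-tailed under the standard-normal calibration of the map).
#'
#' @param zmap 3D array or in-mask vector of standardized values.
#' @param mask analysis [binary_mask()].
#' @param threshold_z binarization threshold.
#' @return a [binary_mask()].
#' @export
binarize_zmap <- function(zmap, mask, threshold_z = 1.96) {
  idx <- mask_indices(mask)
  vals <- if (is.array(zmap) && length(dim(zmap)) == 3L) zmap[idx] else zmap
  if (length(vals) != length(idx))
    stop("zmap length does not match the mask")
  m <- array(0L, mask$grid$shape)
  m[idx[vals > threshold_z]] <- 1L
  binary_mask(m, mask$grid)
}

#' Hit rate of a binarized component against a template
#'
#' Fraction of template voxels covered by the component:
#' `|C n T| / |T|`, both restricted to the brain mask.
#'
#' @param component,template [binary_mask()] objects.
#' @param brain analysis [binary_mask()].
#' @return numeric in `[0, 1]`.
#' @export
hit_rate <- function(component, template, brain) {
  stop_grid_mismatch(component$grid, brain$grid, "component and brain")
  stop_grid_mismatch(template$grid, brain$grid, "template and brain")
  tmpl <- template$data == 1L & brain$data == 1L
  if (!any(tmpl)) stop("template is empty (within the brain mask)")
  sum(component$data == 1L & tmpl) / sum(tmpl)
}

#' False-alarm rate of a binarized component against a template
#'
#' Fraction of non-template brain voxels covered by the component:
#' `|C n (B \\ T)| / |B \\ T|`.
#'
#' @inheritParams hit_rate
#' @return numeric in `[0, 1]`.
#' @export
false_alarm_rate <- function(component, template, brain) {
  stop_grid_mismatch(component$grid, brain$grid, "component and brain")
  stop_grid_mismatch(template$grid, brain$grid, "template and brain")
  outside <- template$data == 0L & brain$data == 1L
  if (!any(outside))
    stop("template covers the whole brain mask; false-alarm rate undefined")
  sum(component$data == 1L & outside) / sum(outside)
}

#' Discriminability index (d-prime) from hit and false-alarm rates
#'
#' `d' = qnorm(HR) - qnorm(FAR)`: both rates are mapped through the inverse
#' cumulative distribution function of the standard Gaussian and subtracted.
#' Rates of exactly 0 or 1 have infinite quantiles, so rates are clipped
#' into `[clip_epsilon, 1 - clip_epsilon]` first — the standard d'
#' continuity correction. `clip_epsilon` may have length 2 to give HR and
#' FAR their own corrections (e.g. `1/(2 |T|)` and `1/(2 |B \\ T|)`).
#'
#' @param hr,far rates in `[0, 1]`.
#' @param clip_epsilon one or two values in `(0, 0.5)`.
#' @return finite numeric d'.
#' @export
dici_score <- function(hr, far, clip_epsilon = 1e-4) {
  if (any(!is.finite(c(hr, far))) || hr < 0 || hr > 1 || far < 0 || far > 1)
    stop("hr and far must be in [0, 1]")
  eps <- rep_len(clip_epsilon, 2L)
  if (any(eps <= 0 | eps >= 0.5)) stop("clip_epsilon must be in (0, 0.5)")
  hr <- min(max(hr, eps[1]), 1 - eps[1])
  far <- min(max(far, eps[2]), 1 - eps[2])
  stats::qnorm(hr) - stats::qnorm(far)
}

#' Goodness-of-fit of a component map against a template
#'
#' The traditional template-matching comparator: in-template minus
#' out-of-template z-value, as means (default, scale-free across template
#' sizes) or sums, over the brain mask.
#'
#' @param zmap 3D array or in-mask vector of standardized values.
#' @param template,brain [binary_mask()] objects (template a non-empty
#'   proper subset of brain).
#' @param variant `"mean"` or `"sum"`.
#' @return numeric GOF score.
#' @export
gof_score <- function(zmap, template, brain, variant = c("mean", "sum")) {
  variant <- match.arg(variant)
  stop_grid_mismatch(template$grid, brain$grid, "template and brain")
  idx <- mask_indices(brain)
  vals <- if (is.array(zmap) && length(dim(zmap)) == 3L) zmap[idx] else zmap
  if (length(vals) != length(idx)) stop("zmap length does not match the brain mask")
  inside <- template$data[idx] == 1L
  if (!any(inside)) stop("template is empty (within the brain mask)")
  if (all(inside)) stop("template covers the whole brain mask")
  agg <- if (variant == "mean") mean else sum
  agg(vals[inside]) - agg(vals[!inside])
}

## Score every component of one set at one threshold.
score_component_set <- function(cs, template, brain, threshold_z,
                                gof_variant = "mean") {
  stop_grid_mismatch(cs$mask$grid, brain$grid, "components and brain")
  n_t <- sum(template$data == 1L & brain$data == 1L)
  n_b <- sum(template$data == 0L & brain$data == 1L)
  eps <- c(1 / (2 * n_t), 1 / (2 * n_b))
  rows <- lapply(seq_len(cs$order), function(i) {
    comp <- binarize_zmap(cs$spatial_zmaps[i, ], cs$mask, threshold_z)
    hr <- hit_rate(comp, template, brain)
    far <- false_alarm_rate(comp, template, brain)
    data.frame(order = cs$order, component_index = i - 1L,
               threshold_z = threshold_z, hit_rate = hr,
               false_alarm_rate = far,
               dici = dici_score(hr, far, eps),
               gof = gof_score(cs$spatial_zmaps[i, ], template, brain,
                               gof_variant))
  })
  do.call(rbind, rows)
}

#' Threshold descent schedule
#'
#' Starts at 1.96 (p < 0.05), drops by 0.2, and is floored at the red line
#' of 0.8: `1.96, 1.76, ..., 0.96, 0.8`.
#'
#' @param initial,step,floor schedule parameters.
#' @export
threshold_schedule <- function(initial = 1.96, step = 0.2, floor = 0.8) {
  if (floor > initial) stop("floor must not exceed the initial threshold")
  if (step <= 0) stop("step must be positive")
  th <- seq(initial, floor, by = -step)
  if (th[length(th)] > floor) th <- c(th, floor)
  th
}

#' Score all components of all model orders under the adaptive threshold
#'
#' The binarization threshold starts at z > 1.96. If, at the current
#' threshold, at least one component of at least one model order overlaps
#' the template by at least one voxel (hit rate > 0), every component of
#' every order is scored at that threshold and the descent stops — a single
#' shared threshold keeps d' values comparable across orders, which the
#' cross-order argmax requires. Otherwise the threshold drops by 0.2 down
#' to the red line of 0.8; if even 0.8 yields no overlap anywhere, all
#' components are scored at 0.8 and `expert_review_flag` is set, signalling
#' that the data needs visual quality assessment.
#'
#' @param components_by_order list of `component_set`s (as returned by
#'   [multi_order_ica()]).
#' @param template,brain [binary_mask()] objects on the components' grid.
#' @param thresholds descent schedule (see [threshold_schedule()]).
#' @param gof_variant `"mean"` or `"sum"` for the GOF comparator column.
#' @return list of class `dici_scores`: `scores` (data frame: order,
#'   component_index, threshold_z, hit_rate, false_alarm_rate, dici, gof),
#'   `threshold_used`, `expert_review_flag`, `descent` (data frame of
#'   thresholds tried and whether any overlap was found).
#' @export
adaptive_score_all <- function(components_by_order, template, brain,
                               thresholds = threshold_schedule(),
                               gof_variant = "mean") {
  if (length(components_by_order) == 0L) stop("no component sets supplied")
  stop_grid_mismatch(template$grid, brain$grid, "template and brain")
  ## A component overlaps the template at threshold t iff its maximum
  ## z-value over template voxels exceeds t.
  tmpl_max <- unlist(lapply(components_by_order, function(cs) {
    stop_grid_mismatch(cs$mask$grid, brain$grid, "components and brain")
    inside <- template$data[mask_indices(cs$mask)] == 1L
    if (!any(inside)) return(rep(-Inf, cs$order))
    apply(cs$spatial_zmaps[, inside, drop = FALSE], 1, max)
  }))
  descent <- data.frame(threshold = numeric(0), any_overlap = logical(0))
  threshold_used <- thresholds[length(thresholds)]
  flag <- TRUE
  for (t in thresholds) {
    ok <- any(tmpl_max > t)
    descent <- rbind(descent, data.frame(threshold = t, any_overlap = ok))
    if (ok) { threshold_used <- t; flag <- FALSE; break }
  }
  scores <- do.call(rbind, lapply(components_by_order, score_component_set,
                                  template = template, brain = brain,
                                  threshold_z = threshold_used,
                                  gof_variant = gof_variant))
  rownames(scores) <- NULL
  structure(list(scores = scores, threshold_used = threshold_used,
                 expert_review_flag = flag, descent = descent),
            class = "dici_scores")
}

#' Select the component of interest across model orders
#'
#' Within each model order the component with the largest d' becomes that
#' order's candidate; the candidate with the largest d' across all orders is
#' the final component of interest, and its order is the optimal model
#' order. Exact ties are broken toward the lower order, then the lower
#' component index.
#'
#' @param scores a `dici_scores` object or its `scores` data frame.
#' @param top_k how many top-ranked components to report across all orders
#'   (`ranked_top_k`; e.g. 2 to inspect the runner-up).
#' @return list of class `selection_result`: `per_order_candidate` (data
#'   frame, one row per order), `global_best` (one row), `ranked_top_k`,
#'   `threshold_used`, `expert_review_flag`.
#' @export
select_component <- function(scores, top_k = 1) {
  flag <- FALSE
  threshold_used <- NA_real_
  if (inherits(scores, "dici_scores")) {
    flag <- scores$expert_review_flag
    threshold_used <- scores$threshold_used
    scores <- scores$scores
  }
  if (is.null(scores) || nrow(scores) == 0L) stop("no component scores supplied")
  ord <- order(-scores$dici, scores$order, scores$component_index)
  ranked <- scores[ord, , drop = FALSE]
  cand <- do.call(rbind, lapply(split(ranked, ranked$order), function(d) d[1, ]))
  cand <- cand[order(cand$order), , drop = FALSE]
  best <- ranked[1, , drop = FALSE]
  rownames(cand) <- rownames(best) <- NULL
  top <- utils::head(ranked, top_k)
  rownames(top) <- NULL
  structure(list(per_order_candidate = cand, global_best = best,
                 ranked_top_k = top, threshold_used = threshold_used,
                 expert_review_flag = flag),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  b <- x$global_best
  cat(sprintf(paste0("<selection_result> best component %d at order %d ",
                     "(d' = %.3f, HR = %.3f, FAR = %.3f, threshold %.2f%s)\n"),
              b$component_index, b$order, b$dici, b$hit_rate,
              b$false_alarm_rate,
              if (is.na(x$threshold_used)) b$threshold_z else x$threshold_used,
              if (x$expert_review_flag) ", EXPERT REVIEW" else ""))
  invisible(x)
}

#' Identify the component of interest in one subject
#'
#' End-to-end single-subject identification: multi-order spatial ICA,
#' adaptive d' scoring against the template, and cross-order selection.
#'
#' @param vol preprocessed [volume4d()].
#' @param mask analysis [binary_mask()].
#' @param template network template [binary_mask()] on the same grid
#'   (already warped to this subject's space).
#' @param orders model-order grid.
#' @param rng_seed integer seed.
#' @param top_k see [select_component()].
#' @param ... passed to [run_ica()].
#' @return a `selection_result` with extra fields `scores` (the
#'   `dici_scores`) and `components` (the per-order `component_set`s).
#' @export
identify_coi <- function(vol, mask, template, orders = c(20, 30, 40, 50, 60),
                         rng_seed, top_k = 1, ...) {
  sets <- multi_order_ica(vol, mask, orders, rng_seed, ...)
  sc <- adaptive_score_all(sets, template, mask)
  sel <- select_component(sc, top_k)
  sel$scores <- sc
  sel$components <- sets
  sel
}

#' Thresholded map of a selected component
#'
#' @param selection a `selection_result` from [identify_coi()].
#' @return list with the winning component's `zmap` (3D array), thresholded
#'   `mask` ([binary_mask()]), `order` and `component_index`.
#' @export
selected_component_map <- function(selection) {
  if (is.null(selection$components))
    stop("selection carries no component sets (was it produced by identify_coi?)")
  b <- selection$global_best
  cs <- selection$components[[as.character(b$order)]]
  vals <- cs$spatial_zmaps[b$component_index + 1L, ]
  zmap <- array(0, cs$mask$grid$shape)
  zmap[mask_indices(cs$mask)] <- vals
  list(zmap = zmap,
       mask = binarize_zmap(vals, cs$mask, selection$threshold_used),
       order = b$order, component_index = b$component_index)
}
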