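#' Classify one stimulation site against a binary map
#'
#' A site is `inside_map` when the voxel nearest to its mm coordinate is a
#' 1-voxel; otherwise `within_radius` when any 1-voxel center lies within
#' `radius_mm` of the site (3D Euclidean distance in mm); otherwise `miss`.
#' At `radius_mm = 0` the test reduces to nearest-voxel membership.
#'
#' @param coord_mm length-3 mm coordinate (must fall inside the grid).
#' @param map a [binary_mask()].
#' @param radius_mm extension radius in mm (default 10, i.e. the 1-cm
#'   clinical convention).
#' @return one of `"inside_map"`, `"within_radius"`, `"miss"`.
#' @export
classify_site <- function(coord_mm, map, radius_mm = 10) {
  if (radius_mm < 0) stop("radius_mm must be non-negative")
  idx <- mm_to_voxel(coord_mm, map$grid)
  if (attr(idx, "out_of_grid"))
    stop(sprintf("site (%s) falls outside the image grid",
                 paste(signif(coord_mm, 4), collapse = ", ")))
  if (map$data[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L] == 1L)
    return("inside_map")
  on <- mask_indices(map)
  if (length(on) == 0L) return("miss")
  ctr <- voxel_centers_mm(map$grid)[on, , drop = FALSE]
  d2 <- (ctr[, 1] - coord_mm[1])^2 + (ctr[, 2] - coord_mm[2])^2 +
    (ctr[, 3] - coord_mm[3])^2
  if (min(d2) <= radius_mm^2) "within_radius" else "miss"
}

#' Site-by-site sensitivity of a binary map
#'
#' Classifies every stimulation-positive site against the map and reports
#' exact sensitivity (`n_inside / n_positive`) and radius-extended
#' sensitivity (`(n_inside + n_within_radius) / n_positive`). Percentages
#' are rounded to one decimal. Negative (stimulation-silent) sites, if
#' present, are classified and counted but no headline specificity is
#' printed.
#'
#' @param sites data frame with columns `label`, `x_mm`, `y_mm`, `z_mm`,
#'   `positive` (see [read_sites_table()]).
#' @param map a [binary_mask()].
#' @param radius_mm extension radius in mm.
#' @return list of class `validation_report`: `per_site` (data frame with a
#'   `classification` column), `n_positive`, `n_inside`, `n_within_radius`
#'   (cumulative, includes `n_inside`), `sensitivity_exact`,
#'   `sensitivity_extended` (fractions), `sensitivity_exact_pct`,
#'   `sensitivity_extended_pct` (one decimal), `radius_mm`, and negative
#'   site counts when supplied.
#' @export
sensitivity_report <- function(sites, map, radius_mm = 10) {
  if (anyDuplicated(sites$label)) stop("site labels must be unique")
  if (!any(sites$positive)) stop("no stimulation-positive sites supplied")
  cls <- vapply(seq_len(nrow(sites)), function(i)
    classify_site(c(sites$x_mm[i], sites$y_mm[i], sites$z_mm[i]),
                  map, radius_mm), character(1))
  per_site <- cbind(sites, classification = cls)
  pos <- per_site[per_site$positive, ]
  n_pos <- nrow(pos)
  n_in <- sum(pos$classification == "inside_map")
  n_wr <- n_in + sum(pos$classification == "within_radius")
  neg <- per_site[!per_site$positive, ]
  structure(list(per_site = per_site,
                 n_positive = n_pos, n_inside = n_in, n_within_radius = n_wr,
                 sensitivity_exact = n_in / n_pos,
                 sensitivity_extended = n_wr / n_pos,
                 sensitivity_exact_pct = round(100 * n_in / n_pos, 1),
                 sensitivity_extended_pct = round(100 * n_wr / n_pos, 1),
                 radius_mm = radius_mm,
                 n_negative = nrow(neg),
                 n_negative_inside = sum(neg$classification == "inside_map")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d/%d positive sites inside the map (%.1f%%)\n",
              x$n_inside, x$n_positive, x$sensitivity_exact_pct))
  cat(sprintf("  %d/%d within %.3g mm (%.1f%%)\n", x$n_within_radius,
              x$n_positive, x$radius_mm, x$sensitivity_extended_pct))
  if (x$n_negative > 0)
    cat(sprintf("  %d negative sites supplied, %d inside the map\n",
                x$n_negative, x$n_negative_inside))
  invisible(x)
}

#' Agreement between two component-selection methods
#'
#' A subject counts as a match iff both methods selected the same optimal
#' model order and the same component index.
#'
#' @param table data frame with columns `subject`, `order_a`, `comp_a`,
#'   `order_b`, `comp_b` (one row per subject).
#' @return list: `agreement` (fraction), `agreement_pct` (one decimal),
#'   `n_match`, `n_subjects`, `matches` (named logical vector).
#' @export
method_agreement <- function(table) {
  if (nrow(table) == 0L) stop("empty comparison table")
  if (anyDuplicated(table$subject)) stop("duplicate subject rows")
  matches <- table$order_a == table$order_b & table$comp_a == table$comp_b
  names(matches) <- as.character(table$subject)
  list(agreement = mean(matches),
       agreement_pct = round(100 * mean(matches), 1),
       n_match = sum(matches), n_subjects = nrow(table), matches = matches)
}

#' Identification success rate
#'
#' @param n_success,n_total counts of successfully mapped and total
#'   subjects.
#' @return list: `rate` (fraction) and `rate_pct` (one decimal, e.g. 95.0
#'   for 19 of 20).
#' @export
success_rate <- function(n_success, n_total) {
  if (n_total < 1 || n_success < 0 || n_success > n_total)
    stop("need 0 <= n_success <= n_total with n_total >= 1")
  list(rate = n_success / n_total, rate_pct = round(100 * n_success / n_total, 1))
}

#' Write a validation report to disk
#'
#' Emits a human-readable text report and a machine-readable key-value
#' (JSON) file.
#'
#' @param report a `validation_report`.
#' @param text_path,json_path output paths (either may be `NULL`).
#' @export
write_validation_report <- function(report, text_path = NULL, json_path = NULL) {
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); print(report)
    cat("\nper-site classification:\n")
    utils::write.table(report$per_site, row.names = FALSE, quote = FALSE)
    sink(); close(con)
  }
  if (!is.null(json_path)) {
    keep <- report[c("n_positive", "n_inside", "n_within_radius",
                     "sensitivity_exact_pct", "sensitivity_extended_pct",
                     "radius_mm", "n_negative", "n_negative_inside")]
    jsonlite::write_json(keep, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
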