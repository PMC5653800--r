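#' Pipeline exit codes
#'
#' Fixed status codes returned by [run_pipeline()] (and the `dicimap`
#' command-line wrapper): `0` success, `2` configuration error, `3` data
#' error, `4` ICA convergence failure, `10` success with the expert-review
#' flag set (the adaptive threshold hit the red line without any
#' template overlap).
#'
#' @format Named integer vector.
#' @export
PIPELINE_EXIT_CODES <- c(ok = 0L, config_error = 2L, data_error = 3L,
                         convergence_error = 4L, expert_review = 10L)

config_error <- function(msg) stop(structure(
  class = c("dicimap_config_error", "error", "condition"),
  list(message = msg, call = NULL)))

default_run_config <- function() {
  list(rng_seed = NULL, out_dir = ".",
       paths = list(),
       seed_center_mm = c(-57, 15, 24), seed_radius_mm = 6,
       orders = c(20, 30, 40, 50, 60),
       threshold_initial = 1.96, threshold_step = 0.2, threshold_floor = 0.8,
       q = 0.001, k_min = 20, connectivity = 26,
       radius_mm = 10, top_k = 1,
       n_discard = 10, low_hz = 0.01, high_hz = 0.08, fwhm_mm = NULL,
       simulate = list())
}

validate_run_config <- function(config, stages) {
  if (is.null(config$rng_seed)) config_error("rng_seed is required")
  if (config$threshold_floor > config$threshold_initial)
    config_error("threshold_floor must not exceed threshold_initial")
  if (config$threshold_step <= 0) config_error("threshold_step must be positive")
  needs <- list(preprocess = "volume", ica = "volume", identify = "volume",
                validate = "sites")
  for (st in intersect(stages, names(needs))) {
    for (key in needs[[st]]) {
      p <- config$paths[[key]]
      supplied_by_sim <- "simulate" %in% stages && key %in% c("volume", "brain_mask")
      if (is.null(p) && !supplied_by_sim)
        config_error(sprintf("stage '%s' requires paths$%s", st, key))
      if (!is.null(p) && !file.exists(p))
        config_error(sprintf("paths$%s does not exist: %s", key, p))
    }
  }
  if ("identify" %in% stages && !("simulate" %in% stages) &&
      (is.null(config$paths$template) || !file.exists(config$paths$template)))
    config_error("stage 'identify' requires an existing paths$template")
  if ("template" %in% stages && is.null(config$paths$cohort_manifest))
    config_error("stage 'template' requires paths$cohort_manifest")
  invisible(TRUE)
}

#' Read a pipeline configuration file
#'
#' YAML key/value file mirroring the fields of the default configuration
#' (seed coordinates, model-order grid, thresholds, q, k_min, radius,
#' rng_seed, paths, ...). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return configuration list merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L)
    config_error(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  utils::modifyList(base, user)
}

write_provenance <- function(config, out_dir, artifacts) {
  tmp <- tempfile()
  saveRDS(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(config_md5 = hash, rng_seed = config$rng_seed,
         package_version = as.character(utils::packageVersion("dicimap")),
         r_version = R.version.string,
         artifacts = as.list(artifacts)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the identification pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (language
#' phantom), `preprocess` (discard/detrend/band-pass/smooth plus motion
#' screening), `template` (group template from a cohort manifest), `ica`
#' (multi-order decomposition, serialized), `identify` (adaptive d' scoring
#' and cross-order selection), `validate` (stimulation-site sensitivity).
#' Artifacts are written under `config$out_dir` together with a provenance
#' sidecar (config hash, seed, versions).
#'
#' @param config configuration list (see [read_run_config()]) or a YAML
#'   path.
#' @param stages character vector of stages to run.
#' @return list with `status` (see [PIPELINE_EXIT_CODES]), `artifacts`
#'   (named paths), and in-memory results per stage.
#' @export
run_pipeline <- function(config, stages = c("simulate", "identify", "validate")) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- utils::modifyList(default_run_config(), config)
  known <- c("simulate", "preprocess", "template", "ica", "identify", "validate")
  stages <- known[known %in% stages]
  result <- list(status = PIPELINE_EXIT_CODES[["ok"]], artifacts = character(0))
  ok <- tryCatch({
    validate_run_config(config, stages)
    TRUE
  }, dicimap_config_error = function(e) {
    result$status <<- PIPELINE_EXIT_CODES[["config_error"]]
    result$error <<- conditionMessage(e)
    FALSE
  })
  if (!ok) return(result)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage) {
    switch(stage,
      simulate = {
        ph <- make_language_phantom(config$simulate, rng_seed = config$rng_seed)
        paths <- write_phantom(ph, file.path(out_dir, "phantom"))
        state$volume <- ph$volume; state$brain <- ph$brain
        state$template <- ph$template
        result$artifacts <<- c(result$artifacts, paths)
        result$phantom <<- ph
      },
      preprocess = {
        vol <- state$volume %||% read_volume(config$paths$volume)
        brain <- state$brain %||% as_mask(read_volume(config$paths$brain_mask))
        if (!is.null(config$paths$motion)) {
          scr <- screen_motion(read_motion_trace(config$paths$motion))
          result$motion_screen <<- scr
          if (!scr$pass)
            stop(sprintf("subject fails motion screening at frames %s",
                         paste(scr$offending_frames, collapse = ", ")))
        }
        vol <- preprocess_volume(vol, brain, config$n_discard, config$low_hz,
                                 config$high_hz, config$fwhm_mm)
        p <- file.path(out_dir, "preprocessed.nii.gz")
        write_volume(vol, p)
        state$volume <- vol; state$brain <- brain
        result$artifacts <<- c(result$artifacts, preprocessed = p)
      },
      template = {
        manifest <- readLines(config$paths$cohort_manifest)
        manifest <- manifest[nzchar(trimws(manifest))]
        cohort <- lapply(manifest, read_volume)
        brain <- state$brain %||% as_mask(read_volume(config$paths$brain_mask))
        tmpl <- build_template(cohort, config$seed_center_mm, brain,
                               q = config$q, k_min = config$k_min,
                               seed_radius_mm = config$seed_radius_mm,
                               connectivity = config$connectivity)
        p <- file.path(out_dir, "template.nii.gz")
        write_volume(tmpl, p)
        tp <- file.path(out_dir, "template_clusters.txt")
        utils::write.table(attr(tmpl, "cluster_table"), tp, row.names = FALSE,
                           quote = FALSE)
        state$template <- tmpl
        result$artifacts <<- c(result$artifacts, template = p,
                               template_clusters = tp)
        result$template <<- tmpl
      },
      ica = {
        vol <- state$volume %||% read_volume(config$paths$volume)
        brain <- state$brain %||% as_mask(read_volume(config$paths$brain_mask))
        sets <- multi_order_ica(vol, brain, config$orders, config$rng_seed)
        for (k in names(sets))
          write_component_set(sets[[k]],
                              file.path(out_dir, sprintf("components_order%s.nii.gz", k)),
                              file.path(out_dir, sprintf("components_order%s.txt", k)))
        state$components <- sets
        result$components <<- sets
      },
      identify = {
        vol <- state$volume %||% read_volume(config$paths$volume)
        brain <- state$brain %||% as_mask(read_volume(config$paths$brain_mask))
        tmpl <- state$template %||% as_mask(read_volume(config$paths$template))
        sets <- state$components %||%
          multi_order_ica(vol, brain, config$orders, config$rng_seed)
        sc <- adaptive_score_all(sets, tmpl, brain,
                                 thresholds = threshold_schedule(
                                   config$threshold_initial,
                                   config$threshold_step,
                                   config$threshold_floor))
        sel <- select_component(sc, config$top_k)
        sel$scores <- sc; sel$components <- sets
        sp <- file.path(out_dir, "component_scores.txt")
        utils::write.table(format(sc$scores, digits = 6), sp,
                           row.names = FALSE, quote = FALSE)
        win <- selected_component_map(sel)
        write_volume(win$zmap, file.path(out_dir, "coi_zmap.nii.gz"),
                     grid = brain$grid)
        write_volume(win$mask, file.path(out_dir, "coi_mask.nii.gz"))
        lg <- file.path(out_dir, "identify_log.txt")
        con <- file(lg, "w")
        writeLines(c(sprintf("threshold_used %.2f", sc$threshold_used),
                     sprintf("expert_review_flag %s", sc$expert_review_flag),
                     "threshold descent:",
                     sprintf("  z > %.2f overlap=%s", sc$descent$threshold,
                             sc$descent$any_overlap),
                     sprintf("selected order %d component %d dici %.6f",
                             sel$global_best$order,
                             sel$global_best$component_index,
                             sel$global_best$dici)), con)
        close(con)
        state$coi_mask <- win$mask
        result$selection <<- sel
        result$artifacts <<- c(result$artifacts, scores = sp, identify_log = lg,
                               coi_zmap = file.path(out_dir, "coi_zmap.nii.gz"),
                               coi_mask = file.path(out_dir, "coi_mask.nii.gz"))
        if (sel$expert_review_flag)
          result$status <<- PIPELINE_EXIT_CODES[["expert_review"]]
      },
      validate = {
        sites <- read_sites_table(config$paths$sites)
        map <- state$coi_mask %||% as_mask(read_volume(config$paths$map))
        rep <- sensitivity_report(sites, map, config$radius_mm)
        write_validation_report(rep,
                                text_path = file.path(out_dir, "validation.txt"),
                                json_path = file.path(out_dir, "validation.json"))
        result$validation <<- rep
        result$artifacts <<- c(result$artifacts,
                               validation = file.path(out_dir, "validation.txt"),
                               validation_json = file.path(out_dir, "validation.json"))
      })
  }

  for (stage in stages) {
    err <- tryCatch({ run_stage(stage); NULL }, error = function(e) e)
    if (!is.null(err)) {
      msg <- conditionMessage(err)
      result$status <- if (grepl("converge", msg, fixed = TRUE))
        PIPELINE_EXIT_CODES[["convergence_error"]]
      else PIPELINE_EXIT_CODES[["data_error"]]
      result$error <- sprintf("stage '%s': %s", stage, msg)
      return(result)
    }
  }
  write_provenance(config, out_dir, result$artifacts)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Coerce a 3D volume read from disk into a binary mask.
as_mask <- function(vol3d) {
  if (is_binary_mask(vol3d)) return(vol3d)
  binary_mask(vol3d$data != 0, vol3d$grid)
}
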