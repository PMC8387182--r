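# End-to-end orchestration: phantom -> acquisition -> reconstruction ->
# filtering -> segmentation -> metrology -> validation, with intermediates
# written in standard formats and a JSON-lines stage log.

PIPELINE_SECTIONS <- c("phantom", "acquisition", "filter", "segment",
                       "measure", "stats", "seed", "out_dir")

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Unknown top-level keys are
#' rejected. Each section takes the arguments of the corresponding
#' constructor: [phantom_spec()], [acquisition_config()],
#' [diffusion_config()], [levelset_config()].
#'
#' @param phantom,acquisition,filter,segment named lists of overrides.
#' @param measure named list; supports `faces` (default both).
#' @param stats named list; supports `n_models` and `long_range` for the
#'   replication study run by [run_pipeline()] when requested.
#' @param seed global seed.
#' @param out_dir output directory for intermediates and reports.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = list(), acquisition = list(),
                            filter = list(), segment = list(),
                            measure = list(), stats = list(),
                            seed = 1L, out_dir = tempfile("echoasd_"), ...) {
  extra <- list(...)
  if (length(extra) > 0)
    config_error("unknown configuration keys: %s",
                 paste(names(extra), collapse = ", "))
  cfg <- list(phantom = phantom, acquisition = acquisition, filter = filter,
              segment = segment, measure = measure, stats = stats,
              seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_SECTIONS)
  if (length(unknown) > 0)
    config_error("unknown configuration keys: %s",
                 paste(unknown, collapse = ", "))
  check_args <- function(given, ctor, label) {
    bad <- setdiff(names(given), names(formals(ctor)))
    if (length(bad) > 0)
      config_error("unknown %s keys: %s", label, paste(bad, collapse = ", "))
  }
  check_args(cfg$phantom, phantom_spec, "phantom")
  check_args(cfg$acquisition, acquisition_config, "acquisition")
  check_args(cfg$filter, diffusion_config, "filter")
  check_args(cfg$segment, levelset_config, "segment")
  invisible(cfg)
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file with the [pipeline_config()] sections.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the virtual measurement pipeline end to end
#'
#' Executes phantom generation, TTO acquisition, scan conversion, multiscale
#' despeckling, FCM + level-set segmentation, rim extraction and defect
#' metrology on both atrial faces, and the real-vs-virtual validation.
#' All intermediates are written under `config$out_dir` (slice stack, volumes
#' as NRRD, cavity surface as PLY, `metrics.csv`, `validation.json`) together
#' with a `log.jsonl` of per-stage parameters and timings.
#'
#' @param config a [pipeline_config()].
#' @return list with `metrics` (data.frame), `validation` (data.frame),
#'   `paths` (named file list) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_path <- file.path(out, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  logs <- list()
  log_stage <- function(stage, params, t0) {
    entry <- list(stage = stage, params = params,
                  elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
        file = log_path, append = TRUE, sep = "")
    logs[[length(logs) + 1L]] <<- entry
  }
  run_stage <- function(stage, params, fun) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fun(), error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s (artifacts kept in %s)",
                stage, conditionMessage(e), out),
        class = class(e)))
    })
    log_stage(stage, params, t0)
    res
  }

  spec <- do.call(phantom_spec, config$phantom)
  acq_args <- config$acquisition
  if (is.null(acq_args$slice_width)) acq_args$slice_width <- spec$grid_shape[1]
  if (is.null(acq_args$slice_depth)) acq_args$slice_depth <- spec$grid_shape[3]
  if (is.null(acq_args$seed)) acq_args$seed <- config$seed
  acq <- do.call(acquisition_config, acq_args)
  filter_cfg <- do.call(diffusion_config, config$filter)
  seg_cfg <- do.call(levelset_config, config$segment)
  faces <- config$measure$faces %||% c("left_atrial", "right_atrial")

  ph <- run_stage("phantom", unclass(spec), function() generate_phantom(spec))
  write_volume(file.path(out, "phantom.nrrd"), ph$volume)
  write_volume(file.path(out, "labels.nrrd"), ph$labels)

  stack <- run_stage("acquire", unclass(acq),
                     function() simulate_tto(ph$volume, acq))
  write_slice_stack(file.path(out, "slices"), stack)
  log_stage("manifest", list(n_slices = dim(stack$slices)[3],
                             angular_step = acq$angular_step),
            as.numeric(Sys.time()))

  vol <- run_stage("reconstruct", list(step = acq$angular_step),
                   function() scan_convert(stack))
  write_volume(file.path(out, "reconstructed.nrrd"), vol)

  filt <- run_stage("filter", unclass(filter_cfg),
                    function() multiscale_filter(vol, filter_cfg))
  write_volume(file.path(out, "filtered.nrrd"),
               quantize_volume(filt, acq$gray_levels))

  seg <- run_stage("segment", unclass(seg_cfg),
                   function() segment_volume(filt, seg_cfg))
  write_volume(file.path(out, "mask.nrrd"),
               cartesian_volume(array(as.numeric(seg$mask), dim(vol)),
                                vol_spacing(vol)))
  mesh <- tryCatch(marching_cubes(seg$mask, spacing = vol_spacing(vol)),
                   error = function(e) NULL)
  if (!is.null(mesh)) write_mesh(file.path(out, "cavity.ply"), mesh)

  plane <- phantom_septum_plane(spec)
  truth <- phantom_true_metrics(spec)
  metrics <- run_stage("measure", list(faces = faces), function() {
    do.call(rbind, lapply(faces, function(face) {
      rim <- extract_rim(seg$mask, plane, face, spacing = vol_spacing(vol))
      if (!isTRUE(rim$found))
        return(data.frame(face = face, found = FALSE,
                          long_diameter = NA_real_, short_diameter = NA_real_,
                          area = NA_real_))
      m <- defect_metrics(rim)
      data.frame(face = face, found = TRUE, long_diameter = m$long_diameter,
                 short_diameter = m$short_diameter, area = m$area)
    }))
  })
  metrics$true_long <- truth$long_diameter
  metrics$true_short <- truth$short_diameter
  metrics$true_area <- truth$area
  utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)

  validation <- run_stage("validate", list(), function() {
    ok <- metrics[metrics$found, , drop = FALSE]
    if (nrow(ok) == 0) return(data.frame())
    data.frame(face = ok$face,
               err_long = abs(ok$long_diameter - ok$true_long) / ok$true_long,
               err_short = abs(ok$short_diameter - ok$true_short) /
                 ok$true_short,
               err_area = abs(ok$area - ok$true_area) / ok$true_area)
  })
  jsonlite::write_json(validation, file.path(out, "validation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  list(metrics = metrics, validation = validation,
       paths = list(out_dir = out,
                    metrics = file.path(out, "metrics.csv"),
                    validation = file.path(out, "validation.json"),
                    log = log_path),
       log = logs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
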