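#' Pipeline run configuration
#'
#' Validated configuration for [run_full_pipeline()].  Unknown keys are
#' rejected.
#'
#' @param dataset A `vt_cohort` (e.g. from [phantom_cohort()]); pipelines
#'   over on-disk data assemble the same structure first.
#' @param output_dir Directory for atlases, reports and provenance.
#' @param planes Planes to process (default: all in the dataset).
#' @param spacing B-spline control spacing (pixels).
#' @param kernel A [kernel_config()].
#' @param tau_spacing Atlas time step (seconds; default the kernel window).
#' @param fold_seed Seed for validation fold pairing.
#' @param n_bins Histogram bins.
#' @param reg_maxit,affine_maxit Optimizer iteration caps.
#' @param validate Run the four-fold cross-validation stage.
#' @param verbose Progress messages.
#' @param ... Rejected; catches misspelled keys.
#' @return List of class `vt_run_config`.
#' @export
run_config <- function(dataset, output_dir = NULL, planes = NULL,
                       spacing = 16, kernel = kernel_config(),
                       tau_spacing = NULL, fold_seed = 1L, n_bins = 256L,
                       reg_maxit = 40L, affine_maxit = 40L,
                       validate = TRUE, verbose = FALSE, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "))
  stopifnot(inherits(dataset, "vt_cohort"), inherits(kernel,
                                                     "vt_kernel_config"))
  structure(list(dataset = dataset, output_dir = output_dir,
                 planes = planes, spacing = spacing, kernel = kernel,
                 tau_spacing = if (is.null(tau_spacing)) kernel$window
                               else tau_spacing,
                 fold_seed = fold_seed, n_bins = n_bins,
                 reg_maxit = reg_maxit, affine_maxit = affine_maxit,
                 validate = validate, verbose = verbose),
            class = "vt_run_config")
}

#' Run the full atlas pipeline
#'
#' Executes, on the whole cohort: reference-space construction per plane;
#' per-frame affine normalization of every dynamic series; reference
#' durations and piecewise alignment; atlas synthesis per CV and plane on
#' a shared time grid; and (optionally) the four-fold cross-validated
#' similarity evaluation.  When `output_dir` is set, atlases, the report
#' CSV and a provenance JSON (configuration, input manifest, config hash)
#' are written there.
#'
#' @param config A [run_config()].
#' @return List of class `vt_pipeline_result`: `reference` (per plane),
#'   `durations`, `atlases` (per CV), `report` (or `NULL`), `provenance`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "vt_run_config"))
  ds <- config$dataset
  say <- function(...) if (config$verbose) message(...)
  planes <- config$planes
  if (is.null(planes)) planes <- names(ds$silence[[1]])
  cvs <- sort(unique(ds$annotations$cv))
  fps <- ds$series[[1]][[1]][[1]]$fps
  sps <- ds$speakers$speaker_id
  stage <- "reference"
  result <- tryCatch({
    refs <- lapply(setNames(planes, planes), function(pl) {
      say("reference space, plane ", pl)
      build_reference_space(
        lapply(setNames(sps, sps), function(sp) ds$silence[[sp]][[pl]]),
        plane = pl, spacing = config$spacing, n_bins = config$n_bins,
        reg_maxit = config$reg_maxit)
    })
    stage <- "alignment"
    durations <- compute_reference_durations(ds$annotations, cvs = cvs)
    atlases <- lapply(setNames(cvs, cvs), function(cv) {
      rd <- duration_row(durations, cv)
      tau_grid <- seq(0, rd$cv_frames / fps, by = config$tau_spacing)
      gs_by_plane <- lapply(setNames(planes, planes), function(pl) {
        aligned <- lapply(sps, function(sp) {
          ser <- ds$series[[sp]][[cv]][[pl]]
          ann <- lookup_annotation(ds$annotations, sp, cv, pl)
          ns <- normalize_series(ser, refs[[pl]],
                                 max_iter = config$affine_maxit)
          piecewise_align(ns, ann, durations)
        })
        pool_global_series(aligned, cv_label = cv, plane = pl)
      })
      say("atlas /", cv, "/")
      build_atlas(gs_by_plane, tau_grid = tau_grid, config = config$kernel)
    })
    stage <- "validation"
    report <- NULL
    if (config$validate)
      report <- run_validation(ds, validation_config(
        seed = config$fold_seed, spacing = config$spacing,
        kernel = config$kernel, tau_spacing = config$tau_spacing,
        planes = planes, n_bins = config$n_bins,
        reg_maxit = config$reg_maxit, affine_maxit = config$affine_maxit,
        verbose = config$verbose))
    list(reference = refs, durations = durations, atlases = atlases,
         report = report)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  cfg_public <- unclass(config)
  cfg_public$dataset <- NULL
  cfg_public$kernel <- unclass(cfg_public$kernel)
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_public, tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  provenance <- list(
    config = cfg_public,
    config_hash = unname(tools::md5sum(tf)),
    input_manifest = list(speakers = sps, cvs = cvs, planes = planes,
                          fps = fps, size = dim(ds$silence[[1]][[1]])[1],
                          dataset_params = ds$params),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("vtatlas")))
  unlink(tf)
  result$provenance <- provenance
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (cv in names(result$atlases))
      write_atlas(result$atlases[[cv]], file.path(config$output_dir, cv))
    if (!is.null(result$report))
      write.csv(result$report$report,
                file.path(config$output_dir, "similarity_report.csv"),
                row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(config$output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(result, class = "vt_pipeline_result")
}

#' @export
print.vt_pipeline_result <- function(x, ...) {
  cat(sprintf("<vt_pipeline_result> %d atlases, %d planes%s\n",
              length(x$atlases), length(x$reference),
              if (is.null(x$report)) "" else ", with validation report"))
  invisible(x)
}
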