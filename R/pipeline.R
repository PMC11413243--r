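#' Pipeline configuration
#'
#' All numeric thresholds of the analysis chain in one flat, serialisable
#' object: the smoothing parameters, the dose handling (the 10 micromolar
#' dose is dropped before scoring by default), the robust-Z convention, the
#' tiered hit-selection cutoffs and the secondary-validation rule.  The
#' object round-trips unchanged through [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param ... overrides of the defaults listed below.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # spatial smoothing
    span = 0.75, degree = 1, toxic_exclusion_fraction = 0.5,
    log_domain = TRUE, min_fit_wells = 30, center = "median",
    fit_wells = "compound",
    # dose handling and scoring
    retained_doses = c(0.1, 1), consistency_constant = 1,
    pool_doses = FALSE,
    # hit selection
    primary_dose = 1, low_dose = 0.1,
    cytotoxic_threshold = -2, proliferative_threshold = 2,
    line_fraction = 0.5, control_threshold = -2, control_filter = TRUE,
    # secondary validation
    secondary_dose = 10, death_threshold = 0.5, min_lines = 3,
    total_lines = 4,
    # QC
    cv_method = "per_plate",
    min_target_occurrence = 2
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown pipeline option(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(all(vapply(cfg[c("primary_dose", "low_dose", "cytotoxic_threshold",
                             "proliferative_threshold", "line_fraction",
                             "control_threshold", "death_threshold")],
                       is.finite, TRUE)))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.smoothing_from <- function(config) {
  smoothing_config(span = config$span, degree = config$degree,
                   toxic_exclusion_fraction = config$toxic_exclusion_fraction,
                   log_domain = config$log_domain,
                   min_fit_wells = config$min_fit_wells,
                   center = config$center, fit_wells = config$fit_wells)
}

#' Run the full screen analysis pipeline
#'
#' Chains the stages in the screen's order: structural validation, loess
#' spatial correction with toxic-well exclusion, per-plate DMSO-median
#' normalisation, viability binning, removal of the non-specific top dose,
#' per-line robust Z-scoring, hit calling, tiered hit selection against the
#' counter-screen, target aggregation (when annotations are supplied) and
#' control QC.  When `output_dir` is given, each stage's table is written as
#' CSV together with a JSON run manifest, and reruns with identical inputs
#' and configuration produce byte-identical files.
#'
#' @param dataset a `well_data` data frame of raw counts, or a `screen_sim`
#'   (its wells, annotations and panel are used).
#' @param panel a [cell_line_panel()].
#' @param annotations optional compound annotation table (`compound_id`,
#'   `target`, `pathway`, ...).
#' @param config a [pipeline_config()].
#' @param layout plate layout used for validation.
#' @param output_dir optional directory for the output bundle.
#' @return An object of class `screen_run`: list with `normalized` (the
#'   dataset after normalisation and binning), `scores` (the
#'   `score_matrix`), `hit_calls`, `hits` (the `hit_selection`), `targets`
#'   (aggregated target table or `NULL`), `qc` (the `screen_qc`),
#'   `validation` (structural report) and `manifest`.
#' @export
run_screen_pipeline <- function(dataset, panel = cell_line_panel(),
                                annotations = NULL,
                                config = pipeline_config(),
                                layout = default_plate_layout(),
                                output_dir = NULL) {
  if (inherits(dataset, "screen_sim")) {
    if (is.null(annotations)) annotations <- dataset$annotations
    panel <- dataset$config$panel
    layout <- dataset$config$layout
    dataset <- dataset$wells
  }
  validation <- validate_dataset(dataset, layout, panel)

  normalized <- normalize_screen(dataset, .smoothing_from(config))
  scores <- score_screen(normalized, retained_doses = config$retained_doses,
                         consistency_constant = config$consistency_constant,
                         pool_doses = config$pool_doses)
  hit_calls <- call_hits(scores, config$cytotoxic_threshold,
                         config$proliferative_threshold)
  hits <- select_hits(scores, panel,
                      dose = config$primary_dose, low_dose = config$low_dose,
                      cytotoxic_threshold = config$cytotoxic_threshold,
                      line_fraction = config$line_fraction,
                      control_threshold = config$control_threshold,
                      control_filter = config$control_filter)
  targets <- NULL
  if (!is.null(annotations) && nrow(hits$secondary))
    targets <- aggregate_targets(hits$secondary$compound_id, annotations,
                                 min_occurrence = config$min_target_occurrence)
  qc <- control_summary(normalized, cv_method = config$cv_method)

  cfg_file <- tempfile(fileext = ".yaml")
  write_pipeline_config(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("qhtscreen")),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_wells = nrow(dataset), n_plates = length(unique(dataset$plate_id)),
    n_cell_lines = length(unique(dataset$cell_line)),
    n_validation_issues = nrow(validation))
  unlink(cfg_file)

  run <- structure(list(normalized = normalized, scores = scores,
                        hit_calls = hit_calls, hits = hits, targets = targets,
                        qc = qc, validation = validation, manifest = manifest),
                   class = "screen_run")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(output_dir, f)
    write_screen_csv(normalized, fp("wells_normalized.csv"))
    write_scores_csv(scores, fp("robust_z_scores.csv"))
    utils::write.csv(hits$table, fp("hit_selection.csv"), row.names = FALSE,
                     na = "")
    utils::write.csv(hits$secondary, fp("secondary_candidates.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(targets))
      utils::write.csv(targets, fp("target_frequencies.csv"),
                       row.names = FALSE, na = "")
    utils::write.csv(as.data.frame(qc), fp("qc_summary.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.screen_run <- function(x, ...) {
  cat("Screen analysis run:", x$manifest$n_wells, "wells,",
      x$manifest$n_plates, "plates,", x$manifest$n_cell_lines,
      "cell lines\n")
  if (nrow(x$validation))
    cat("  structural issues:", nrow(x$validation), "\n")
  print(x$hits)
  invisible(x)
}
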