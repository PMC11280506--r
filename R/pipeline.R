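# High-level runners tying the modules together; the CLI dispatches here.

#' Compute an epoch feature table from raw inputs
#'
#' Reads the two sensor exports and the annotation file, aligns the
#' annotations to the sensor clock, runs the preprocessing chain on
#' each leg and builds the epoch table.
#'
#' @param left_path,right_path Sensor export files (see
#'   [read_sensor_table()]).
#' @param annotations_path Annotation interval file (see
#'   [read_annotations()]).
#' @param meta A [subject_meta()].
#' @param offset Annotation-to-sensor clock offset in seconds.
#' @param out Optional path: write the epoch table as CSV.
#' @param window_s Epoch length in seconds.
#' @param time_unit,strict Passed to [read_annotations()].
#' @param column_map,sampling_rate,unit_scale Passed to
#'   [read_sensor_table()].
#' @inheritParams preprocess_leg
#' @return The epoch [tibble::tibble()], invisibly when `out` is given.
#' @export
run_features <- function(left_path, right_path, annotations_path, meta,
                         offset = 0, out = NULL, window_s = 2,
                         time_unit = "s", strict = FALSE,
                         column_map = c(time = "time", x = "ax", y = "ay",
                                        z = "az"),
                         sampling_rate = NULL, unit_scale = 1,
                         window_samples = 10, range_threshold = 0.1,
                         baseline_cm = 26.5) {
  left <- read_sensor_table(left_path, column_map, sampling_rate, unit_scale)
  right <- read_sensor_table(right_path, column_map, sampling_rate,
                             unit_scale)
  track <- read_annotations(annotations_path, time_unit = time_unit,
                            strict = strict)
  track <- align_annotations(track, left, offset = offset)
  lp <- preprocess_leg(left, meta, window_samples, range_threshold,
                       baseline_cm)
  rp <- preprocess_leg(right, meta, window_samples, range_threshold,
                       baseline_cm)
  epochs <- build_epochs(lp, rp, track, meta, window_s = window_s)
  if (!is.null(out)) {
    write_epochs(epochs, out)
    return(invisible(epochs))
  }
  epochs
}

#' Fit cut-points from an epoch table file
#'
#' @param epochs_path Epoch CSV (from [run_features()] or
#'   [write_epochs()]).
#' @param quantity,placement,method,grid Passed to [fit_thresholds()].
#' @param out Optional path for the fitted threshold JSON.
#' @param curve_out Optional path for the primary cost curve CSV.
#' @return The [fit_thresholds()] result, invisibly when `out` is
#'   given.
#' @export
run_fit <- function(epochs_path, quantity, placement, method,
                    grid = NULL, out = NULL, curve_out = NULL) {
  epochs <- read_epochs(epochs_path)
  fit <- fit_thresholds(epochs, quantity, placement, method, grid)
  if (!is.null(out)) {
    write_thresholds(fit$thresholds, out,
                     provenance = paste0("fitted from ", epochs_path))
  }
  if (!is.null(curve_out)) {
    utils::write.csv(fit$cost_curve_primary, curve_out, row.names = FALSE)
  }
  if (!is.null(out)) invisible(fit) else fit
}

#' Classify an epoch table with given or published cut-points
#'
#' @param epochs_path Epoch CSV.
#' @param thresholds A [threshold_set()], a threshold JSON path, or
#'   `NULL` to use [published_thresholds()] for
#'   `quantity`/`placement`/`method`.
#' @param quantity,placement,method Used when `thresholds` is `NULL`.
#' @param out Optional path: write the labeled epochs as CSV.
#' @return A list with the labeled epoch table (`epochs`, with a
#'   `predicted_label` column) and the predicted class proportions in
#'   percent (`proportions`).
#' @export
run_classify <- function(epochs_path, thresholds = NULL,
                         quantity = "acceleration", placement = "both",
                         method = "PAP", out = NULL) {
  epochs <- read_epochs(epochs_path)
  if (is.null(thresholds)) {
    thresholds <- published_thresholds(quantity, placement, method)
  } else if (is.character(thresholds)) {
    thresholds <- read_thresholds(thresholds)
  }
  values <- epoch_values(epochs, thresholds$quantity, thresholds$placement)
  epochs$predicted_label <- classify_epoch(values, thresholds)
  props <- 100 * vapply(ACTIVITY_LEVELS, function(k) {
    mean(epochs$predicted_label == k)
  }, numeric(1))
  if (!is.null(out)) write_epochs(epochs, out)
  list(epochs = epochs, proportions = props)
}

#' Evaluate an epoch table against cut-points
#'
#' @inheritParams run_classify
#' @param stage `"secondary"` or `"primary"`.
#' @return The [evaluation_report()].
#' @export
run_evaluate <- function(epochs_path, thresholds = NULL,
                         quantity = "acceleration", placement = "both",
                         method = "PAP", stage = "secondary") {
  epochs <- read_epochs(epochs_path)
  if (is.null(thresholds)) {
    thresholds <- published_thresholds(quantity, placement, method)
  } else if (is.character(thresholds)) {
    thresholds <- read_thresholds(thresholds)
  }
  evaluate_epochs(epochs, thresholds, stage = stage)
}

#' Simulate a session and write it to files
#'
#' @param config A [simulation_config()] (or `NULL` for defaults with
#'   `seed`).
#' @param out_dir Output directory; created if needed.
#' @param seed Seed used when `config` is `NULL`.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config = NULL, out_dir, seed = 1L) {
  if (is.null(config)) config <- simulation_config(seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ses <- generate_session(config)
  paths <- list(
    left = file.path(out_dir, "left.csv"),
    right = file.path(out_dir, "right.csv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    meta = file.path(out_dir, "meta.json"),
    truth = file.path(out_dir, "truth.csv")
  )
  write_sensor_table(ses$left, paths$left)
  write_sensor_table(ses$right, paths$right)
  write_annotations(ses$track, paths$annotations)
  jsonlite::write_json(unclass(ses$meta), paths$meta, auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(ses$truth, paths$truth, row.names = FALSE)
  invisible(paths)
}
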