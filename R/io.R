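# Readers/writers for sensor exports, annotations, epoch tables, thresholds.

# Label alias table used by read_annotations(); case-insensitive.
LABEL_ALIASES <- c(
  "sed" = "SED", "sedentary" = "SED", "s" = "SED",
  "light" = "LIGHT", "l" = "LIGHT",
  "mv" = "MV", "moderate-to-vigorous" = "MV", "moderate to vigorous" = "MV",
  "moderate_to_vigorous" = "MV", "vigorous" = "MV", "moderate" = "MV"
)

normalize_label <- function(x) {
  key <- tolower(trimws(x))
  out <- LABEL_ALIASES[key]
  if (any(is.na(out))) {
    stop("unknown activity label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a delimited sensor export
#'
#' Parses a CSV/TSV accelerometer export with a time column and three
#' axis columns into a [triaxial_series()]. Time must be strictly
#' increasing and uniformly sampled; gaps larger than 1.5 times the
#' sampling interval are an error.
#'
#' @param path File path.
#' @param column_map Named character vector mapping the roles `time`,
#'   `x`, `y`, `z` to the file's column names.
#' @param sampling_rate Optional sampling rate in Hz; when omitted the
#'   rate is inferred from the median time step.
#' @param unit_scale Multiplier applied to the axis values (e.g. 9.81
#'   for an export in units of g); default 1 for m/s^2.
#' @return A [triaxial_series()].
#' @export
read_sensor_table <- function(path,
                              column_map = c(time = "time", x = "ax",
                                             y = "ay", z = "az"),
                              sampling_rate = NULL, unit_scale = 1) {
  df <- read_delim_auto(path)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(column_map))) {
    stop("column_map must name time, x, y, z", call. = FALSE)
  }
  missing <- setdiff(unname(column_map[need]), names(df))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tm <- as.numeric(df[[column_map[["time"]]]])
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  if (any(diff(tm) <= 0)) stop("time column must be strictly increasing",
                               call. = FALSE)
  dt <- if (!is.null(sampling_rate)) 1 / sampling_rate
        else stats::median(diff(tm))
  if (length(tm) > 1L && any(diff(tm) > 1.5 * dt)) {
    stop("gap in time column larger than 1.5 x sample period",
         call. = FALSE)
  }
  triaxial_series(
    ax = as.numeric(df[[column_map[["x"]]]]) * unit_scale,
    ay = as.numeric(df[[column_map[["y"]]]]) * unit_scale,
    az = as.numeric(df[[column_map[["z"]]]]) * unit_scale,
    sample_period = dt, start_time = tm[1L])
}

#' Read an annotation interval export
#'
#' Reads a tab- or comma-delimited interval file in the style of an
#' ELAN plain-text export: one labeled interval per row with start
#' time, end time (millisecond precision) and activity label. Labels
#' are normalized to `SED`/`LIGHT`/`MV` through a case-insensitive
#' alias table (`sedentary`, `light`, `moderate-to-vigorous`, ...).
#' Rows out of order are sorted with a warning; overlapping intervals
#' are an error; intervals shorter than 2 s warn, or error when
#' `strict = TRUE`.
#'
#' @param path File path. Columns `start`, `end`, `label` by header
#'   name, or the first three columns in that order when no recognized
#'   header is present.
#' @param time_unit `"s"` (default) or `"ms"` for start/end columns.
#' @param strict Escalate short-interval warnings to errors.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path, time_unit = c("s", "ms"),
                             strict = FALSE) {
  time_unit <- match.arg(time_unit)
  df <- read_delim_auto(path)
  nm <- tolower(names(df))
  if (all(c("start", "end", "label") %in% nm)) {
    df <- df[, match(c("start", "end", "label"), nm)]
  } else if (ncol(df) >= 3L) {
    df <- df[, 1:3]
  } else {
    stop("annotation file needs start, end, label columns", call. = FALSE)
  }
  names(df) <- c("start", "end", "label")
  scale <- if (time_unit == "ms") 1e-3 else 1
  annotation_track(as.numeric(df$start) * scale,
                   as.numeric(df$end) * scale,
                   normalize_label(df$label), strict = strict)
}

#' Align annotation times to the sensor clock
#'
#' Shifts interval boundaries by `offset` (annotation clock minus
#' sensor clock, derived externally from the sync event) and snaps each
#' boundary to the nearest sample instant, ties toward the earlier
#' sample. Intervals falling wholly outside the recording are dropped
#' with a warning; partially outside intervals are clipped.
#'
#' @param track An [annotation_track()].
#' @param series The [triaxial_series()] defining the sample grid.
#' @param offset Clock offset in seconds (default 0).
#' @return The aligned [annotation_track()].
#' @export
align_annotations <- function(track, series, offset = 0) {
  stopifnot(inherits(track, "annotation_track"),
            inherits(series, "triaxial_series"))
  dt <- series$sample_period
  t0 <- series$start_time
  t1 <- t0 + (length(series) - 1L) * dt
  # nearest sample instant, exact half-sample ties toward the earlier one
  snap <- function(x) t0 + ceiling((x - t0) / dt - 0.5) * dt
  start <- snap(track$start + offset)
  end <- snap(track$end + offset)
  outside <- end <= t0 | start >= t1
  if (any(outside)) {
    warning(sum(outside), " interval(s) outside the recording dropped",
            call. = FALSE)
  }
  start <- pmax(start[!outside], t0)
  end <- pmin(end[!outside], t1)
  keep <- start < end
  if (!any(keep)) stop("no annotation intervals overlap the recording",
                       call. = FALSE)
  suppressWarnings(
    annotation_track(start[keep], end[keep], track$label[!outside][keep])
  )
}

#' Write/read an epoch feature table
#'
#' CSV with a header, full numeric precision; round-trips losslessly.
#'
#' @param epochs Epoch table from [build_epochs()].
#' @param path File path.
#' @return `read_epochs()` returns the epoch [tibble::tibble()];
#'   `write_epochs()` returns `path` invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(is.data.frame(epochs))
  df <- as.data.frame(epochs)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Write/read a threshold file
#'
#' JSON record of a [threshold_set()] including units and provenance
#' metadata; round-trips losslessly. A file without units is rejected.
#'
#' @param thresholds A [threshold_set()].
#' @param path File path.
#' @param provenance Optional character note (e.g. the fitting data's
#'   identity) stored alongside the values.
#' @return `read_thresholds()` returns the [threshold_set()];
#'   `write_thresholds()` returns `path` invisibly.
#' @export
write_thresholds <- function(thresholds, path, provenance = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"))
  rec <- list(
    quantity = thresholds$quantity, placement = thresholds$placement,
    method = thresholds$method, t_sed_active = thresholds$t_sed_active,
    t_light_mv = thresholds$t_light_mv, units = thresholds$units,
    tp_fixed = thresholds$tp_fixed,
    provenance = list(package = "legacc",
                      version = as.character(utils::packageVersion("legacc")),
                      note = provenance)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("quantity", "placement", "method", "t_sed_active",
            "t_light_mv", "units")
  missing <- setdiff(need, names(rec))
  if (length(missing) > 0L) {
    stop("threshold file missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(rec$units, threshold_units(rec$quantity))) {
    stop("threshold file units '", rec$units,
         "' inconsistent with quantity '", rec$quantity, "'",
         call. = FALSE)
  }
  threshold_set(rec$quantity, rec$placement, rec$method,
                t_sed_active = rec$t_sed_active,
                t_light_mv = rec$t_light_mv,
                tp_fixed = rec$tp_fixed)
}

#' Write a sensor series or annotation track to delimited text
#'
#' Counterparts of [read_sensor_table()] and [read_annotations()],
#' used mainly to export simulated sessions.
#'
#' @param series A [triaxial_series()].
#' @param track An [annotation_track()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sensor_table <- function(series, path) {
  stopifnot(inherits(series, "triaxial_series"))
  tm <- series$start_time + (seq_len(length(series)) - 1L) *
    series$sample_period
  df <- data.frame(time = sprintf("%.17g", tm),
                   ax = sprintf("%.17g", series$ax),
                   ay = sprintf("%.17g", series$ay),
                   az = sprintf("%.17g", series$az))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_table
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  df <- data.frame(start = sprintf("%.17g", track$start),
                   end = sprintf("%.17g", track$end),
                   label = track$label)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
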