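# Core S3 containers shared across modules.

#' Activity-intensity class labels
#'
#' The three-level observational rating scale: sedentary (`SED`), light
#' (`LIGHT`) and moderate-to-vigorous (`MV`). Ordered by intensity.
#'
#' @export
ACTIVITY_LEVELS <- c("SED", "LIGHT", "MV")

#' Tri-axial acceleration time series
#'
#' A uniformly sampled three-axis accelerometer recording for one sensor
#' (one leg). Values are in m/s^2 and include the gravity component.
#'
#' @param ax,ay,az Numeric vectors of equal length: the three axis
#'   components in m/s^2.
#' @param sample_period Time between consecutive samples in seconds
#'   (inverse of the sampling rate; 0.05 s at 20 Hz).
#' @param start_time Session-clock time of the first sample in seconds.
#'
#' @return An object of class `triaxial_series`.
#' @examples
#' triaxial_series(ax = c(0, 0), ay = c(0, 0), az = c(9.81, 9.81),
#'                 sample_period = 0.05)
#' @export
triaxial_series <- function(ax, ay, az, sample_period, start_time = 0) {
  stopifnot(is.numeric(ax), is.numeric(ay), is.numeric(az))
  n <- length(ax)
  if (n < 1L || length(ay) != n || length(az) != n) {
    stop("axis sequences must have equal length >= 1", call. = FALSE)
  }
  if (!is.numeric(sample_period) || length(sample_period) != 1L ||
      !is.finite(sample_period) || sample_period <= 0) {
    stop("sample_period must be a single positive number", call. = FALSE)
  }
  structure(
    list(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         sample_period = as.numeric(sample_period),
         start_time = as.numeric(start_time)),
    class = "triaxial_series"
  )
}

#' @export
length.triaxial_series <- function(x) length(x$ax)

#' @export
print.triaxial_series <- function(x, ...) {
  cat(sprintf(
    "<triaxial_series> %d samples @ %g Hz (dt = %g s), start %.3f s, %.2f s duration\n",
    length(x), 1 / x$sample_period, x$sample_period, x$start_time,
    length(x) * x$sample_period))
  invisible(x)
}

#' Scalar-valued derived time series
#'
#' Holds one of the scalar signals derived from a [triaxial_series()]:
#' the acceleration magnitude (`a_M`), the gravity-independent magnitude
#' (`a_IND`), the leg-length-adjusted magnitude (`a_ADJ`), all in m/s^2,
#' or the instantaneous jerk (`j`) in m/s^3.
#'
#' @param values Numeric vector of signal values.
#' @param sample_period Sampling interval in seconds.
#' @param role One of `"a_M"`, `"a_IND"`, `"a_ADJ"`, `"j"`.
#' @param start_time Session-clock time of the first sample in seconds.
#'
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(values, sample_period,
                          role = c("a_M", "a_IND", "a_ADJ", "j"),
                          start_time = 0) {
  role <- match.arg(role)
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!is.numeric(sample_period) || sample_period <= 0) {
    stop("sample_period must be positive", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), sample_period = as.numeric(sample_period),
         role = role, start_time = as.numeric(start_time)),
    class = "scalar_series"
  )
}

#' @export
length.scalar_series <- function(x) length(x$values)

#' @export
print.scalar_series <- function(x, ...) {
  units <- if (x$role == "j") "m/s^3" else "m/s^2"
  cat(sprintf("<scalar_series:%s> %d samples @ dt = %g s [%s]\n",
              x$role, length(x), x$sample_period, units))
  invisible(x)
}

#' Gold-standard annotation track
#'
#' An ordered set of non-overlapping labeled intervals, as produced by
#' observational (video) rating. Each interval carries one of the three
#' intensity labels and must last at least `min_duration` seconds, the
#' minimum epoch length of the rating protocol.
#'
#' @param start,end Numeric vectors of interval boundaries in seconds
#'   (session clock); `start < end` element-wise.
#' @param label Character vector of labels in `SED`, `LIGHT`, `MV`.
#' @param min_duration Minimum interval duration in seconds (default 2).
#' @param strict If `TRUE`, intervals shorter than `min_duration` are an
#'   error; otherwise a warning.
#'
#' @return An object of class `annotation_track`: a data frame with
#'   columns `start`, `end`, `label`, sorted by start time.
#' @export
annotation_track <- function(start, end, label, min_duration = 2,
                             strict = FALSE) {
  n <- length(start)
  if (n == 0L) stop("annotation track must contain at least one interval",
                    call. = FALSE)
  stopifnot(length(end) == n, length(label) == n)
  label <- as.character(label)
  if (!all(label %in% ACTIVITY_LEVELS)) {
    bad <- setdiff(unique(label), ACTIVITY_LEVELS)
    stop("unknown activity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start >= end)) {
    stop("each interval must satisfy start < end", call. = FALSE)
  }
  ord <- order(start)
  if (is.unsorted(start)) {
    warning("intervals were not sorted by start time; sorting", call. = FALSE)
  }
  start <- start[ord]; end <- end[ord]; label <- label[ord]
  if (n > 1L && any(start[-1L] < end[-n] - 1e-9)) {
    stop("intervals overlap", call. = FALSE)
  }
  short <- (end - start) < min_duration - 1e-9
  if (any(short)) {
    msg <- sprintf("%d interval(s) shorter than %g s", sum(short), min_duration)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(
    data.frame(start = start, end = end, label = label,
               stringsAsFactors = FALSE),
    class = c("annotation_track", "data.frame")
  )
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %d intervals, %.3f-%.3f s\n",
              nrow(x), min(x$start), max(x$end)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Subject metadata
#'
#' @param subject_id Subject identifier.
#' @param group `"TD"` (typically developing) or `"AR"` (at risk for
#'   neurodevelopmental disability).
#' @param age_days Age in days (adjusted for prematurity where relevant).
#' @param leg_length_cm Leg length in centimeters (thigh + shank), used
#'   for the acceleration adjustment.
#'
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, group = c("TD", "AR"), age_days = NA,
                         leg_length_cm) {
  group <- match.arg(group)
  if (!is.numeric(leg_length_cm) || length(leg_length_cm) != 1L ||
      !is.finite(leg_length_cm) || leg_length_cm <= 0) {
    stop("leg_length_cm must be a single positive number", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         age_days = age_days, leg_length_cm = as.numeric(leg_length_cm)),
    class = "subject_meta"
  )
}

#' Cut-point set for epoch classification
#'
#' Two cut-points on a derived epoch quantity: sedentary/active and
#' light/MV. Units follow the quantity: m/s for the acceleration area
#' `c_A`, m/s^2 for the jerk area `c_J`.
#'
#' @param quantity `"acceleration"` or `"jerk"`.
#' @param placement Which leg(s) the quantity was combined over:
#'   `"both"`, `"left"` or `"right"`.
#' @param method Calibration method that produced the cut-points:
#'   `"TP"` (true-positive-rate matching) or `"PAP"`
#'   (predicted-activity-proportion matching).
#' @param t_sed_active Sedentary/active cut-point (lower).
#' @param t_light_mv Light/MV cut-point (upper, `>= t_sed_active`).
#' @param tp_fixed For `method = "TP"`: the frozen sedentary TP rate (%)
#'   that the secondary step matched. `NULL` otherwise.
#'
#' @return An object of class `threshold_set`.
#' @examples
#' threshold_set("acceleration", "both", "PAP", 1.0, 2.6)
#' @export
threshold_set <- function(quantity = c("acceleration", "jerk"),
                          placement = c("both", "left", "right"),
                          method = c("TP", "PAP"),
                          t_sed_active, t_light_mv, tp_fixed = NULL) {
  quantity <- match.arg(quantity)
  placement <- match.arg(placement)
  method <- match.arg(method)
  if (!is.numeric(t_sed_active) || !is.numeric(t_light_mv) ||
      t_sed_active <= 0 || t_light_mv < t_sed_active) {
    stop("require 0 < t_sed_active <= t_light_mv", call. = FALSE)
  }
  structure(
    list(quantity = quantity, placement = placement, method = method,
         t_sed_active = as.numeric(t_sed_active),
         t_light_mv = as.numeric(t_light_mv),
         tp_fixed = if (is.null(tp_fixed)) NULL else as.numeric(tp_fixed),
         units = threshold_units(quantity)),
    class = "threshold_set"
  )
}

threshold_units <- function(quantity) {
  switch(quantity, acceleration = "m/s", jerk = "m/s^2",
         stop("unknown quantity: ", quantity, call. = FALSE))
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %s, %s leg(s), %s method\n",
              x$quantity, x$placement, x$method))
  cat(sprintf("  sedentary/active: %s %s\n", signif(x$t_sed_active, 3), x$units))
  cat(sprintf("  light/MV:         %s %s\n", signif(x$t_light_mv, 3), x$units))
  if (!is.null(x$tp_fixed)) {
    cat(sprintf("  TP_FIXED: %.1f %%\n", x$tp_fixed))
  }
  invisible(x)
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so simulation calls do not perturb it.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
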