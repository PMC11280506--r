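# Raw tri-axial samples -> gravity-free, leg-length-adjusted scalar signal.

#' Acceleration magnitude
#'
#' Element-wise Euclidean norm of the three axis components,
#' `a_M = sqrt(ax^2 + ay^2 + az^2)`. The magnitude is orientation-free:
#' it is invariant under axis permutations and sign flips.
#'
#' @param series A [triaxial_series()].
#' @return A [scalar_series()] with role `"a_M"` (m/s^2).
#' @export
magnitude <- function(series) {
  stopifnot(inherits(series, "triaxial_series"))
  scalar_series(sqrt(series$ax^2 + series$ay^2 + series$az^2),
                sample_period = series$sample_period, role = "a_M",
                start_time = series$start_time)
}

#' Detect static segments of the magnitude signal
#'
#' A window of `window_samples` consecutive samples (0.5 s at 20 Hz) is
#' static when its range (max minus min) is at most `range_threshold`
#' (10 mg by default). The scan slides one sample at a time; overlapping
#' qualifying windows are merged into maximal runs.
#'
#' @param a_m A [scalar_series()] (role `"a_M"`), or a plain numeric vector.
#' @param window_samples Window length in samples (default 10).
#' @param range_threshold Maximum allowed max-min range in m/s^2
#'   (default 0.1).
#' @return A data frame with columns `start`, `end`: 1-based inclusive
#'   sample indices of each maximal static run. Zero rows when no window
#'   qualifies.
#' @export
find_static_segments <- function(a_m, window_samples = 10,
                                 range_threshold = 0.1) {
  x <- if (inherits(a_m, "scalar_series")) a_m$values else as.numeric(a_m)
  w <- as.integer(window_samples)
  stopifnot(w >= 1L, range_threshold >= 0)
  n <- length(x)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < w) return(empty)
  # running max/min over the w shifted copies (vectorized, no deps)
  shifts <- lapply(seq_len(w) - 1L, function(k) x[(1L + k):(n - w + 1L + k)])
  rng <- do.call(pmax, shifts) - do.call(pmin, shifts)
  ok <- which(rng <= range_threshold + 1e-12)   # "less than or equal to"
  if (length(ok) == 0L) return(empty)
  # merge overlapping/adjacent qualifying windows [i, i+w-1] into maximal runs
  merged_start <- integer(0); merged_end <- integer(0)
  cs <- ok[1L]; ce <- ok[1L] + w - 1L
  for (i in ok[-1L]) {
    if (i <= ce + 1L) {
      ce <- i + w - 1L
    } else {
      merged_start <- c(merged_start, cs); merged_end <- c(merged_end, ce)
      cs <- i; ce <- i + w - 1L
    }
  }
  merged_start <- c(merged_start, cs); merged_end <- c(merged_end, ce)
  data.frame(start = merged_start, end = merged_end)
}

#' Estimate the gravity baseline
#'
#' The gravity magnitude `a_G` is the mean of `a_M` over all samples that
#' lie inside static segments (see [find_static_segments()]). When the
#' recording contains no static segment, the median of the whole series
#' is used as a fallback.
#'
#' @param a_m A [scalar_series()] with role `"a_M"`.
#' @param window_samples,range_threshold Passed to [find_static_segments()].
#' @return An object of class `gravity_estimate`: a list with elements
#'   `a_G` (m/s^2), `source` (`"static_segments"` or `"median_fallback"`)
#'   and `static_segments` (the detected runs).
#' @export
gravity_baseline <- function(a_m, window_samples = 10, range_threshold = 0.1) {
  stopifnot(inherits(a_m, "scalar_series"))
  if (length(a_m) == 0L) stop("empty series", call. = FALSE)
  segs <- find_static_segments(a_m, window_samples, range_threshold)
  if (nrow(segs) > 0L) {
    idx <- unlist(Map(seq.int, segs$start, segs$end), use.names = FALSE)
    est <- mean(a_m$values[idx])
    src <- "static_segments"
  } else {
    est <- stats::median(a_m$values)
    src <- "median_fallback"
  }
  structure(list(a_G = est, source = src, static_segments = segs),
            class = "gravity_estimate")
}

#' @export
print.gravity_estimate <- function(x, ...) {
  cat(sprintf("<gravity_estimate> a_G = %.4f m/s^2 (%s, %d static run(s))\n",
              x$a_G, x$source, nrow(x$static_segments)))
  invisible(x)
}

#' Remove the gravity component
#'
#' `a_IND = a_M - a_G`, element-wise. Values may be negative (the
#' magnitude dips below the gravity baseline when the sensor accelerates
#' against gravity); downstream epoch areas rectify.
#'
#' @param a_m A [scalar_series()] with role `"a_M"`.
#' @param g A [gravity_baseline()] result, or a single number in m/s^2.
#' @return A [scalar_series()] with role `"a_IND"`.
#' @export
remove_gravity <- function(a_m, g) {
  stopifnot(inherits(a_m, "scalar_series"))
  a_g <- if (inherits(g, "gravity_estimate")) g$a_G else as.numeric(g)
  stopifnot(length(a_g) == 1L, is.finite(a_g))
  scalar_series(a_m$values - a_g, sample_period = a_m$sample_period,
                role = "a_IND", start_time = a_m$start_time)
}

#' Adjust for leg length
#'
#' Longer legs produce larger linear accelerations at the ankle for the
#' same angular movement, so the gravity-independent signal is rescaled
#' to a common baseline leg length (26.5 cm, the median rump-sole length
#' of 3-5-month-old infants):
#' `a_ADJ = a_IND * baseline_cm / leg_length_cm`.
#'
#' @param a_ind A [scalar_series()] with role `"a_IND"`.
#' @param meta A [subject_meta()] (or a single positive leg length in cm).
#' @param baseline_cm Baseline leg length in cm (default 26.5).
#' @param direction `"baseline_over_leg"` (default: longer legs scaled
#'   down) or `"leg_over_baseline"` (the inverse reading, available for
#'   sensitivity analysis).
#' @return A [scalar_series()] with role `"a_ADJ"`.
#' @export
adjust_leg_length <- function(a_ind, meta, baseline_cm = 26.5,
                              direction = c("baseline_over_leg",
                                            "leg_over_baseline")) {
  stopifnot(inherits(a_ind, "scalar_series"))
  direction <- match.arg(direction)
  leg <- if (inherits(meta, "subject_meta")) meta$leg_length_cm
         else as.numeric(meta)
  if (!is.finite(leg) || leg <= 0) {
    stop("leg length must be positive", call. = FALSE)
  }
  stopifnot(baseline_cm > 0)
  f <- if (direction == "baseline_over_leg") baseline_cm / leg
       else leg / baseline_cm
  scalar_series(a_ind$values * f, sample_period = a_ind$sample_period,
                role = "a_ADJ", start_time = a_ind$start_time)
}

#' Full preprocessing chain for one leg
#'
#' Convenience wrapper: magnitude, gravity estimation and removal, leg
#' length adjustment, and jerk. Returns the adjusted acceleration and
#' jerk series used by [build_epochs()].
#'
#' @param series A [triaxial_series()] for one leg.
#' @param meta A [subject_meta()].
#' @inheritParams gravity_baseline
#' @inheritParams adjust_leg_length
#' @return A list with elements `a_adj`, `j` (both [scalar_series()])
#'   and `gravity` (the [gravity_baseline()] estimate).
#' @export
preprocess_leg <- function(series, meta, window_samples = 10,
                           range_threshold = 0.1, baseline_cm = 26.5,
                           direction = "baseline_over_leg") {
  a_m <- magnitude(series)
  g <- gravity_baseline(a_m, window_samples, range_threshold)
  a_ind <- remove_gravity(a_m, g)
  a_adj <- adjust_leg_length(a_ind, meta, baseline_cm, direction)
  list(a_adj = a_adj, j = jerk(a_adj), gravity = g)
}
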