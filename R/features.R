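# Epoch-level derived quantities c_A and c_J on valid 2-s windows.

#' Instantaneous jerk
#'
#' First difference of the adjusted acceleration divided by the sampling
#' interval: `j_i = (a_ADJ,i - a_ADJ,i-1) / dt`. The first sample, which
#' has no predecessor, is set to zero. Jerk is computed once on the
#' continuous recording, not restarted per window, so the sample before
#' a window boundary contributes to the first jerk value inside it.
#'
#' @param a_adj A [scalar_series()] with role `"a_ADJ"` (length >= 2).
#' @return A [scalar_series()] with role `"j"` (m/s^3).
#' @export
jerk <- function(a_adj) {
  stopifnot(inherits(a_adj, "scalar_series"))
  if (length(a_adj) < 2L) stop("need at least 2 samples for jerk",
                               call. = FALSE)
  scalar_series(c(0, diff(a_adj$values) / a_adj$sample_period),
                sample_period = a_adj$sample_period, role = "j",
                start_time = a_adj$start_time)
}

#' Enumerate valid epoch windows
#'
#' Within each annotated interval, non-overlapping windows of
#' `window_s` seconds are laid out starting at the interval start. A
#' trailing remainder shorter than the window length is discarded, so
#' every window is wholly contained in a single intensity region.
#'
#' @param track An [annotation_track()] already aligned to the sensor
#'   clock.
#' @param window_s Window length in seconds (default 2).
#' @return A [tibble::tibble()] with columns `start`, `end`, `label`,
#'   one row per valid window.
#' @export
valid_windows <- function(track, window_s = 2.0) {
  stopifnot(inherits(track, "annotation_track"), window_s > 0)
  out <- lapply(seq_len(nrow(track)), function(i) {
    dur <- track$end[i] - track$start[i]
    k <- floor(dur / window_s + 1e-9)
    if (k < 1) return(NULL)
    s <- track$start[i] + (seq_len(k) - 1) * window_s
    tibble::tibble(start = s, end = s + window_s, label = track$label[i])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- tibble::tibble(start = numeric(0), end = numeric(0),
                          label = character(0))
  }
  out
}

#' Area under a scalar signal over one window
#'
#' Left-Riemann approximation of the time integral over `[start, end)`:
#' the sum of rectified sample values times the sampling interval. With
#' `rectify = TRUE` (the default, matching activity-count convention)
#' absolute values are integrated; `rectify = FALSE` gives the signed
#' integral for sensitivity analysis. A 2-s window at 20 Hz covers
#' exactly 40 samples.
#'
#' @param series A [scalar_series()] (`a_ADJ` for `c_A`, `j` for `c_J`).
#' @param window Numeric length-2 vector `c(start, end)` in seconds
#'   (session clock); must lie fully inside the series.
#' @param rectify Integrate absolute values? Default `TRUE`.
#' @return The area: m/s for an acceleration signal, m/s^2 for jerk.
#' @export
epoch_area <- function(series, window, rectify = TRUE) {
  stopifnot(inherits(series, "scalar_series"), length(window) == 2L)
  dt <- series$sample_period
  i0 <- round((window[1] - series$start_time) / dt) + 1L
  n <- round((window[2] - window[1]) / dt)
  if (i0 < 1L || i0 + n - 1L > length(series)) {
    stop("window extends past the series", call. = FALSE)
  }
  v <- series$values[i0:(i0 + n - 1L)]
  if (rectify) v <- abs(v)
  sum(v) * dt
}

#' Combine per-leg epoch areas
#'
#' `c_TOTAL` is the sum of the left- and right-leg areas for
#' `placement = "both"`, or the single leg's area otherwise.
#'
#' @param left,right Per-leg areas (either may be `NA` if that leg is
#'   not required by `placement`).
#' @param placement `"both"`, `"left"` or `"right"`.
#' @return The combined area.
#' @export
combine_legs <- function(left, right, placement = c("both", "left", "right")) {
  placement <- match.arg(placement)
  need <- switch(placement, both = c("left", "right"), left = "left",
                 right = "right")
  if ("left" %in% need && (is.null(left) || any(is.na(left)))) {
    stop("left-leg area required for placement '", placement, "'",
         call. = FALSE)
  }
  if ("right" %in% need && (is.null(right) || any(is.na(right)))) {
    stop("right-leg area required for placement '", placement, "'",
         call. = FALSE)
  }
  switch(placement, both = left + right, left = left, right = right)
}

#' Build the epoch feature table
#'
#' Computes, for every valid window of the annotation track, the
#' acceleration area `c_A` and jerk area `c_J` for each leg, plus the
#' both-legs totals, alongside the gold-standard label.
#'
#' @param left,right Per-leg signal lists as returned by
#'   [preprocess_leg()]: each a list with elements `a_adj` and `j`.
#' @param track An aligned [annotation_track()].
#' @param meta A [subject_meta()].
#' @param window_s Epoch length in seconds (default 2).
#' @param rectify Passed to [epoch_area()].
#' @return A [tibble::tibble()] with one row per epoch and columns
#'   `subject_id`, `window_start_s`, `window_end_s`, `gold_label`,
#'   `c_a_left`, `c_a_right`, `c_a_total`, `c_j_left`, `c_j_right`,
#'   `c_j_total`.
#' @export
build_epochs <- function(left, right, track, meta, window_s = 2.0,
                         rectify = TRUE) {
  stopifnot(is.list(left), is.list(right),
            inherits(left$a_adj, "scalar_series"),
            inherits(right$a_adj, "scalar_series"),
            inherits(meta, "subject_meta"))
  win <- valid_windows(track, window_s)
  if (nrow(win) == 0L) stop("no valid windows in the annotation track",
                            call. = FALSE)
  area <- function(series, rect) {
    vapply(seq_len(nrow(win)), function(i) {
      epoch_area(series, c(win$start[i], win$end[i]), rectify = rect)
    }, numeric(1))
  }
  c_a_left <- area(left$a_adj, rectify)
  c_a_right <- area(right$a_adj, rectify)
  c_j_left <- area(left$j, rectify)
  c_j_right <- area(right$j, rectify)
  tibble::tibble(
    subject_id = meta$subject_id,
    window_start_s = win$start, window_end_s = win$end,
    gold_label = win$label,
    c_a_left = c_a_left, c_a_right = c_a_right,
    c_a_total = c_a_left + c_a_right,
    c_j_left = c_j_left, c_j_right = c_j_right,
    c_j_total = c_j_left + c_j_right
  )
}

#' Extract the c_TOTAL column for a quantity/placement pair
#'
#' @param epochs An epoch table from [build_epochs()].
#' @param quantity `"acceleration"` or `"jerk"`.
#' @param placement `"both"`, `"left"` or `"right"`.
#' @return Numeric vector of epoch values.
#' @export
epoch_values <- function(epochs, quantity = c("acceleration", "jerk"),
                         placement = c("both", "left", "right")) {
  quantity <- match.arg(quantity)
  placement <- match.arg(placement)
  col <- paste0(if (quantity == "acceleration") "c_a_" else "c_j_",
                if (placement == "both") "total" else placement)
  if (!col %in% names(epochs)) stop("epoch table lacks column ", col,
                                    call. = FALSE)
  epochs[[col]]
}

#' Classify epochs by cut-points
#'
#' Applies the two cut-points to epoch values. Boundaries are
#' left-closed toward the higher class: a value exactly at a cut-point
#' takes the more intense label, i.e. `c < t_sed_active` is `SED`,
#' `t_sed_active <= c < t_light_mv` is `LIGHT`, `c >= t_light_mv` is
#' `MV`. Classification is monotone in the epoch value.
#'
#' @param c_total Numeric vector of combined epoch areas, in the units
#'   of `thresholds$quantity`.
#' @param thresholds A [threshold_set()].
#' @return Character vector of predicted labels.
#' @export
classify_epoch <- function(c_total, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"), is.numeric(c_total))
  ifelse(c_total < thresholds$t_sed_active, "SED",
         ifelse(c_total < thresholds$t_light_mv, "LIGHT", "MV"))
}
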