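# Published cut-points for the four approaches and three sensor placements.

published_table <- local({
  rows <- rbind(
    # placement, quantity, method, t_sed_active, t_light_mv
    c("both",  "jerk",         "TP",  27.0,  41.0),
    c("both",  "jerk",         "PAP", 18.0,  56.0),
    c("both",  "acceleration", "TP",  1.30,  1.80),
    c("both",  "acceleration", "PAP", 1.00,  2.60),
    c("left",  "jerk",         "TP",  10.0,  16.0),
    c("left",  "jerk",         "PAP", 8.00,  27.0),
    c("left",  "acceleration", "TP",  0.600, 0.800),
    c("left",  "acceleration", "PAP", 0.50,  1.30),
    c("right", "jerk",         "TP",  11.0,  17.0),
    c("right", "jerk",         "PAP", 7.00,  24.0),
    c("right", "acceleration", "TP",  0.400, 0.800),
    c("right", "acceleration", "PAP", 0.300, 1.00)
  )
  tibble::tibble(
    placement = rows[, 1], quantity = rows[, 2], method = rows[, 3],
    t_sed_active = as.numeric(rows[, 4]), t_light_mv = as.numeric(rows[, 5]),
    units = ifelse(rows[, 2] == "acceleration", "m/s", "m/s^2")
  )
})

#' Published activity-intensity cut-points
#'
#' The calibrated sedentary/active and light/MV cut-points for
#' pre-ambulatory infants, for every combination of derived quantity
#' (acceleration area in m/s, jerk area in m/s^2), sensor placement
#' (both legs, left only, right only) and calibration method (TP or
#' PAP). The recommended set for two ankle sensors is the
#' acceleration/PAP pair: 1.00 and 2.60 m/s.
#'
#' @param quantity,placement,method Select one set; call
#'   [published_threshold_table()] for all twelve.
#' @return A [threshold_set()].
#' @examples
#' published_thresholds("acceleration", "both", "PAP")
#' @export
published_thresholds <- function(quantity = c("acceleration", "jerk"),
                                 placement = c("both", "left", "right"),
                                 method = c("PAP", "TP")) {
  quantity <- match.arg(quantity)
  placement <- match.arg(placement)
  method <- match.arg(method)
  row <- published_table[published_table$quantity == quantity &
                         published_table$placement == placement &
                         published_table$method == method, ]
  stopifnot(nrow(row) == 1L)
  threshold_set(quantity, placement, method,
                t_sed_active = row$t_sed_active,
                t_light_mv = row$t_light_mv)
}

#' @rdname published_thresholds
#' @export
published_threshold_table <- function() published_table
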