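# Two-stage grid-search calibration of cut-points against gold labels.

# Internal: two-class TP rates at a sedentary/active candidate.
tp_rates_primary <- function(values, gold, candidate) {
  is_sed <- gold == "SED"
  pred_sed <- values < candidate
  list(tp_sed = 100 * sum(pred_sed & is_sed) / sum(is_sed),
       tp_active = 100 * sum(!pred_sed & !is_sed) / sum(!is_sed))
}

check_classes <- function(gold, needed) {
  miss <- setdiff(needed, unique(gold))
  if (length(miss) > 0L) {
    stop("gold label class(es) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Primary TP cost: |TP_SED - TP_ACTIVE|
#'
#' The sedentary/active cut-point is chosen to equalize the true
#' positive rates of the two classes (ACTIVE = LIGHT plus MV). A
#' candidate that is too low makes `TP_SED` small and `TP_ACTIVE` large;
#' too high does the opposite; the optimum is the crossing point, so the
#' raw difference is minimized in absolute value.
#'
#' @param epochs Epoch table from [build_epochs()].
#' @param quantity,placement Select the `c_TOTAL` column
#'   (see [epoch_values()]).
#' @param candidate Candidate sedentary/active cut-point.
#' @return The cost in percentage points.
#' @export
cost_tp_primary <- function(epochs, quantity, placement, candidate) {
  values <- epoch_values(epochs, quantity, placement)
  gold <- epochs$gold_label
  check_classes(gold, "SED")
  if (all(gold == "SED")) stop("gold label class(es) absent: ACTIVE",
                               call. = FALSE)
  r <- tp_rates_primary(values, gold, candidate)
  abs(r$tp_sed - r$tp_active)
}

#' Secondary TP cost: |TP_MV - TP_FIXED|
#'
#' The light/MV cut-point is chosen so that the MV true positive rate
#' matches `TP_FIXED`, the sedentary TP rate frozen from the primary
#' step. Predictions use the full three-class rule with the primary
#' cut-point `t_primary` and the candidate.
#'
#' @inheritParams cost_tp_primary
#' @param t_primary Fitted sedentary/active cut-point.
#' @param candidate Candidate light/MV cut-point (`>= t_primary`).
#' @param tp_fixed Frozen reference TP rate in percent.
#' @return The cost in percentage points.
#' @export
cost_tp_secondary <- function(epochs, quantity, placement, t_primary,
                              candidate, tp_fixed) {
  values <- epoch_values(epochs, quantity, placement)
  gold <- epochs$gold_label
  check_classes(gold, "MV")
  is_mv <- gold == "MV"
  tp_mv <- 100 * sum(is_mv & values >= candidate & values >= t_primary) /
    sum(is_mv)
  abs(tp_mv - tp_fixed)
}

#' Primary PAP cost: proportion matching, sedentary vs active
#'
#' The cut-point is chosen so that the number of epochs the
#' accelerometer assigns to each class (true and false positives alike)
#' matches the gold-standard count. Each class deviation is expressed
#' relative to its gold count and weighted equally:
#' `|gold_sed - pred_sed| / gold_sed * 100 + |gold_active - pred_active| / gold_active * 100`.
#'
#' @inheritParams cost_tp_primary
#' @return The cost in percentage points.
#' @export
cost_pap_primary <- function(epochs, quantity, placement, candidate) {
  values <- epoch_values(epochs, quantity, placement)
  gold <- epochs$gold_label
  g_sed <- sum(gold == "SED"); g_act <- sum(gold != "SED")
  if (g_sed == 0L || g_act == 0L) {
    stop("both gold classes required for the PAP cost", call. = FALSE)
  }
  p_sed <- sum(values < candidate); p_act <- length(values) - p_sed
  100 * abs(g_sed - p_sed) / g_sed + 100 * abs(g_act - p_act) / g_act
}

#' Secondary PAP cost: proportion matching, light vs MV
#'
#' Same proportion-matching principle as [cost_pap_primary()], applied
#' to the light and MV classes with predictions from the full
#' three-class rule.
#'
#' @inheritParams cost_tp_secondary
#' @return The cost in percentage points.
#' @export
cost_pap_secondary <- function(epochs, quantity, placement, t_primary,
                               candidate) {
  values <- epoch_values(epochs, quantity, placement)
  gold <- epochs$gold_label
  g_light <- sum(gold == "LIGHT"); g_mv <- sum(gold == "MV")
  if (g_light == 0L || g_mv == 0L) {
    stop("gold LIGHT and MV classes required", call. = FALSE)
  }
  p_light <- sum(values >= t_primary & values < candidate)
  p_mv <- sum(values >= t_primary & values >= candidate)
  100 * abs(g_light - p_light) / g_light + 100 * abs(g_mv - p_mv) / g_mv
}

#' Fit sedentary/active and light/MV cut-points
#'
#' Two-stage grid search. The primary stage minimizes the method's
#' primary cost over a uniform candidate grid; the secondary stage
#' minimizes the secondary cost over candidates at or above the fitted
#' primary cut-point. Primary ties are broken toward the smallest
#' candidate; secondary ties toward the largest (the secondary costs
#' plateau at zero over a whole band when the classes separate cleanly,
#' and the plateau's upper end is the crossing point of the matched
#' rate). For the TP method, `TP_FIXED` is frozen at the sedentary TP
#' rate of the fitted primary cut-point before the secondary search.
#'
#' The default grid steps are 0.01 m/s for acceleration areas and
#' 0.1 m/s^2 for jerk areas, spanning 0 to the largest observed
#' `c_TOTAL`.
#'
#' @param epochs Epoch table from [build_epochs()]; all three gold
#'   classes must be present.
#' @param quantity `"acceleration"` or `"jerk"`.
#' @param placement `"both"`, `"left"` or `"right"`.
#' @param method `"TP"` or `"PAP"`.
#' @param grid Optional list with elements `min`, `max`, `step`
#'   overriding the default candidate grid.
#' @return An object of class `optimization_result`: list with elements
#'   `thresholds` (a [threshold_set()]), `tp_fixed` (TP method only),
#'   `cost_curve_primary` and `cost_curve_secondary` (tibbles with
#'   columns `candidate`, `cost`), and `confusion` (training-data
#'   secondary-stage counts at the fitted cut-points).
#' @export
fit_thresholds <- function(epochs, quantity = c("acceleration", "jerk"),
                           placement = c("both", "left", "right"),
                           method = c("TP", "PAP"), grid = NULL) {
  quantity <- match.arg(quantity)
  placement <- match.arg(placement)
  method <- match.arg(method)
  values <- epoch_values(epochs, quantity, placement)
  gold <- epochs$gold_label
  check_classes(gold, c("SED", "LIGHT", "MV"))

  step <- if (!is.null(grid$step)) grid$step
          else if (quantity == "acceleration") 0.01 else 0.1
  gmin <- if (!is.null(grid$min)) grid$min else 0
  gmax <- if (!is.null(grid$max)) grid$max else max(values)
  candidates <- seq(gmin, gmax + step, by = step)
  candidates <- candidates[candidates > 0]   # a cut-point must be positive
  if (length(candidates) < 2L) stop("empty candidate grid", call. = FALSE)

  primary_cost <- switch(method,
    TP = function(t) cost_tp_primary(epochs, quantity, placement, t),
    PAP = function(t) cost_pap_primary(epochs, quantity, placement, t))
  cost_p <- vapply(candidates, primary_cost, numeric(1))
  t_primary <- candidates[which.min(cost_p)]   # first minimum = smallest

  tp_fixed <- NULL
  if (method == "TP") {
    tp_fixed <- tp_rates_primary(values, gold, t_primary)$tp_sed
  }
  secondary_cost <- switch(method,
    TP = function(t) cost_tp_secondary(epochs, quantity, placement,
                                       t_primary, t, tp_fixed),
    PAP = function(t) cost_pap_secondary(epochs, quantity, placement,
                                         t_primary, t))
  cand_s <- candidates[candidates >= t_primary]
  cost_s <- vapply(cand_s, secondary_cost, numeric(1))
  # largest minimizer: the secondary costs plateau at their minimum when
  # classes separate cleanly (TP_FIXED = 100), and the upper end of the
  # plateau is the crossing point where the cost is about to rise
  t_secondary <- cand_s[max(which(cost_s == min(cost_s)))]

  ths <- threshold_set(quantity, placement, method,
                       t_sed_active = t_primary,
                       t_light_mv = t_secondary,
                       tp_fixed = tp_fixed)
  pred <- classify_epoch(values, ths)
  structure(
    list(thresholds = ths, tp_fixed = tp_fixed,
         cost_curve_primary = tibble::tibble(candidate = candidates,
                                             cost = cost_p),
         cost_curve_secondary = tibble::tibble(candidate = cand_s,
                                               cost = cost_s),
         confusion = confusion(gold, pred, stage = "secondary")),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>\n")
  print(x$thresholds)
  cat(sprintf("  primary cost at optimum:   %.4g\n",
              min(x$cost_curve_primary$cost)))
  cat(sprintf("  secondary cost at optimum: %.4g\n",
              min(x$cost_curve_secondary$cost)))
  invisible(x)
}
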