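# Confusion counts and evaluation metrics (TP/TN rate, PAP, MTPR, PMR).

stage_levels <- function(stage) {
  switch(stage, primary = c("SED", "ACTIVE"),
         secondary = c("SED", "LIGHT", "MV"),
         stop("stage must be 'primary' or 'secondary'", call. = FALSE))
}

# Collapse three-class labels to the primary (two-class) scheme.
to_primary <- function(labels) ifelse(labels == "SED", "SED", "ACTIVE")

#' Cross-tabulate gold and predicted labels
#'
#' Builds the gold-by-predicted confusion matrix for one evaluation
#' stage. In the primary stage the LIGHT and MV labels are collapsed to
#' ACTIVE before tabulation.
#'
#' @param gold,predicted Character vectors of equal length with labels
#'   in `SED`/`LIGHT`/`MV` (or already `SED`/`ACTIVE` for the primary
#'   stage).
#' @param stage `"primary"` (2x2) or `"secondary"` (3x3).
#' @return An object of class `confusion_counts`: an integer matrix
#'   with gold classes as rows and predicted classes as columns, and a
#'   `stage` attribute.
#' @export
confusion <- function(gold, predicted, stage = c("secondary", "primary")) {
  stage <- match.arg(stage)
  if (length(gold) != length(predicted)) {
    stop("gold and predicted must have equal length", call. = FALSE)
  }
  lev <- stage_levels(stage)
  if (stage == "primary") {
    gold <- to_primary(gold); predicted <- to_primary(predicted)
  }
  ok <- c(lev)
  if (!all(gold %in% ok) || !all(predicted %in% ok)) {
    stop("invalid label for stage '", stage, "'", call. = FALSE)
  }
  m <- table(factor(gold, levels = lev), factor(predicted, levels = lev))
  m <- matrix(as.integer(m), nrow = length(lev),
              dimnames = list(gold = lev, predicted = lev))
  structure(m, stage = stage, class = c("confusion_counts", class(m)))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %s stage, %d epochs\n",
              attr(x, "stage"), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' True positive rate (sensitivity) for one class
#'
#' Percentage of gold epochs of the class that were predicted as that
#' class: 100 times the diagonal cell over the gold row total.
#'
#' @param counts A [confusion()] matrix.
#' @param class A class name; omit to get all classes as a named vector.
#' @return Percent in `[0, 100]`.
#' @export
tp_rate <- function(counts, class = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  lev <- rownames(counts)
  if (is.null(class)) {
    return(stats::setNames(vapply(lev, function(k) tp_rate(counts, k),
                                  numeric(1)), lev))
  }
  stopifnot(class %in% lev)
  tot <- sum(counts[class, ])
  if (tot == 0) stop("no gold epochs of class ", class, call. = FALSE)
  100 * counts[class, class] / tot
}

#' True negative rate (specificity) for one class
#'
#' Percentage of gold epochs NOT of the class that were predicted as
#' any label other than the class: for MV, the numerator counts SED and
#' LIGHT gold epochs predicted SED or LIGHT.
#'
#' @inheritParams tp_rate
#' @return Percent in `[0, 100]`.
#' @export
tn_rate <- function(counts, class = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  lev <- rownames(counts)
  if (is.null(class)) {
    return(stats::setNames(vapply(lev, function(k) tn_rate(counts, k),
                                  numeric(1)), lev))
  }
  stopifnot(class %in% lev)
  other <- setdiff(lev, class)
  tot <- sum(counts[other, ])
  if (tot == 0) stop("no gold epochs outside class ", class, call. = FALSE)
  100 * sum(counts[other, other, drop = FALSE]) / tot
}

#' Predicted and gold activity proportions
#'
#' `pap()` is the percentage of all evaluated epochs that the
#' accelerometer assigned to the class (true and false positives
#' alike): 100 times the predicted column total over the grand total.
#' `pap_gold()` is the gold-standard analogue using row totals. Each
#' set of proportions sums to 100.
#'
#' @inheritParams tp_rate
#' @return Percent in `[0, 100]`.
#' @export
pap <- function(counts, class = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  lev <- colnames(counts)
  if (sum(counts) == 0) stop("empty confusion counts", call. = FALSE)
  if (is.null(class)) {
    return(stats::setNames(vapply(lev, function(k) pap(counts, k),
                                  numeric(1)), lev))
  }
  stopifnot(class %in% lev)
  100 * sum(counts[, class]) / sum(counts)
}

#' @rdname pap
#' @export
pap_gold <- function(counts, class = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  lev <- rownames(counts)
  if (sum(counts) == 0) stop("empty confusion counts", call. = FALSE)
  if (is.null(class)) {
    return(stats::setNames(vapply(lev, function(k) pap_gold(counts, k),
                                  numeric(1)), lev))
  }
  stopifnot(class %in% lev)
  100 * sum(counts[class, ]) / sum(counts)
}

#' Assemble an evaluation report
#'
#' Bundles per-class rates and proportions for one evaluation stage.
#' Reports are usually produced by [evaluate_epochs()], but can be
#' built directly from externally reported rates (e.g. published
#' tables) to recompute the summary metrics [mtpr()] and [pmr()].
#'
#' @param stage `"primary"` or `"secondary"`.
#' @param tp_rate,tn_rate Named per-class rates in percent (`tn_rate`
#'   optional).
#' @param pap_gold,pap_pred Named per-class activity proportions in
#'   percent (gold-standard and accelerometer-predicted).
#' @param counts Optional [confusion()] matrix the rates came from.
#' @return An object of class `evaluation_report`.
#' @export
evaluation_report <- function(stage = c("secondary", "primary"), tp_rate,
                              tn_rate = NULL, pap_gold, pap_pred,
                              counts = NULL) {
  stage <- match.arg(stage)
  lev <- stage_levels(stage)
  for (v in list(tp_rate, pap_gold, pap_pred)) {
    if (!all(lev %in% names(v))) {
      stop("rates must be named vectors covering: ",
           paste(lev, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(stage = stage, tp_rate = tp_rate[lev],
         tn_rate = if (!is.null(tn_rate)) tn_rate[lev],
         pap_gold = pap_gold[lev], pap_pred = pap_pred[lev],
         counts = counts),
    class = "evaluation_report"
  )
}

#' Evaluate epoch classifications against the gold standard
#'
#' Classifies each epoch with the given cut-points, cross-tabulates
#' against the gold labels, and computes all per-class metrics. All
#' rates are carried at full precision; round only for display.
#'
#' @param epochs Epoch table from [build_epochs()].
#' @param thresholds A [threshold_set()]; its `quantity` and
#'   `placement` select the epoch value column.
#' @param stage `"primary"` (sedentary/active) or `"secondary"`
#'   (three classes).
#' @return An [evaluation_report()].
#' @export
evaluate_epochs <- function(epochs, thresholds,
                            stage = c("secondary", "primary")) {
  stage <- match.arg(stage)
  stopifnot(inherits(thresholds, "threshold_set"))
  values <- epoch_values(epochs, thresholds$quantity, thresholds$placement)
  pred <- classify_epoch(values, thresholds)
  cts <- confusion(epochs$gold_label, pred, stage = stage)
  evaluation_report(stage = stage,
                    tp_rate = tp_rate(cts), tn_rate = tn_rate(cts),
                    pap_gold = pap_gold(cts), pap_pred = pap(cts),
                    counts = cts)
}

#' Minimum true positive rate (MTPR)
#'
#' The overall rating for the TP calibration method: the smallest TP
#' rate over the stage-relevant classes. Primary stage:
#' `min(TP_SED, TP_ACTIVE)`. Secondary stage: `min(TP_SED, TP_MV)` --
#' the light class is deliberately excluded because MV classification
#' is prioritized over light.
#'
#' @param report An [evaluation_report()].
#' @return Percent in `[0, 100]`.
#' @export
mtpr <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  if (report$stage == "primary") {
    min(report$tp_rate[["SED"]], report$tp_rate[["ACTIVE"]])
  } else {
    min(report$tp_rate[["SED"]], report$tp_rate[["MV"]])
  }
}

#' PAP match rate (PMR)
#'
#' The overall rating for the PAP calibration method: 100 minus the
#' total absolute deviation between gold-standard and predicted
#' activity proportions over the stage's classes (two terms in the
#' primary stage, three in the secondary). Equals 100 exactly when the
#' predicted proportions match the gold proportions.
#'
#' @param report An [evaluation_report()].
#' @return Percent (at most 100).
#' @export
pmr <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  100 - sum(abs(report$pap_gold - report$pap_pred))
}

#' @export
print.evaluation_report <- function(x, digits = 1, ...) {
  cat(sprintf("<evaluation_report> %s optimization step\n", x$stage))
  tab <- rbind(`TP rate (%)` = x$tp_rate,
               `TN rate (%)` = if (is.null(x$tn_rate)) NA else x$tn_rate,
               `PAP gold (%)` = x$pap_gold,
               `PAP predicted (%)` = x$pap_pred)
  print(round(tab, digits))
  cat(sprintf("MTPR: %.*f   PMR: %.*f\n", digits, mtpr(x), digits, pmr(x)))
  invisible(x)
}
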