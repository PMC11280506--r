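# Confusion counts and the evaluation metrics.

test_that("confusion cross-tabulates exactly", {
  g <- c("SED", "LIGHT", "MV", "SED")
  cts <- confusion(g, g, stage = "secondary")
  expect_equal(unname(diag(cts)), c(2L, 1L, 1L))
  expect_equal(sum(cts), 4L)

  off <- confusion(rep("SED", 5), rep("MV", 5), stage = "secondary")
  expect_equal(off["SED", "MV"], 5L)
  expect_equal(sum(off), 5L)

  # primary stage collapses LIGHT and MV to ACTIVE
  p <- confusion(c("SED", "LIGHT", "MV"), c("MV", "SED", "LIGHT"),
                 stage = "primary")
  expect_equal(p["SED", "ACTIVE"], 1L)
  expect_equal(p["ACTIVE", "SED"], 1L)
  expect_equal(p["ACTIVE", "ACTIVE"], 1L)

  expect_error(confusion(c("SED"), c("SED", "MV")), "equal length")
  expect_error(confusion("WALK", "SED", stage = "secondary"), "invalid label")

  set.seed(41)
  for (k in 1:20) {
    gold <- sample(ACTIVITY_LEVELS, 30, replace = TRUE)
    pred <- sample(ACTIVITY_LEVELS, 30, replace = TRUE)
    cts <- confusion(gold, pred, "secondary")
    expect_equal(unclass(cts)[, ],
                 oracle_confusion(gold, pred, ACTIVITY_LEVELS)[, ])
  }
})

test_that("TP rate is the diagonal over the gold row total", {
  cts <- confusion(c("SED", "SED", "MV", "MV", "MV", "MV", "LIGHT"),
                   c("SED", "SED", "SED", "LIGHT", "MV", "MV", "LIGHT"),
                   "secondary")
  # MV row (1, 1, 2): 2/4 = 50%
  expect_equal(tp_rate(cts, "MV"), 50.0)
  expect_equal(tp_rate(cts, "SED"), 100.0)

  fix <- generate_confusion_fixture(
    "primary", matrix(c(78, 22, 10, 90), 2, byrow = TRUE), seed = 5)
  cts2 <- confusion(fix$gold, fix$predicted, "primary")
  expect_equal(tp_rate(cts2, "SED"), 78.0)   # 78 / (78 + 22)
})

test_that("TN rate counts complement epochs predicted outside the class", {
  g <- c("SED", "LIGHT", "MV")
  diagm <- confusion(g, g, "secondary")
  expect_equal(unname(tn_rate(diagm)), c(100, 100, 100))

  set.seed(42)
  for (k in 1:20) {
    gold <- sample(ACTIVITY_LEVELS, 40, replace = TRUE)
    pred <- sample(ACTIVITY_LEVELS, 40, replace = TRUE)
    cts <- confusion(gold, pred, "secondary")
    for (cl in ACTIVITY_LEVELS) {
      other <- gold != cl
      expect_equal(tn_rate(cts, cl), 100 * sum(other & pred != cl) /
                     sum(other))
    }
  }
})

test_that("two-class TN equals the other class's TP", {
  set.seed(43)
  for (k in 1:20) {
    gold <- sample(ACTIVITY_LEVELS, 50, replace = TRUE)
    pred <- sample(ACTIVITY_LEVELS, 50, replace = TRUE)
    cts <- confusion(gold, pred, "primary")
    expect_equal(tn_rate(cts, "SED"), tp_rate(cts, "ACTIVE"))
    expect_equal(tn_rate(cts, "ACTIVE"), tp_rate(cts, "SED"))
  }
})

test_that("activity proportions use column (predicted) and row (gold) totals", {
  m <- matrix(c(3, 1, 0, 1, 0, 1, 0, 0, 4), 3, byrow = TRUE)
  fix <- generate_confusion_fixture("secondary", m, seed = 7)
  cts <- confusion(fix$gold, fix$predicted, "secondary")
  expect_equal(unname(pap(cts)), c(40, 10, 50))      # columns (4, 1, 5) of 10
  expect_equal(unname(pap_gold(cts)), c(40, 20, 40)) # rows (4, 2, 4) of 10
  expect_equal(sum(pap(cts)), 100)
  expect_equal(sum(pap_gold(cts)), 100)

  g <- c("SED", "LIGHT", "MV")
  d <- confusion(g, g, "secondary")
  expect_equal(pap(d), pap_gold(d))   # diagonal: predicted equals gold
})

test_that("MTPR takes the stage-relevant minimum, excluding light", {
  # rates as printed for the both-legs jerk threshold set (TP method)
  rep1 <- evaluation_report(
    "secondary",
    tp_rate = c(SED = 78.5, LIGHT = 25.8, MV = 77.2),
    pap_gold = c(SED = 40.6, LIGHT = 18.6, MV = 40.8),
    pap_pred = c(SED = 42.0, LIGHT = 10.1, MV = 47.9))
  expect_equal(mtpr(rep1), 77.2)   # min(78.5, 77.2); LIGHT ignored
  # left-leg acceleration-TP rates: the sedentary rate is the minimum
  rep2 <- evaluation_report(
    "secondary",
    tp_rate = c(SED = 70.1, LIGHT = 18.2, MV = 76.6),
    pap_gold = c(SED = 40.6, LIGHT = 18.6, MV = 40.8),
    pap_pred = c(SED = 42.5, LIGHT = 10.7, MV = 46.8))
  expect_equal(mtpr(rep2), 70.1)
  # equal rates: that rate
  rep3 <- evaluation_report(
    "primary", tp_rate = c(SED = 80, ACTIVE = 80),
    pap_gold = c(SED = 50, ACTIVE = 50), pap_pred = c(SED = 50, ACTIVE = 50))
  expect_equal(mtpr(rep3), 80)
  expect_lte(mtpr(rep1), min(rep1$tp_rate[c("SED", "MV")]))
})

test_that("PMR is 100 minus the total proportion deviation", {
  r <- evaluation_report(
    "primary", tp_rate = c(SED = 78.5, ACTIVE = 82.9),
    pap_gold = c(SED = 40.6, ACTIVE = 59.4),
    pap_pred = c(SED = 42.0, ACTIVE = 58.0))
  expect_equal(pmr(r), 97.2)
  perfect <- evaluation_report(
    "primary", tp_rate = c(SED = 90, ACTIVE = 90),
    pap_gold = c(SED = 40, ACTIVE = 60), pap_pred = c(SED = 40, ACTIVE = 60))
  expect_equal(pmr(perfect), 100)

  set.seed(44)
  for (k in 1:20) {
    pg <- as.numeric(table(factor(sample(ACTIVITY_LEVELS, 50, TRUE),
                                  ACTIVITY_LEVELS)))
    pp <- as.numeric(table(factor(sample(ACTIVITY_LEVELS, 50, TRUE),
                                  ACTIVITY_LEVELS)))
    pg <- 100 * pg / sum(pg); pp <- 100 * pp / sum(pp)
    names(pg) <- names(pp) <- ACTIVITY_LEVELS
    r2 <- evaluation_report("secondary",
                            tp_rate = c(SED = 1, LIGHT = 1, MV = 1),
                            pap_gold = pg, pap_pred = pp)
    manual <- 100 - (abs(pg[1] - pp[1]) + abs(pg[2] - pp[2]) +
                       abs(pg[3] - pp[3]))
    expect_equal(pmr(r2), unname(manual))
    expect_lte(pmr(r2), 100)
  }
})

test_that("evaluate_epochs composes classification and tabulation", {
  values <- c(0.2, 0.4, 1.4, 1.9, 3.0, 3.3, 0.8, 2.7)
  gold <- c("SED", "SED", "LIGHT", "LIGHT", "MV", "MV", "LIGHT", "MV")
  ep <- make_epochs(values, gold)
  ths <- threshold_set("acceleration", "both", "PAP", 1.0, 2.6)
  r <- evaluate_epochs(ep, ths, stage = "secondary")
  pred <- classify_epoch(values, ths)
  cts <- confusion(gold, pred, "secondary")
  expect_equal(r$tp_rate, tp_rate(cts))
  expect_equal(r$pap_pred, pap(cts))
  expect_equal(sum(r$pap_pred), 100)
  expect_equal(sum(r$pap_gold), 100)
  rp <- evaluate_epochs(ep, ths, stage = "primary")
  expect_equal(rp$tn_rate[["SED"]], rp$tp_rate[["ACTIVE"]])
})
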