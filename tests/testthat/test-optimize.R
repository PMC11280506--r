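# Cost functions and the two-stage grid search.

test_that("primary TP cost behaves at the extremes and at separation", {
  ep <- make_epochs(c(0.2, 0.3, 0.4, 2.0, 2.5, 3.0),
                    c("SED", "SED", "SED", "LIGHT", "MV", "MV"))
  # candidate below all values: TP_SED = 0, TP_ACTIVE = 100
  expect_equal(cost_tp_primary(ep, "acceleration", "both", 0.01), 100)
  # candidate above all values: TP_SED = 100, TP_ACTIVE = 0
  expect_equal(cost_tp_primary(ep, "acceleration", "both", 10), 100)
  # perfectly separated classes, candidate in the gap: cost 0
  expect_equal(cost_tp_primary(ep, "acceleration", "both", 1.0), 0)
  expect_error(cost_tp_primary(make_epochs(1:3, rep("SED", 3)),
                               "acceleration", "both", 1), "absent")
})

test_that("secondary TP cost matches the frozen reference rate", {
  ep <- make_epochs(c(0.2, 0.3, 1.5, 1.6, 3.0, 3.5),
                    c("SED", "SED", "LIGHT", "LIGHT", "MV", "MV"))
  # candidate at t_primary: every active prediction is MV, TP_MV maximal
  expect_equal(cost_tp_secondary(ep, "acceleration", "both", 1.0, 1.0, 100),
               0)
  # candidate above all values: TP_MV = 0, cost = tp_fixed
  expect_equal(cost_tp_secondary(ep, "acceleration", "both", 1.0, 10, 80),
               80)
  expect_error(cost_tp_secondary(make_epochs(1:2, c("SED", "LIGHT")),
                                 "acceleration", "both", 1, 2, 80), "absent")
})

test_that("PAP costs are zero exactly when predicted counts match gold", {
  ep <- make_epochs(c(0.2, 0.3, 1.5, 1.6, 3.0, 3.5),
                    c("SED", "SED", "LIGHT", "LIGHT", "MV", "MV"))
  expect_equal(cost_pap_primary(ep, "acceleration", "both", 1.0), 0)
  expect_equal(cost_pap_secondary(ep, "acceleration", "both", 1.0, 2.0), 0)
  # all epochs predicted MV: light shortfall 100% plus MV excess
  g_l <- 2; g_m <- 2
  expect_equal(cost_pap_secondary(ep, "acceleration", "both", 0.01, 0.01),
               100 + 100 * abs(g_m - 6) / g_m)
  expect_error(cost_pap_primary(make_epochs(1:3, rep("MV", 3)),
                                "acceleration", "both", 1), "both gold")
})

test_that("all four costs agree with brute-force oracles", {
  set.seed(31)
  for (k in 1:30) {
    re <- random_epoch_set(40)
    ep <- make_epochs(re$values, re$gold)
    t1 <- runif(1, 0, 4); t2 <- t1 + runif(1, 0, 2)
    expect_equal(cost_tp_primary(ep, "acceleration", "both", t1),
                 oracle_cost_tp_primary(re$values, re$gold, t1))
    expect_equal(cost_pap_primary(ep, "acceleration", "both", t1),
                 oracle_cost_pap_primary(re$values, re$gold, t1))
    expect_equal(cost_tp_secondary(ep, "acceleration", "both", t1, t2, 77),
                 oracle_cost_tp_secondary(re$values, re$gold, t1, t2, 77))
    expect_equal(cost_pap_secondary(ep, "acceleration", "both", t1, t2),
                 oracle_cost_pap_secondary(re$values, re$gold, t1, t2))
  }
})

test_that("grid search recovers separating cut-points on disjoint clusters", {
  set.seed(32)
  values <- c(runif(30, 0.1, 0.5), runif(20, 1.2, 1.8), runif(25, 2.8, 3.9))
  gold <- rep(c("SED", "LIGHT", "MV"), c(30, 20, 25))
  ep <- make_epochs(values, gold)
  for (m in c("TP", "PAP")) {
    fit <- fit_thresholds(ep, "acceleration", "both", m)
    t1 <- fit$thresholds$t_sed_active
    t2 <- fit$thresholds$t_light_mv
    # primary: smallest zero-cost candidate, one step above the SED band;
    # secondary: largest zero-cost candidate, one step below the MV band
    expect_gt(t1, max(values[gold == "SED"]))
    expect_lte(t1, max(values[gold == "SED"]) + 0.01 + 1e-12)
    expect_gt(t2, max(values[gold == "LIGHT"]))
    expect_lte(t2, min(values[gold == "MV"]) + 1e-12)
    expect_gt(t2, min(values[gold == "MV"]) - 0.01 - 1e-12)
    # perfect three-class recovery
    pred <- classify_epoch(values, fit$thresholds)
    expect_equal(pred, gold)
  }
  # both methods agree within one grid step on disjoint supports
  t_tp <- fit_thresholds(ep, "acceleration", "both", "TP")$thresholds
  t_pap <- fit_thresholds(ep, "acceleration", "both", "PAP")$thresholds
  expect_lte(abs(t_tp$t_sed_active - t_pap$t_sed_active), 0.01 + 1e-12)
  expect_lte(abs(t_tp$t_light_mv - t_pap$t_light_mv), 0.01 + 1e-12)
  # PAP method reproduces the gold class proportions exactly
  rep_pap <- evaluate_epochs(ep, t_pap, stage = "secondary")
  expect_equal(pmr(rep_pap), 100)
})

test_that("fitted primary TP cost is a local minimum on the grid", {
  set.seed(33)
  re <- random_epoch_set(80)
  ep <- make_epochs(re$values, re$gold)
  fit <- fit_thresholds(ep, "acceleration", "both", "TP")
  curve <- fit$cost_curve_primary
  i <- which(curve$candidate == fit$thresholds$t_sed_active)
  expect_length(i, 1L)
  expect_equal(curve$cost[i], min(curve$cost))
  if (i > 1) expect_lte(curve$cost[i], curve$cost[i - 1])
  if (i < nrow(curve)) expect_lte(curve$cost[i], curve$cost[i + 1])
  # ties break to the smallest candidate
  expect_equal(fit$thresholds$t_sed_active,
               min(curve$candidate[curve$cost == min(curve$cost)]))
})

test_that("secondary cut-point never falls below the primary", {
  set.seed(34)
  for (k in 1:10) {
    re <- random_epoch_set(60)
    ep <- make_epochs(re$values, re$gold)
    for (m in c("TP", "PAP")) {
      fit <- fit_thresholds(ep, "acceleration", "both", m)
      expect_gte(fit$thresholds$t_light_mv, fit$thresholds$t_sed_active)
    }
  }
})

test_that("degenerate label distributions are rejected", {
  expect_error(fit_thresholds(make_epochs(1:5, rep("SED", 5)),
                              "acceleration", "both", "TP"), "absent")
  expect_error(fit_thresholds(make_epochs(1:4, rep(c("SED", "MV"), 2)),
                              "acceleration", "both", "PAP"), "absent")
})

test_that("TP_FIXED is frozen from the primary stage", {
  set.seed(35)
  re <- random_epoch_set(80)
  ep <- make_epochs(re$values, re$gold)
  fit <- fit_thresholds(ep, "acceleration", "both", "TP")
  t1 <- fit$thresholds$t_sed_active
  is_sed <- re$gold == "SED"
  expect_equal(fit$tp_fixed,
               100 * sum(re$values[is_sed] < t1) / sum(is_sed))
  expect_equal(fit$thresholds$tp_fixed, fit$tp_fixed)
  expect_null(fit_thresholds(ep, "acceleration", "both", "PAP")$tp_fixed)
})
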