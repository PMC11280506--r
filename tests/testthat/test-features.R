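# Jerk, window layout, epoch areas, leg combination, classification.

test_that("jerk is the finite difference over the sampling interval", {
  expect_equal(jerk(make_scalar(rep(1.5, 10)))$values, rep(0, 10))
  # ramp of +0.1 m/s^2 per sample at dt = 0.05 -> 2.0 m/s^3
  ramp <- make_scalar(seq(0, 0.9, by = 0.1))
  expect_equal(jerk(ramp)$values, c(0, rep(2.0, 9)))
  set.seed(21)
  x <- rnorm(80)
  j <- jerk(make_scalar(x))$values
  oracle <- c(0, (x[-1] - x[-80]) / 0.05)
  expect_equal(j, oracle)
  expect_error(jerk(make_scalar(1)), "at least 2")
})

test_that("valid windows tile intervals from their start, tails discarded", {
  tr <- annotation_track(0, 4, "SED")
  w <- valid_windows(tr)
  expect_equal(w$start, c(0, 2))
  expect_equal(w$end, c(2, 4))

  tr5 <- annotation_track(0, 5, "LIGHT")
  w5 <- valid_windows(tr5)
  expect_equal(nrow(w5), 2L)     # the trailing 1 s is discarded
  expect_equal(w5$end, c(2, 4))

  tr3 <- suppressWarnings(
    annotation_track(c(0, 2), c(2, 4.9), c("SED", "MV")))
  w3 <- valid_windows(tr3)
  expect_equal(nrow(w3), 2L)     # 1 + 1 windows, 0.9 s discarded
  expect_equal(w3$label, c("SED", "MV"))
})

test_that("window durations plus discarded tails equal annotated time", {
  set.seed(22)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    gaps <- runif(n, 2, 9)
    starts <- cumsum(c(runif(1, 0, 3), gaps[-n]))
    tr <- annotation_track(starts, starts + gaps,
                           sample(ACTIVITY_LEVELS, n, replace = TRUE))
    w <- valid_windows(tr)
    tails <- (tr$end - tr$start) %% 2
    tails[abs(tails - 2) < 1e-9] <- 0
    expect_equal(sum(w$end - w$start) + sum(tails),
                 sum(tr$end - tr$start), tolerance = 1e-9)
  }
})

test_that("epoch area is the rectified Riemann sum", {
  # constant 2 m/s^2 over 2 s -> rectangle of area 4 m/s
  const <- make_scalar(rep(2, 40))
  expect_equal(epoch_area(const, c(0, 2)), 4.0)
  # alternating +-1 integrates to 2 rectified, 0 signed
  alt <- make_scalar(rep(c(1, -1), 20))
  expect_equal(epoch_area(alt, c(0, 2)), 2.0)
  expect_equal(epoch_area(alt, c(0, 2), rectify = FALSE), 0.0)
  # 2-s window at 20 Hz covers exactly 40 samples
  marked <- make_scalar(c(rep(1, 40), rep(100, 10)))
  expect_equal(epoch_area(marked, c(0, 2)), 2.0)
  expect_error(epoch_area(make_scalar(rep(1, 30)), c(0, 2)), "past")

  set.seed(23)
  x <- rnorm(200)
  s <- make_scalar(x)
  for (k in 1:20) {
    i0 <- sample(1:160, 1)
    win <- c((i0 - 1) * 0.05, (i0 - 1) * 0.05 + 2)
    expect_equal(epoch_area(s, win), oracle_area(x, 0.05, i0, 40))
  }
})

test_that("epoch areas are non-negative and scale linearly", {
  set.seed(24)
  x <- rnorm(80)
  a1 <- epoch_area(make_scalar(x), c(0, 2))
  expect_gte(a1, 0)
  expect_equal(epoch_area(make_scalar(3 * x), c(0, 2)), 3 * a1)
})

test_that("leg combination sums for both, passes through for one", {
  expect_equal(combine_legs(1.2, 0.8, "both"), 2.0)
  expect_equal(combine_legs(1.2, 0.8, "left"), 1.2)
  expect_equal(combine_legs(1.2, 0.8, "right"), 0.8)
  expect_error(combine_legs(1.2, NA, "both"), "right-leg")
  expect_equal(combine_legs(1.2, NA, "left"), 1.2)
})

test_that("build_epochs produces closed-form areas on constant signals", {
  dt <- 0.05
  n <- 200   # 10 s
  meta <- subject_meta("s1", "TD", 120, 26.5)
  left <- list(a_adj = make_scalar(rep(2, n), dt), j = NULL)
  left$j <- jerk(left$a_adj)
  right <- list(a_adj = make_scalar(rep(0.5, n), dt), j = NULL)
  right$j <- jerk(right$a_adj)
  tr <- annotation_track(c(0, 4), c(4, 8), c("SED", "MV"))
  ep <- build_epochs(left, right, tr, meta)
  expect_equal(nrow(ep), 4L)     # two 4-s intervals -> 4 records
  expect_equal(ep$c_a_left, rep(4.0, 4))    # 2 m/s^2 x 2 s
  expect_equal(ep$c_a_right, rep(1.0, 4))   # 0.5 m/s^2 x 2 s
  expect_equal(ep$c_a_total, rep(5.0, 4))
  expect_equal(ep$c_j_total, rep(0, 4))     # constant signal: zero jerk
  expect_equal(ep$gold_label, c("SED", "SED", "MV", "MV"))

  # constant-slope signal: jerk area has the closed form |slope| x 2 s
  slope <- 0.1 / dt   # 2 m/s^3
  rampL <- list(a_adj = make_scalar(seq(0, by = 0.1, length.out = n), dt))
  rampL$j <- jerk(rampL$a_adj)
  ep2 <- build_epochs(rampL, right, tr, meta)
  expect_equal(ep2$c_j_left[-1], rep(slope * 2, 3))
  # first window contains the zero-filled initial jerk sample
  expect_equal(ep2$c_j_left[1], slope * 2 - slope * dt)

  # a 1.9-s tail is absent from the records
  tr_tail <- annotation_track(c(0, 4), c(4, 9.9), c("SED", "MV"))
  ep3 <- build_epochs(left, right, tr_tail, meta)
  expect_equal(nrow(ep3), 4L)
  expect_lte(max(ep3$window_end_s), 8)
})

test_that("classification applies left-closed cut-points monotonically", {
  ths <- published_thresholds("acceleration", "both", "PAP")
  expect_equal(ths$t_sed_active, 1.0)
  expect_equal(ths$t_light_mv, 2.6)
  expect_equal(classify_epoch(0.5, ths), "SED")
  expect_equal(classify_epoch(1.5, ths), "LIGHT")
  expect_equal(classify_epoch(2.6, ths), "MV")    # boundary takes higher class
  expect_equal(classify_epoch(1.0, ths), "LIGHT")

  # monotone: a larger value never yields a lower class
  set.seed(25)
  v <- sort(runif(100, 0, 4))
  cls <- match(classify_epoch(v, ths), ACTIVITY_LEVELS)
  expect_true(all(diff(cls) >= 0))
})
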