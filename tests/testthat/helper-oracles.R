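# Fixture builders and independent brute-force oracles used across tests.

make_scalar <- function(values, dt = 0.05, role = "a_ADJ", start_time = 0) {
  scalar_series(values, sample_period = dt, role = role,
                start_time = start_time)
}

# Minimal epoch table whose c_TOTAL columns all equal `values`.
make_epochs <- function(values, gold) {
  tibble::tibble(
    subject_id = "fix",
    window_start_s = 2 * (seq_along(values) - 1),
    window_end_s = 2 * seq_along(values),
    gold_label = gold,
    c_a_left = values / 2, c_a_right = values / 2, c_a_total = values,
    c_j_left = values / 2, c_j_right = values / 2, c_j_total = values
  )
}

# Exhaustive scan: every w-length window checked one by one, covered
# samples collected, then contiguous index runs reported.
oracle_static_segments <- function(x, w = 10, thr = 0.1) {
  n <- length(x)
  covered <- logical(n)
  if (n >= w) {
    for (i in seq_len(n - w + 1L)) {
      win <- x[i:(i + w - 1L)]
      if (max(win) - min(win) <= thr + 1e-12) covered[i:(i + w - 1L)] <- TRUE
    }
  }
  idx <- which(covered)
  if (length(idx) == 0L) return(data.frame(start = integer(0),
                                           end = integer(0)))
  breaks <- which(diff(idx) > 1L)
  data.frame(start = idx[c(1L, breaks + 1L)],
             end = idx[c(breaks, length(idx))])
}

# Independent accumulation of the rectified left-Riemann epoch area.
oracle_area <- function(values, dt, i0, n, rectify = TRUE) {
  acc <- 0
  for (k in seq_len(n)) {
    v <- values[i0 + k - 1L]
    acc <- acc + (if (rectify) abs(v) else v) * dt
  }
  acc
}

# Loop-based confusion tally.
oracle_confusion <- function(gold, pred, levels) {
  m <- matrix(0L, length(levels), length(levels),
              dimnames = list(gold = levels, predicted = levels))
  for (k in seq_along(gold)) {
    m[gold[k], pred[k]] <- m[gold[k], pred[k]] + 1L
  }
  m
}

# Brute-force costs computed straight from confusion cells.
oracle_cost_tp_primary <- function(values, gold, t) {
  pred <- ifelse(values < t, "SED", "ACTIVE")
  g <- ifelse(gold == "SED", "SED", "ACTIVE")
  m <- oracle_confusion(g, pred, c("SED", "ACTIVE"))
  tp_sed <- 100 * m["SED", "SED"] / sum(m["SED", ])
  tp_act <- 100 * m["ACTIVE", "ACTIVE"] / sum(m["ACTIVE", ])
  abs(tp_sed - tp_act)
}

oracle_cost_tp_secondary <- function(values, gold, t1, t2, tp_fixed) {
  pred <- ifelse(values < t1, "SED", ifelse(values < t2, "LIGHT", "MV"))
  m <- oracle_confusion(gold, pred, c("SED", "LIGHT", "MV"))
  tp_mv <- 100 * m["MV", "MV"] / sum(m["MV", ])
  abs(tp_mv - tp_fixed)
}

oracle_cost_pap_primary <- function(values, gold, t) {
  pred <- ifelse(values < t, "SED", "ACTIVE")
  g <- ifelse(gold == "SED", "SED", "ACTIVE")
  m <- oracle_confusion(g, pred, c("SED", "ACTIVE"))
  d_sed <- (sum(m["SED", ]) - sum(m[, "SED"])) / sum(m["SED", ])
  d_act <- (sum(m["ACTIVE", ]) - sum(m[, "ACTIVE"])) / sum(m["ACTIVE", ])
  abs(d_sed) * 100 + abs(d_act) * 100
}

oracle_cost_pap_secondary <- function(values, gold, t1, t2) {
  pred <- ifelse(values < t1, "SED", ifelse(values < t2, "LIGHT", "MV"))
  m <- oracle_confusion(gold, pred, c("SED", "LIGHT", "MV"))
  d_l <- (sum(m["LIGHT", ]) - sum(m[, "LIGHT"])) / sum(m["LIGHT", ])
  d_m <- (sum(m["MV", ]) - sum(m[, "MV"])) / sum(m["MV", ])
  abs(d_l) * 100 + abs(d_m) * 100
}

# Random three-class epoch set with overlapping class distributions.
random_epoch_set <- function(n = 60) {
  gold <- sample(c("SED", "LIGHT", "MV"), n, replace = TRUE,
                 prob = c(0.4, 0.25, 0.35))
  mu <- c(SED = 0.5, LIGHT = 1.6, MV = 3.2)
  values <- abs(stats::rnorm(n, mu[gold], 0.6))
  list(values = values, gold = gold)
}
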