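# Seeded synthetic two-leg sessions with gold annotations.

#' Configuration for a synthetic session
#'
#' Describes a simulated supine free-play session of a pre-ambulatory
#' infant wearing one tri-axial accelerometer per ankle. The movement
#' model is a per-bout sinusoid burst (random frequency and phase)
#' superimposed on a slowly rotating gravity vector plus white axis
#' noise; movement amplitude depends on the bout's intensity class.
#' Defaults mirror the study conditions: 20 Hz sampling, sessions of
#' about 5.5 min, bouts of at least 2 s, class mix of roughly 41%
#' sedentary, 19% light and 40% MV, and a still prefix from which the
#' gravity baseline can be estimated.
#'
#' @param sampling_rate Hz (default 20).
#' @param session_length Seconds (default 330).
#' @param bout_length_range Min/max bout duration in seconds
#'   (default 2-12; the minimum must be at least 2).
#' @param class_proportions Named simplex over `SED`/`LIGHT`/`MV`
#'   giving the probability that a bout belongs to each class.
#' @param amplitudes Named per-class movement amplitudes in m/s^2,
#'   ordered SED < LIGHT < MV.
#' @param amplitude_jitter_sdlog Lognormal sd of per-bout amplitude
#'   jitter (0 disables jitter).
#' @param freq_range Min/max sinusoid frequency in Hz (must stay below
#'   the Nyquist frequency).
#' @param gravity_magnitude m/s^2 (default 9.81).
#' @param orientation_drift_scale Peak gravity-vector tilt in radians
#'   over the session (slow sinusoidal drift).
#' @param noise_sd Axis white-noise sd in m/s^2.
#' @param static_prefix Seconds of guaranteed stillness at the start
#'   (>= 0.5 so a static segment exists); labeled sedentary.
#' @param leg_length_cm Subject leg length in centimeters.
#' @param seed Integer seed; the generated session is a deterministic
#'   function of the configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 20, session_length = 330,
                              bout_length_range = c(2, 12),
                              class_proportions = c(SED = 0.41, LIGHT = 0.19,
                                                    MV = 0.40),
                              amplitudes = c(SED = 0.10, LIGHT = 0.60,
                                             MV = 2.00),
                              amplitude_jitter_sdlog = 0.2,
                              freq_range = c(1, 4),
                              gravity_magnitude = 9.81,
                              orientation_drift_scale = 0.1,
                              noise_sd = 0.05, static_prefix = 2,
                              leg_length_cm = 26.5, seed = 1L) {
  stopifnot(sampling_rate > 0, session_length > 0,
            length(bout_length_range) == 2L, bout_length_range[1] >= 2,
            bout_length_range[1] <= bout_length_range[2],
            bout_length_range[1] <= session_length,
            static_prefix >= 0.5, leg_length_cm > 0, noise_sd >= 0,
            freq_range[1] > 0, freq_range[2] < sampling_rate / 2)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (!all(names(class_proportions) == ACTIVITY_LEVELS) ||
      !all(names(amplitudes) == ACTIVITY_LEVELS)) {
    stop("class_proportions and amplitudes must be named SED, LIGHT, MV",
         call. = FALSE)
  }
  if (is.unsorted(amplitudes, strictly = TRUE)) {
    stop("amplitudes must be strictly increasing SED < LIGHT < MV",
         call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate, session_length = session_length,
         bout_length_range = bout_length_range,
         class_proportions = class_proportions, amplitudes = amplitudes,
         amplitude_jitter_sdlog = amplitude_jitter_sdlog,
         freq_range = freq_range, gravity_magnitude = gravity_magnitude,
         orientation_drift_scale = orientation_drift_scale,
         noise_sd = noise_sd, static_prefix = static_prefix,
         leg_length_cm = leg_length_cm, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a synthetic two-leg session
#'
#' Draws a bout sequence (each bout labeled by its generating intensity
#' class), synthesizes the two per-leg tri-axial signals, and returns
#' the gold annotation track and subject metadata. The session starts
#' with a still prefix whose quiet windows allow gravity estimation;
#' adjacent same-class bouts are merged in the annotation track.
#'
#' Movement is directed along the (slowly tilting) gravity vector, so
#' the acceleration magnitude of the movement signal is controlled
#' exactly by the class amplitude; per-leg phases, frequencies and
#' amplitude jitters are independent.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `left`, `right` ([triaxial_series()]),
#'   `track` ([annotation_track()]), `meta` ([subject_meta()]) and
#'   `truth` (a tibble of per-bout generating parameters: class,
#'   per-leg amplitude and frequency).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    dt <- 1 / config$sampling_rate
    n <- floor(config$session_length / dt)
    t <- (seq_len(n) - 1L) * dt

    # bout sequence: still SED prefix, then random bouts until filled
    snap <- function(x) round(x / dt) * dt
    starts <- numeric(0); ends <- numeric(0); labels <- character(0)
    still <- logical(0)
    cur <- 0
    prefix <- snap(max(config$static_prefix, 2))
    starts <- cur; ends <- prefix; labels <- "SED"; still <- TRUE
    cur <- prefix
    total <- n * dt
    while (total - cur >= config$bout_length_range[1] - 1e-9) {
      len <- snap(stats::runif(1, config$bout_length_range[1],
                               config$bout_length_range[2]))
      len <- min(len, snap(total - cur))
      if (len < config$bout_length_range[1] - 1e-9) break
      lab <- sample(ACTIVITY_LEVELS, 1, prob = config$class_proportions)
      starts <- c(starts, cur); ends <- c(ends, cur + len)
      labels <- c(labels, lab); still <- c(still, FALSE)
      cur <- cur + len
    }

    # per-bout, per-leg movement parameters
    nb <- length(starts)
    truth <- tibble::tibble(
      start = starts, end = ends, label = labels,
      amp_left = ifelse(still, 0, config$amplitudes[labels] *
        exp(stats::rnorm(nb, 0, config$amplitude_jitter_sdlog))),
      amp_right = ifelse(still, 0, config$amplitudes[labels] *
        exp(stats::rnorm(nb, 0, config$amplitude_jitter_sdlog))),
      freq_left = stats::runif(nb, config$freq_range[1], config$freq_range[2]),
      freq_right = stats::runif(nb, config$freq_range[1], config$freq_range[2]),
      phase_left = stats::runif(nb, 0, 2 * pi),
      phase_right = stats::runif(nb, 0, 2 * pi)
    )

    movement <- function(amp, freq, phase) {
      m <- numeric(n)
      for (b in seq_len(nb)) {
        i0 <- round(starts[b] / dt) + 1L
        i1 <- min(round(ends[b] / dt), n)
        if (i0 > i1) next
        tb <- t[i0:i1]
        m[i0:i1] <- amp[b] * sin(2 * pi * freq[b] * tb + phase[b])
      }
      m
    }
    m_left <- movement(truth$amp_left, truth$freq_left, truth$phase_left)
    m_right <- movement(truth$amp_right, truth$freq_right, truth$phase_right)

    # slowly tilting gravity direction in the x-z plane
    theta <- config$orientation_drift_scale *
      sin(2 * pi * t / (2 * config$session_length) +
            stats::runif(1, 0, 2 * pi))
    g <- config$gravity_magnitude

    # axis noise: quiet prefix gets reduced noise so the 10-sample
    # range rule is guaranteed to fire there
    prefix_n <- round(prefix / dt)
    noise_scale <- rep(config$noise_sd, n)
    noise_scale[seq_len(prefix_n)] <- min(config$noise_sd, 0.01)
    axes <- function(m) {
      r <- g + m   # magnitude along the gravity direction
      list(ax = r * sin(theta) + stats::rnorm(n) * noise_scale,
           ay = stats::rnorm(n) * noise_scale,
           az = r * cos(theta) + stats::rnorm(n) * noise_scale)
    }
    al <- axes(m_left)
    ar <- axes(m_right)

    # merge adjacent same-label bouts into annotation intervals
    keep <- c(TRUE, labels[-1L] != labels[-nb])
    astart <- starts[keep]
    aend <- c(astart[-1L], ends[nb])
    alab <- labels[keep]

    list(
      left = triaxial_series(al$ax, al$ay, al$az, sample_period = dt),
      right = triaxial_series(ar$ax, ar$ay, ar$az, sample_period = dt),
      track = annotation_track(astart, aend, alab),
      meta = subject_meta(paste0("sim-", config$seed), group = "TD",
                          age_days = 120,
                          leg_length_cm = config$leg_length_cm),
      truth = truth
    )
  })
}

#' Build label lists with a prescribed confusion matrix
#'
#' Constructs gold and predicted label vectors whose cross-tabulation
#' equals `cell_counts` exactly, in an order shuffled by `seed`. Useful
#' for exercising the evaluation metrics on exactly known counts.
#'
#' @param stage `"primary"` or `"secondary"`.
#' @param cell_counts Square matrix of non-negative integers with gold
#'   classes as rows and predicted classes as columns (2x2 for primary
#'   with classes SED/ACTIVE, 3x3 for secondary with SED/LIGHT/MV).
#'   Dimnames optional; stage order assumed when absent.
#' @param seed Integer seed for the shuffle (`NULL` leaves the
#'   cell-major order).
#' @return A list with character vectors `gold` and `predicted`.
#' @export
generate_confusion_fixture <- function(stage = c("secondary", "primary"),
                                       cell_counts, seed = NULL) {
  stage <- match.arg(stage)
  lev <- stage_levels(stage)
  cell_counts <- as.matrix(cell_counts)
  stopifnot(nrow(cell_counts) == length(lev),
            ncol(cell_counts) == length(lev),
            all(cell_counts >= 0), all(cell_counts == round(cell_counts)))
  gold <- character(0); predicted <- character(0)
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      k <- cell_counts[i, j]
      gold <- c(gold, rep(lev[i], k))
      predicted <- c(predicted, rep(lev[j], k))
    }
  }
  if (!is.null(seed) && length(gold) > 0L) {
    ord <- with_seed(seed, sample.int(length(gold)))
    gold <- gold[ord]; predicted <- predicted[ord]
  }
  list(gold = gold, predicted = predicted)
}
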