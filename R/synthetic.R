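#' Synthetic IMU generator configuration
#'
#' Controls the labelled six-axis trace generator. Defaults describe a
#' 100 Hz waist-worn sensor and a fall whose free-fall (weightless) phase
#' lasts 100--400 ms — comfortably above the 20 ms minimum a free-fall
#' interrupt requires — with an impact peak of 4--8 g.
#'
#' The activity templates are stylised, not biomechanical: sinusoidal gait
#' oscillations for locomotion (class-specific frequency and amplitude),
#' flight/landing cycles for jumping, smooth one-off posture transients for
#' standing up / sitting down, and a four-phase fall (quasi-static 1 g,
#' free fall with all three |a| below the interrupt threshold, impact
#' spike, sub-threshold rest). Additive Gaussian noise is applied per
#' channel, then samples are clipped to the sensor ranges.
#'
#' @param rate sampling frequency in Hz.
#' @param duration_s trace duration in seconds.
#' @param freefall_ms length-2 range (ms) the fall's weightless phase is
#'   drawn from; must stay at or above the free-fall interrupt duration
#'   (20 ms) for falls to be detectable.
#' @param impact_peak_g length-2 range (g) of the fall impact peak.
#' @param noise_sd_g accelerometer noise standard deviation (g).
#' @param noise_sd_dps gyroscope noise standard deviation (deg/s).
#' @return a list of class `imu_generator_config`.
#' @export
generator_config <- function(rate = 100, duration_s = 4,
                             freefall_ms = c(100, 400),
                             impact_peak_g = c(4, 8),
                             noise_sd_g = 0.02, noise_sd_dps = 2) {
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (length(freefall_ms) != 2 || any(freefall_ms <= 0) ||
      freefall_ms[1] > freefall_ms[2]) {
    stop("freefall_ms must be a positive, ordered range", call. = FALSE)
  }
  if (freefall_ms[1] < 20) {
    stop("freefall_ms must be >= 20 ms so generated falls are detectable",
         call. = FALSE)
  }
  if (length(impact_peak_g) != 2 || impact_peak_g[1] > impact_peak_g[2]) {
    stop("impact_peak_g must be an ordered range", call. = FALSE)
  }
  structure(list(rate = rate, duration_s = duration_s,
                 freefall_ms = freefall_ms, impact_peak_g = impact_peak_g,
                 noise_sd_g = noise_sd_g, noise_sd_dps = noise_sd_dps),
            class = "imu_generator_config")
}

# smooth unit bump on [0,1] (raised cosine)
.bump <- function(u) ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)

# Gait-style template: vertical-axis oscillation about 1 g with an
# anti-phase fore-aft component sized so that no 20 ms window ever has all
# three |a| below the 0.563 g free-fall threshold.
.gait <- function(t, f, az_amp, ax_amp, ay_amp, g_amp, phase) {
  w <- 2 * pi * f
  cbind(ax = -ax_amp * sin(w * t + phase),
        ay = ay_amp * cos(w * t + phase),
        az = 1 + az_amp * sin(w * t + phase),
        gx = g_amp * sin(w * t + phase),
        gy = 0.6 * g_amp * sin(w * t + phase + 1.1),
        gz = 0.4 * g_amp * cos(w * t + phase + 0.4))
}

# Posture transition (sit<->stand): quasi-static 1 g with one smooth
# vertical bump/dip pair and a pitch-rate pulse of the given sign.
.transition <- function(t, sign, phase) {
  t0 <- 1.2 + 0.4 * .bump(phase / (2 * pi)) # onset jitter from phase
  u <- (t - t0) / 1.0
  az <- 1 + sign * (0.45 * .bump(u) - 0.25 * .bump(u - 0.5))
  ax <- 0.15 * sign * .bump(u + 0.15)
  gx <- sign * 80 * .bump(u)
  cbind(ax = ax, ay = rep(0, length(t)), az = az,
        gx = gx, gy = 0.25 * gx, gz = rep(0, length(t)))
}

.jump_template <- function(t, phase) {
  period <- 0.9
  u <- ((t + phase / (2 * pi) * period) %% period) / period
  flight <- u < 0.3                       # airborne: ~0 g for 270 ms
  land <- u >= 0.3 & u < 0.36             # landing spike
  az <- ifelse(flight, 0.06, ifelse(land, 3.0, 1 + 0.1 * sin(2 * pi * u)))
  ax <- ifelse(flight, 0.03, ifelse(land, 0.8, 0.1 * sin(4 * pi * u)))
  gx <- ifelse(flight, 25, 60 * .bump((u - 0.3) / 0.3))
  cbind(ax = ax, ay = 0.05 * cos(2 * pi * u), az = az,
        gx = gx, gy = 0.3 * gx, gz = rep(5, length(t)))
}

.fall_template <- function(t, rate, config) {
  n <- length(t)
  ff_dur <- stats::runif(1, config$freefall_ms[1], config$freefall_ms[2]) / 1000
  peak <- stats::runif(1, config$impact_peak_g[1], config$impact_peak_g[2])
  t_pre <- stats::runif(1, 1.0, 1.4)      # upright quasi-static phase
  t_imp <- 0.10                           # impact + ring-down
  m <- matrix(0, n, 6)
  pre <- t < t_pre
  ff <- t >= t_pre & t < t_pre + ff_dur
  imp <- t >= t_pre + ff_dur & t < t_pre + ff_dur + t_imp
  rest <- t >= t_pre + ff_dur + t_imp
  # upright: gravity on the vertical axis, negligible rotation
  m[pre, 3] <- 1
  # weightless: all axes well below the 0.563 g threshold; body rotates
  m[ff, 1:3] <- 0.08
  m[ff, 4] <- -220
  m[ff, 5] <- 90
  # impact: decaying spike on the vertical axis plus a fore-aft jolt
  if (any(imp)) {
    u <- (t[imp] - t[imp][1]) / t_imp   # first impact sample carries the peak
    m[imp, 3] <- peak * exp(-6 * u)
    m[imp, 1] <- 0.35 * peak * exp(-8 * u)
    m[imp, 4] <- -80 * exp(-5 * u)
  }
  # post-impact rest: motionless, with residual axis readings kept below
  # the 0.5 g zero-motion threshold (emulating the gravity-compensated
  # stillness detection of the sensor; see the package vignette)
  m[rest, 1] <- 0.25
  m[rest, 2] <- 0.12
  m[rest, 3] <- 0.18
  colnames(m) <- imu_channels()
  m
}

#' Generate a labelled synthetic IMU trace
#'
#' Produces one trace of a single activity with the kinematic structure the
#' interrupt engine and the classifier assume. Identical
#' `(activity, config, seed)` triples reproduce identical traces.
#'
#' Falling traces contain, in order: a quasi-static ~1 g phase, a
#' weightless phase with all three |acceleration| below 0.563 g lasting at
#' least the configured free-fall duration, an impact spike exceeding the
#' configured peak range minimum, and a motionless rest phase that
#' satisfies the zero-motion interrupt condition. Walking and other gait
#' activities are constructed so that no 20 ms window has all three axes
#' below the free-fall threshold; jumping legitimately contains airborne
#' (near 0 g) phases and may trigger free-fall interrupts.
#'
#' @param activity one of [activity_labels()].
#' @param config an [generator_config()].
#' @param seed integer seed; fully determines the trace.
#' @return an [imu_trace()] with a single segment covering the whole trace.
#' @examples
#' tr <- generate_trace("falling", seed = 1)
#' tr
#' @export
generate_trace <- function(activity, config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "imu_generator_config"))
  activity <- match.arg(activity, activity_labels())
  n <- round(config$duration_s * config$rate)
  t <- (seq_len(n) - 1) / config$rate
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    m <- switch(activity,
      walking = .gait(t, f = 1.8, az_amp = 0.25, ax_amp = 0.30,
                      ay_amp = 0.12, g_amp = 40, phase = phase),
      jogging = .gait(t, f = 3.0, az_amp = 0.50, ax_amp = 0.75,
                      ay_amp = 0.20, g_amp = 120, phase = phase),
      jumping = .jump_template(t, phase),
      going_upstairs = .gait(t, f = 1.2, az_amp = 0.30, ax_amp = 0.40,
                             ay_amp = 0.08, g_amp = 60, phase = phase),
      going_downstairs = .gait(t, f = 2.4, az_amp = 0.35, ax_amp = 0.55,
                               ay_amp = 0.28, g_amp = 80, phase = phase),
      standing_up = .transition(t, sign = +1, phase = phase),
      sitting_down = .transition(t, sign = -1, phase = phase),
      falling = .fall_template(t, config$rate, config))
    noise <- cbind(matrix(stats::rnorm(3 * n, 0, config$noise_sd_g), n),
                   matrix(stats::rnorm(3 * n, 0, config$noise_sd_dps), n))
    imu_trace(m + noise, rate = config$rate,
              segments = data.frame(start = 1L, end = n, label = activity))
  })
}

#' Generate a balanced, windowed, labelled dataset
#'
#' Generates traces for all eight activities, conditions them with the
#' standard server-side chain (range normalization to \[0, 1\] and a
#' moving-average filter), cuts sliding windows and assigns a stratified
#' train/validation/test split. Class balance is exact: `per_class` windows
#' per activity.
#'
#' @param per_class number of windows per activity class.
#' @param config an [generator_config()].
#' @param window a [window_spec()]; the default is a 2 s window (200
#'   samples at 100 Hz) with 50% overlap.
#' @param split length-3 fractions (train, validation, test); default
#'   70/10/20.
#' @param condition apply range normalization and the moving-average filter
#'   (`M = 5`) before windowing (default `TRUE`); set `FALSE` for raw
#'   windows in sensor units.
#' @param seed integer seed; fully determines the dataset, including the
#'   split.
#' @return a list of class `imu_window_set` with elements `x` (array
#'   `n_windows x length x 6`), `label` (integer codes 0--7), `activity`
#'   (labels), and `split` (factor with levels train/validation/test).
#' @examples
#' ds <- generate_dataset(per_class = 3, seed = 1)
#' table(ds$activity)
#' @export
generate_dataset <- function(per_class, config = generator_config(),
                             window = window_spec(rate = config$rate),
                             split = c(0.7, 0.1, 0.2), condition = TRUE,
                             seed = 1) {
  if (per_class < 1) stop("per_class must be >= 1", call. = FALSE)
  if (length(split) != 3 || any(split < 0) || abs(sum(split) - 1) > 1e-8) {
    stop("split must be three non-negative fractions summing to 1",
         call. = FALSE)
  }
  n_trace <- round(config$duration_s * config$rate)
  if (window$length > n_trace) {
    stop("window longer than generated traces", call. = FALSE)
  }
  per_trace <- floor((n_trace - window$length) / window$stride) + 1
  n_traces <- ceiling(per_class / per_trace)
  acts <- activity_labels()
  xs <- vector("list", length(acts))
  for (a in seq_along(acts)) {
    wins <- vector("list", n_traces)
    for (i in seq_len(n_traces)) {
      tr <- generate_trace(acts[a], config,
                           seed = derive_seed(seed, a - 1L, i))
      if (condition) {
        tr$samples <- moving_average(
          normalize_channels(tr$samples, normalization_spec()),
          filter_spec(5))
      }
      wins[[i]] <- assemble_windows(tr, window)
    }
    w <- do.call(c, wins)
    xs[[a]] <- w[seq_len(per_class)]
  }
  len <- window$length
  x <- array(0, c(per_class * length(acts), len, 6),
             dimnames = list(NULL, NULL, imu_channels()))
  k <- 0L
  for (a in seq_along(acts)) {
    for (w in xs[[a]]) {
      k <- k + 1L
      x[k, , ] <- w$data
    }
  }
  activity <- rep(acts, each = per_class)
  # stratified split, exact counts per class
  n1 <- round(per_class * split[1])
  n2 <- round(per_class * split[2])
  n3 <- per_class - n1 - n2
  sp <- character(per_class * length(acts))
  with_seed(derive_seed(seed, "split"), {
    for (a in seq_along(acts)) {
      idx <- (a - 1L) * per_class + sample.int(per_class)
      sp[idx] <- rep(c("train", "validation", "test"), c(n1, n2, n3))
    }
  })
  structure(list(x = x, label = activity_code(activity), activity = activity,
                 split = factor(sp, levels = c("train", "validation", "test")),
                 window = window, conditioned = condition),
            class = "imu_window_set")
}

#' Persist window sets with shape metadata
#'
#' Window tensors are stored in R's native serialization format wrapped in
#' an explicit container: fields `shape` (`n, length, channels`),
#' `channels` (names), `label`, `activity`, `split`, `conditioned` and the
#' tensor `x` itself, so a reader can validate the geometry before use.
#'
#' @param ws an `imu_window_set` (from [generate_dataset()] or
#'   [cmd_preprocess()]).
#' @param path output file (conventionally `.rds`).
#' @return `read_window_set()` returns the `imu_window_set`.
#' @export
write_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "imu_window_set"))
  obj <- list(container = "imu_window_set", version = 1L,
              shape = dim(ws$x), channels = dimnames(ws$x)[[3]],
              label = ws$label, activity = ws$activity, split = ws$split,
              conditioned = ws$conditioned, window = ws$window, x = ws$x)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container, "imu_window_set")) {
    stop("not an imu_window_set container", call. = FALSE)
  }
  if (!identical(dim(obj$x), obj$shape)) {
    stop("corrupt container: tensor shape does not match metadata",
         call. = FALSE)
  }
  structure(list(x = obj$x, label = obj$label, activity = obj$activity,
                 split = obj$split, window = obj$window,
                 conditioned = obj$conditioned),
            class = "imu_window_set")
}

#' @export
print.imu_window_set <- function(x, ...) {
  cat(sprintf("<imu_window_set> %d windows of %d x 6 (%s)\n",
              dim(x$x)[1], dim(x$x)[2],
              if (isTRUE(x$conditioned)) "conditioned" else "raw"))
  print(table(split = x$split, activity = x$activity))
  invisible(x)
}
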