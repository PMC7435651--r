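#' Interrupt register configuration
#'
#' Thresholds and durations of the MPU6050-style interrupt registers driving
#' the duty-cycled transmission scheduler, plus FIFO geometry. Defaults
#' mirror a 100 Hz waist-worn module: free fall fires when all three
#' |acceleration| axes stay below `ff_thr_g` (0.563 g) for `ff_dur_ms`
#' (20 ms); motion fires when any axis exceeds `mot_thr_g` for
#' `mot_dur_ms`; zero motion fires when all three axes stay below
#' `zrmot_thr_g` (0.5 g) for `zrmot_dur_ms` (1000 ms). The 0.563 g default
#' sits just below 1/sqrt(3) g, the worst-case largest axis component of
#' static gravity (see [min_max_gravity_component()]), so an oddly oriented
#' resting sensor can never satisfy the free-fall condition.
#'
#' The FIFO holds `fifo_cnt_bytes` of interleaved 16-bit samples across all
#' `channels`; at the defaults, 600 bytes = 50 six-channel sample sets =
#' 0.5 s at 100 Hz (see [fifo_span_seconds()]).
#'
#' Gyroscope channels never participate in interrupt conditions.
#'
#' @param ff_thr_g,ff_dur_ms free-fall threshold (g) and duration (ms).
#' @param mot_thr_g,mot_dur_ms motion threshold (g) and duration (ms).
#' @param zrmot_thr_g,zrmot_dur_ms zero-motion threshold (g) and duration (ms).
#' @param fifo_cnt_bytes FIFO watermark in bytes.
#' @param rate sampling rate in Hz.
#' @param channels number of interleaved channels in the FIFO.
#' @param bits_per_value sample width in bits.
#' @param gravity_compensated if `TRUE`, interrupt conditions are evaluated
#'   on acceleration with a running gravity estimate (1 s mean per axis)
#'   subtracted, resolving the tension between the literal zero-motion
#'   condition and the 1 g static field. Default `FALSE` (literal register
#'   semantics).
#' @return a list of class `interrupt_config`.
#' @export
interrupt_config <- function(ff_thr_g = 0.563, ff_dur_ms = 20,
                             mot_thr_g = 2.0, mot_dur_ms = 20,
                             zrmot_thr_g = 0.5, zrmot_dur_ms = 1000,
                             fifo_cnt_bytes = 600, rate = 100,
                             channels = 6, bits_per_value = 16,
                             gravity_compensated = FALSE) {
  thr <- c(ff_thr_g, mot_thr_g, zrmot_thr_g)
  dur <- c(ff_dur_ms, mot_dur_ms, zrmot_dur_ms)
  if (any(thr <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (any(dur < 1000 / rate)) {
    stop("durations must be at least one sample period", call. = FALSE)
  }
  set_bytes <- channels * bits_per_value / 8
  if (fifo_cnt_bytes %% set_bytes != 0) {
    warning("fifo_cnt_bytes not divisible by one sample set (",
            set_bytes, " bytes); capacity rounded down", call. = FALSE)
  }
  structure(list(ff_thr_g = ff_thr_g, ff_dur_ms = ff_dur_ms,
                 mot_thr_g = mot_thr_g, mot_dur_ms = mot_dur_ms,
                 zrmot_thr_g = zrmot_thr_g, zrmot_dur_ms = zrmot_dur_ms,
                 fifo_cnt_bytes = fifo_cnt_bytes, rate = rate,
                 channels = channels, bits_per_value = bits_per_value,
                 gravity_compensated = gravity_compensated),
            class = "interrupt_config")
}

# samples needed for a duration register: condition must hold for
# >= ceil(dur * rate) consecutive samples (conservative register semantics)
.dur_samples <- function(dur_ms, rate) max(1L, as.integer(ceiling(dur_ms / 1000 * rate)))

# FIFO capacity in sample sets
.fifo_capacity <- function(config) {
  max(1L, as.integer(config$fifo_cnt_bytes %/%
                       (config$channels * config$bits_per_value / 8)))
}

# acceleration matrix used for interrupt conditions, optionally with a
# running 1 s mean removed per axis
.interrupt_accel <- function(trace, config) {
  a <- trace$samples[, 1:3, drop = FALSE]
  if (isTRUE(config$gravity_compensated)) {
    m <- round(config$rate)
    a <- a - apply(a, 2, function(x) moving_average(x, filter_spec(m)))
  }
  a
}

# indices (1-based) where `cond` has held for exactly `need` consecutive
# samples since it last became true, with latch re-arming: after a fire the
# run must break before the same interrupt can fire again.
.fire_indices <- function(cond, need) {
  if (!length(cond)) return(integer())
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fire_runs <- which(r$values & r$lengths >= need)
  starts[fire_runs] + need - 1L
}

#' Scan a trace for interrupt events
#'
#' Applies the three acceleration-based interrupt conditions sample by
#' sample and reports, for each kind, every position where the condition
#' has held continuously for its configured duration. An interrupt latches:
#' after firing, it re-arms only once its condition has been broken for at
#' least one sample. At 100 Hz the 20 ms free-fall duration corresponds to
#' exactly 2 consecutive qualifying samples.
#'
#' `sample_index` in the result is 0-based (the on-wire sample counter), so
#' a free-fall condition beginning at 0-based index 100 with a 2-sample
#' duration fires at index 101.
#'
#' @param trace an [imu_trace()].
#' @param config an [interrupt_config()]; its `rate` must equal the trace's.
#' @return a `data.frame` of class `interrupt_events` with columns `kind`
#'   (`free_fall`, `motion`, `zero_motion`), `sample_index` (0-based) and
#'   `time_s`, sorted by index (free fall first on ties).
#' @export
scan_interrupts <- function(trace, config = interrupt_config()) {
  stopifnot(inherits(trace, "imu_trace"), inherits(config, "interrupt_config"))
  if (trace$rate != config$rate) {
    stop("trace rate (", trace$rate, " Hz) does not match config rate (",
         config$rate, " Hz)", call. = FALSE)
  }
  a <- abs(.interrupt_accel(trace, config))
  if (!nrow(a)) {
    return(.as_events(data.frame(kind = character(), sample_index = integer(),
                                 time_s = numeric())))
  }
  conds <- list(
    free_fall = a[, 1] < config$ff_thr_g & a[, 2] < config$ff_thr_g &
      a[, 3] < config$ff_thr_g,
    motion = a[, 1] > config$mot_thr_g | a[, 2] > config$mot_thr_g |
      a[, 3] > config$mot_thr_g,
    zero_motion = a[, 1] < config$zrmot_thr_g & a[, 2] < config$zrmot_thr_g &
      a[, 3] < config$zrmot_thr_g)
  needs <- c(free_fall = .dur_samples(config$ff_dur_ms, config$rate),
             motion = .dur_samples(config$mot_dur_ms, config$rate),
             zero_motion = .dur_samples(config$zrmot_dur_ms, config$rate))
  ev <- do.call(rbind, lapply(names(conds), function(k) {
    idx <- .fire_indices(conds[[k]], needs[[k]])
    if (!length(idx)) return(NULL)
    data.frame(kind = k, sample_index = idx - 1L,
               time_s = (idx - 1L) / config$rate)
  }))
  if (is.null(ev)) {
    ev <- data.frame(kind = character(), sample_index = integer(),
                     time_s = numeric())
  }
  prio <- match(ev$kind, c("free_fall", "motion", "zero_motion"))
  ev <- ev[order(ev$sample_index, prio), , drop = FALSE]
  rownames(ev) <- NULL
  .as_events(ev)
}

.as_events <- function(df) {
  class(df) <- c("interrupt_events", "data.frame")
  df
}

#' Run the duty-cycled transmission state machine over a trace
#'
#' Simulates, one sample at a time, the two-state scheduler that decides
#' when the radio transmits. In the monitoring state (`F0`) samples are
#' continuously buffered in a FIFO with oldest-overwritten semantics while
#' free-fall, motion and FIFO interrupts are armed and zero motion is
#' disabled. When a free-fall or motion interrupt fires, the buffered FIFO
#' contents are transmitted, zero motion is enabled, and the machine enters
#' the transmitting state (`F1`): every subsequent FIFO fill is flushed to
#' the radio until a zero-motion interrupt fires, upon which the machine
#' returns to `F0`. The zero-motion duration counter runs only while that
#' interrupt is enabled.
#'
#' @inheritParams scan_interrupts
#' @return a list of class `transmission_log`: `ranges` (two-column matrix
#'   of half-open, 0-based `[start, end)` transmitted sample ranges),
#'   `radio_on_samples`, `mcu_awake_samples` (samples spent in `F1`),
#'   `buffered_samples` (total sensed), `events` (the interrupt events that
#'   drove transitions), `n` (trace length) and `rate`.
#' @export
run_fsm <- function(trace, config = interrupt_config()) {
  stopifnot(inherits(trace, "imu_trace"), inherits(config, "interrupt_config"))
  if (trace$rate != config$rate) {
    stop("trace rate (", trace$rate, " Hz) does not match config rate (",
         config$rate, " Hz)", call. = FALSE)
  }
  a <- abs(.interrupt_accel(trace, config))
  n <- nrow(a)
  cap <- .fifo_capacity(config)
  need_ff <- .dur_samples(config$ff_dur_ms, config$rate)
  need_mot <- .dur_samples(config$mot_dur_ms, config$rate)
  need_zr <- .dur_samples(config$zrmot_dur_ms, config$rate)
  ff_cond <- if (n) a[, 1] < config$ff_thr_g & a[, 2] < config$ff_thr_g &
    a[, 3] < config$ff_thr_g else logical()
  mot_cond <- if (n) a[, 1] > config$mot_thr_g | a[, 2] > config$mot_thr_g |
    a[, 3] > config$mot_thr_g else logical()
  zr_cond <- if (n) a[, 1] < config$zrmot_thr_g & a[, 2] < config$zrmot_thr_g &
    a[, 3] < config$zrmot_thr_g else logical()

  state <- "F0"
  run_ff <- 0L; armed_ff <- TRUE
  run_mot <- 0L; armed_mot <- TRUE
  run_zr <- 0L; armed_zr <- TRUE
  buf_start <- 1L   # 1-based index of the oldest sample held in the FIFO
  buf_len <- 0L
  awake <- 0L
  ranges <- list()
  events <- list()
  flush <- function(i) {
    # transmit current FIFO contents [buf_start, i] and empty the buffer
    if (buf_len > 0L) {
      ranges[[length(ranges) + 1L]] <<- c(buf_start - 1L, i)  # 0-based half-open
    }
    buf_start <<- i + 1L
    buf_len <<- 0L
  }
  for (i in seq_len(n)) {
    # buffer the new sample (oldest overwritten beyond capacity)
    buf_len <- buf_len + 1L
    if (buf_len > cap) {
      buf_len <- cap
      buf_start <- i - cap + 1L
    }
    if (state == "F1") awake <- awake + 1L
    # duration counters with latch re-arming
    if (ff_cond[i]) run_ff <- run_ff + 1L else { run_ff <- 0L; armed_ff <- TRUE }
    if (mot_cond[i]) run_mot <- run_mot + 1L else { run_mot <- 0L; armed_mot <- TRUE }
    fired_ff <- armed_ff && run_ff >= need_ff
    fired_mot <- armed_mot && run_mot >= need_mot
    if (state == "F0") {
      run_zr <- 0L; armed_zr <- TRUE   # zero motion disabled in F0
      if (fired_ff || fired_mot) {
        kind <- if (fired_ff) "free_fall" else "motion"  # free fall wins ties
        if (fired_ff) armed_ff <- FALSE
        if (fired_mot) armed_mot <- FALSE
        events[[length(events) + 1L]] <-
          data.frame(kind = kind, sample_index = i - 1L,
                     time_s = (i - 1L) / config$rate)
        flush(i)
        state <- "F1"
        awake <- awake + 1L  # woken by this sample
      }
    } else {
      if (fired_ff) armed_ff <- FALSE
      if (fired_mot) armed_mot <- FALSE
      if (zr_cond[i]) run_zr <- run_zr + 1L else { run_zr <- 0L; armed_zr <- TRUE }
      if (armed_zr && run_zr >= need_zr) {
        armed_zr <- FALSE
        events[[length(events) + 1L]] <-
          data.frame(kind = "zero_motion", sample_index = i - 1L,
                     time_s = (i - 1L) / config$rate)
        state <- "F0"
      } else if (buf_len >= cap) {
        flush(i)  # FIFO interrupt: flush to the radio while transmitting
      }
    }
  }
  ranges <- if (length(ranges)) do.call(rbind, ranges) else
    matrix(integer(), 0, 2)
  colnames(ranges) <- c("start", "end")
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), sample_index = integer(), time_s = numeric())
  structure(list(ranges = ranges,
                 radio_on_samples = sum(ranges[, 2] - ranges[, 1]),
                 mcu_awake_samples = awake,
                 buffered_samples = n,
                 events = .as_events(events),
                 n = n, rate = config$rate),
            class = "transmission_log")
}

#' @export
print.transmission_log <- function(x, ...) {
  cat(sprintf("<transmission_log> %d/%d samples transmitted (duty cycle %.3f)\n",
              x$radio_on_samples, x$n, duty_cycle(x, x$n)))
  cat(sprintf("  %d transmitted range(s), %d event(s), MCU awake %d samples\n",
              nrow(x$ranges), nrow(x$events), x$mcu_awake_samples))
  invisible(x)
}

#' Time span covered by a FIFO buffer
#'
#' How many seconds of interleaved multi-channel data a FIFO watermark
#' holds: `capacity_bytes / (rate * channels * bits_per_value / 8)`. At the
#' module defaults, 600 bytes at 100 Hz with six 16-bit channels span
#' exactly 0.5 s.
#'
#' @param capacity_bytes FIFO watermark in bytes.
#' @param rate sampling rate in Hz.
#' @param channels number of interleaved channels.
#' @param bits_per_value sample width in bits.
#' @return span in seconds. A capacity not divisible by one sample set
#'   raises a warning and returns the fractional span.
#' @examples
#' fifo_span_seconds(600, 100, 6, 16)  # 0.5
#' @export
fifo_span_seconds <- function(capacity_bytes, rate = 100, channels = 6,
                              bits_per_value = 16) {
  if (rate <= 0 || channels <= 0 || bits_per_value <= 0) {
    stop("rate, channels and bits_per_value must be positive", call. = FALSE)
  }
  if (capacity_bytes < 0) stop("capacity_bytes must be >= 0", call. = FALSE)
  set_bytes <- channels * bits_per_value / 8
  if (capacity_bytes %% set_bytes != 0) {
    warning("capacity is not a whole number of sample sets; ",
            "returning fractional span", call. = FALSE)
  }
  capacity_bytes / (rate * set_bytes)
}

#' Worst-case largest axis component of static gravity
#'
#' Over all orientations of a resting sensor, the largest absolute axis
#' reading of the 1 g gravity vector is smallest when gravity makes equal
#' angles with all three axes, giving 1/sqrt(3) = 0.57735 g. Any free-fall
#' threshold below this value can never be satisfied by a stationary
#' sensor, whatever its orientation — the rationale for the 0.563 g
#' default.
#'
#' @return the scalar `1/sqrt(3)`.
#' @examples
#' min_max_gravity_component()
#' @export
min_max_gravity_component <- function() 1 / sqrt(3)

#' Radio duty cycle of a transmission log
#'
#' Fraction of sensed samples that were transmitted — the simulator's proxy
#' for radio energy. An always-transmit baseline has duty cycle 1; an idle
#' trace has 0.
#'
#' @param log a `transmission_log` from [run_fsm()].
#' @param trace_length total number of sensed samples (defaults to the
#'   log's own length).
#' @return a fraction in `[0, 1]`.
#' @export
duty_cycle <- function(log, trace_length = log$n) {
  stopifnot(inherits(log, "transmission_log"))
  if (trace_length <= 0) stop("trace_length must be positive", call. = FALSE)
  log$radio_on_samples / trace_length
}

#' Export interrupt events and transmission logs as JSON
#'
#' Events are written as JSON lines (one object per event with fields
#' `kind`, `sample_index`, `time_s`); a transmission log as a single JSON
#' object with `ranges`, `radio_on_samples` and `duty_cycle`.
#'
#' @param events an `interrupt_events` data frame.
#' @param log a `transmission_log`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
write_transmission_json <- function(log, path) {
  stopifnot(inherits(log, "transmission_log"))
  obj <- list(ranges = unname(apply(log$ranges, 1, as.list, simplify = FALSE)),
              radio_on_samples = log$radio_on_samples,
              duty_cycle = duty_cycle(log))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
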