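#' Six-axis IMU traces
#'
#' An `imu_trace` bundles a sampled six-channel inertial stream with its
#' sampling rate and labelled activity segments. Channels are, in order,
#' `ax, ay, az` (acceleration, g) and `gx, gy, gz` (angular velocity,
#' deg/s) in the waist-worn coordinate convention used throughout the
#' package. The sensor is an MPU6050-class part: accelerations are clipped
#' to +/-16 g and angular velocities to +/-2000 deg/s.
#'
#' Segment indices are 1-based and inclusive, must be non-overlapping and
#' within bounds. Interrupt events and transmission logs produced from a
#' trace use 0-based sample counters (see [scan_interrupts()]).
#'
#' @param samples numeric matrix with 6 columns (`ax, ay, az, gx, gy, gz`).
#' @param rate sampling frequency in Hz (default 100).
#' @param segments `data.frame` with columns `start`, `end` (1-based,
#'   inclusive) and `label` (activity string), or `NULL` for an unlabelled
#'   trace.
#' @param clip clip samples to the sensor ranges (default `TRUE`).
#' @return an object of class `imu_trace`.
#' @seealso [generate_trace()], [read_imu_csv()], [write_imu_csv()]
#' @export
imu_trace <- function(samples, rate = 100, segments = NULL, clip = TRUE) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 6) stop("samples must have 6 columns", call. = FALSE)
  if (!is.numeric(samples)) stop("samples must be numeric", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a positive scalar (Hz)", call. = FALSE)
  }
  colnames(samples) <- imu_channels()
  if (clip && nrow(samples)) {
    samples[, 1:3] <- pmin(pmax(samples[, 1:3], -16), 16)
    samples[, 4:6] <- pmin(pmax(samples[, 4:6], -2000), 2000)
  }
  if (!is.null(segments)) {
    segments <- as.data.frame(segments)
    stopifnot(all(c("start", "end", "label") %in% names(segments)))
    segments <- segments[order(segments$start), , drop = FALSE]
    rownames(segments) <- NULL
    bad <- segments$start < 1 | segments$end > nrow(samples) |
      segments$start > segments$end
    if (any(bad)) stop("segment indices out of bounds", call. = FALSE)
    if (nrow(segments) > 1 &&
        any(segments$start[-1] <= segments$end[-nrow(segments)])) {
      stop("segments overlap", call. = FALSE)
    }
    activity_code(segments$label)  # validates labels
  }
  structure(list(samples = samples, rate = rate, segments = segments),
            class = "imu_trace")
}

imu_channels <- function() c("ax", "ay", "az", "gx", "gy", "gz")

#' @export
print.imu_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<imu_trace> %d samples @ %g Hz (%.2f s)\n",
              n, x$rate, n / x$rate))
  if (!is.null(x$segments) && nrow(x$segments)) {
    cat("segments:\n")
    for (i in seq_len(nrow(x$segments))) {
      s <- x$segments[i, ]
      cat(sprintf("  [%d, %d] %s\n", s$start, s$end, s$label))
    }
  } else {
    cat("(unlabelled)\n")
  }
  invisible(x)
}

#' @export
length.imu_trace <- function(x) nrow(x$samples)

# per-sample label vector; NA outside segments
trace_labels <- function(trace) {
  lab <- rep(NA_character_, nrow(trace$samples))
  if (!is.null(trace$segments)) {
    for (i in seq_len(nrow(trace$segments))) {
      s <- trace$segments[i, ]
      lab[s$start:s$end] <- s$label
    }
  }
  lab
}

#' Read and write IMU traces as CSV
#'
#' The on-disk format is a plain CSV with header
#' `t,ax,ay,az,gx,gy,gz,label`: `t` in seconds, accelerations in g,
#' angular velocities in deg/s, `label` the activity string or empty for
#' unlabelled samples. The writer/reader pair round-trips a trace exactly
#' (up to 15 significant digits).
#'
#' @param trace an [imu_trace()].
#' @param path file path.
#' @return `read_imu_csv()` returns an `imu_trace`; `write_imu_csv()`
#'   returns `path` invisibly.
#' @export
write_imu_csv <- function(trace, path) {
  stopifnot(inherits(trace, "imu_trace"))
  lab <- trace_labels(trace)
  lab[is.na(lab)] <- ""
  n <- nrow(trace$samples)
  df <- data.frame(t = (seq_len(n) - 1) / trace$rate, trace$samples,
                   label = lab, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @param rate sampling rate override; by default inferred from the `t`
#'   column spacing.
#' @export
read_imu_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", imu_channels(), "label")
  if (!all(need %in% names(df))) {
    stop("not an IMU trace CSV (expected header t,ax,ay,az,gx,gy,gz,label)",
         call. = FALSE)
  }
  if (is.null(rate)) {
    rate <- if (nrow(df) > 1) round(1 / stats::median(diff(df$t))) else 100
  }
  lab <- as.character(df$label)
  lab[is.na(lab)] <- ""
  segments <- NULL
  if (any(nzchar(lab))) {
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- nzchar(r$values)
    segments <- data.frame(start = starts[keep], end = ends[keep],
                           label = r$values[keep])
  }
  imu_trace(as.matrix(df[, imu_channels()]), rate = rate,
            segments = segments, clip = FALSE)
}
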