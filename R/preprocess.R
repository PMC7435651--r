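#' Signed-permutation axis remapping
#'
#' Sensors worn in different positions or datasets recorded with other
#' conventions are brought into the package's waist-worn coordinate frame
#' by a signed 3x3 permutation matrix applied to both the acceleration and
#' the gyroscope triplet.
#'
#' @param m a 3x3 matrix with exactly one entry of +/-1 in each row and
#'   column and zeros elsewhere.
#' @return a validated `axis_map`.
#' @examples
#' # swap X and Y, negate Z
#' am <- axis_map(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1)))
#' @export
axis_map <- function(m) {
  m <- as.matrix(m)
  ok <- all(dim(m) == c(3, 3)) && all(m %in% c(-1, 0, 1)) &&
    all(rowSums(abs(m)) == 1) && all(colSums(abs(m)) == 1)
  if (!ok) {
    stop("axis map must be a 3x3 signed permutation matrix", call. = FALSE)
  }
  structure(m, class = c("axis_map", "matrix", "array"))
}

#' @rdname axis_map
#' @param trace an [imu_trace()].
#' @param map an `axis_map`.
#' @return `remap_axes()` returns the remapped trace; length, rate and
#'   segments are preserved.
#' @export
remap_axes <- function(trace, map) {
  stopifnot(inherits(trace, "imu_trace"))
  if (!inherits(map, "axis_map")) map <- axis_map(map)
  s <- trace$samples
  s[, 1:3] <- s[, 1:3, drop = FALSE] %*% t(unclass(map))
  s[, 4:6] <- s[, 4:6, drop = FALSE] %*% t(unclass(map))
  trace$samples <- s
  colnames(trace$samples) <- imu_channels()
  trace
}

#' Decimate a trace to a lower rate
#'
#' Keeps every `factor`-th sample starting at the first; the rate is
#' divided by `factor` and segment indices are rescaled accordingly. Used
#' to bring 200 Hz recordings down to the module's 100 Hz.
#'
#' @param trace an [imu_trace()].
#' @param factor positive integer decimation factor.
#' @return the downsampled `imu_trace`.
#' @export
downsample <- function(trace, factor) {
  stopifnot(inherits(trace, "imu_trace"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1) return(trace)
  keep <- seq(1, nrow(trace$samples), by = factor)
  seg <- trace$segments
  if (!is.null(seg)) {
    seg$start <- (seg$start - 1L) %/% factor + 1L
    seg$end <- (seg$end - 1L) %/% factor + 1L
    seg <- seg[seg$start <= seg$end, , drop = FALSE]
  }
  imu_trace(trace$samples[keep, , drop = FALSE], rate = trace$rate / factor,
            segments = seg, clip = FALSE)
}

#' Per-channel min-max normalization
#'
#' Maps each channel onto \[0, 1\] by `y = (x - min) / (max - min)` using
#' the sensor's nominal range specification, so the same value always maps
#' to the same code regardless of what a particular recording contains.
#' Defaults: +/-16 g for the three acceleration channels, +/-2000 deg/s for
#' the three gyroscope channels.
#'
#' @param mins,maxs length-6 per-channel range bounds.
#' @return `normalization_spec()` returns a spec; `normalize_channels()`
#'   and `denormalize_channels()` the transformed matrix.
#' @export
normalization_spec <- function(mins = c(rep(-16, 3), rep(-2000, 3)),
                               maxs = c(rep(16, 3), rep(2000, 3))) {
  if (length(mins) != length(maxs)) stop("mins/maxs length mismatch", call. = FALSE)
  if (any(maxs <= mins)) stop("max must exceed min for every channel", call. = FALSE)
  structure(list(mins = as.numeric(mins), maxs = as.numeric(maxs)),
            class = "normalization_spec")
}

#' @rdname normalization_spec
#' @param x numeric matrix (samples x channels) or vector (one channel).
#' @param spec a `normalization_spec` whose length matches `ncol(x)`.
#' @export
normalize_channels <- function(x, spec = normalization_spec()) {
  stopifnot(inherits(spec, "normalization_spec"))
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1)
  if (ncol(x) != length(spec$mins)) {
    stop("spec has ", length(spec$mins), " channels, data has ", ncol(x),
         call. = FALSE)
  }
  y <- sweep(sweep(x, 2, spec$mins), 2, spec$maxs - spec$mins, "/")
  if (v) drop(y) else y
}

#' @rdname normalization_spec
#' @export
denormalize_channels <- function(x, spec = normalization_spec()) {
  stopifnot(inherits(spec, "normalization_spec"))
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1)
  y <- sweep(sweep(x, 2, spec$maxs - spec$mins, "*"), 2, spec$mins, "+")
  if (v) drop(y) else y
}

#' Causal moving-average filter
#'
#' Smooths sensor noise with the causal mean of the last `m` samples:
#' `y[n] = (x[n] + x[n-1] + ... + x[n-m+1]) / m`. For the first `m - 1`
#' samples, where a full history does not exist, the mean is taken over the
#' samples available, so the output has the input's length and no startup
#' transient. The default `m = 5` (50 ms at 100 Hz) smooths noise without
#' blunting the ~20 ms free-fall signature.
#'
#' @param m window size in samples (>= 1).
#' @return `filter_spec()` returns a spec; `moving_average()` the filtered
#'   series (vector in, vector out; matrix in, per-column filtering).
#' @examples
#' moving_average(c(1, 2, 3, 4), filter_spec(2))  # 1.0 1.5 2.5 3.5
#' @export
filter_spec <- function(m = 5) {
  m <- as.integer(m)
  if (is.na(m) || m < 1) stop("filter window m must be >= 1", call. = FALSE)
  structure(list(m = m), class = "filter_spec")
}

#' @rdname filter_spec
#' @param x numeric vector or matrix (samples x channels).
#' @param spec a `filter_spec`.
#' @export
moving_average <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  m <- spec$m
  ma1 <- function(v) {
    n <- length(v)
    if (!n || m == 1) return(v)
    cs <- cumsum(v)
    head_n <- seq_len(min(m - 1, n))
    out <- numeric(n)
    out[head_n] <- cs[head_n] / head_n
    if (n >= m) {
      idx <- m:n
      out[idx] <- (cs[idx] - c(0, cs)[idx - m + 1]) / m
    }
    out
  }
  if (is.null(dim(x))) ma1(x) else apply(x, 2, ma1)
}

#' Sliding-window specification and assembly
#'
#' The classifier consumes fixed-length windows of the six-channel stream.
#' The default window is 2 s — 200 sample sets at 100 Hz, matching the
#' duration an impact-bearing fall fits into — advanced with a stride of
#' 100 samples (50% overlap), oldest samples dropped as new ones arrive.
#'
#' @param length window length in samples.
#' @param stride advance between consecutive windows in samples.
#' @param rate sampling rate in Hz the spec assumes.
#' @return `window_spec()` returns a spec; `assemble_windows()` a list of
#'   windows, each `list(data = <length x 6 matrix>, label = <chr or NA>)`.
#' @export
window_spec <- function(length = round(2 * rate), stride = 100, rate = 100) {
  if (length < 1 || stride < 1) {
    stop("window length and stride must be >= 1", call. = FALSE)
  }
  structure(list(length = as.integer(length), stride = as.integer(stride),
                 rate = rate), class = "window_spec")
}

#' @rdname window_spec
#' @param trace an [imu_trace()] (or a bare samples x 6 matrix).
#' @param spec a `window_spec`.
#' @details Each window is labelled by the majority per-sample label of the
#'   samples it covers; ties are broken toward `"falling"` (a missed fall
#'   costs more than a false alarm), then toward the lower activity code.
#'   A stream shorter than one window yields an empty list.
#' @export
assemble_windows <- function(trace, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  if (inherits(trace, "imu_trace")) {
    x <- trace$samples
    labels <- trace_labels(trace)
  } else {
    x <- as.matrix(trace)
    labels <- rep(NA_character_, nrow(x))
  }
  n <- nrow(x)
  if (n < spec$length) return(list())
  starts <- seq(1L, n - spec$length + 1L, by = spec$stride)
  lapply(starts, function(s) {
    idx <- s:(s + spec$length - 1L)
    lab <- .majority_label(labels[idx])
    list(data = x[idx, , drop = FALSE], label = lab, start = s)
  })
}

.majority_label <- function(labs) {
  labs <- labs[!is.na(labs)]
  if (!length(labs)) return(NA_character_)
  tab <- table(labs)
  top <- names(tab)[tab == max(tab)]
  if ("falling" %in% top) return("falling")
  top[order(activity_code(top))][1]
}

#' Read SisFall/MobiFall-style delimited recordings
#'
#' Interface adapters for the two common public fall-detection corpora
#' formats: plain delimited text with one sample per line, accelerometer
#' and gyroscope columns in raw integer counts or physical units. Scale
#' factors convert counts to g and deg/s; an [axis_map()] brings the
#' recording into the package frame (the corpora do not document a single
#' canonical map, so it is user-supplied). No data ships with the package;
#' these functions only define the interface.
#'
#' @param path delimited text file, one sample per line.
#' @param columns integer positions of the `ax, ay, az, gx, gy, gz` columns.
#' @param accel_scale multiplicative factor from file units to g.
#' @param gyro_scale multiplicative factor from file units to deg/s.
#' @param rate recording rate in Hz.
#' @param map optional [axis_map()] applied after scaling.
#' @param sep field separator (default `","`).
#' @param label optional activity label for the whole recording.
#' @return an [imu_trace()].
#' @export
read_delimited_trace <- function(path, columns = 1:6, accel_scale = 1,
                                 gyro_scale = 1, rate = 200, map = NULL,
                                 sep = ",", label = NULL) {
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          strip.white = TRUE, comment.char = "")
  if (max(columns) > ncol(df)) stop("column indices out of range", call. = FALSE)
  m <- as.matrix(df[, columns])
  m[, 1:3] <- m[, 1:3] * accel_scale
  m[, 4:6] <- m[, 4:6] * gyro_scale
  seg <- if (!is.null(label)) {
    data.frame(start = 1L, end = nrow(m), label = label)
  }
  tr <- imu_trace(m, rate = rate, segments = seg, clip = FALSE)
  if (!is.null(map)) tr <- remap_axes(tr, map)
  tr
}
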