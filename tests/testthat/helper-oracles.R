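# Independent reference implementations used to cross-check the package.
# Everything here is deliberately naive: straight per-sample loops with
# explicit counters, no vectorisation, no code shared with R/.

# Brute-force interrupt scanner: walks the trace one sample at a time,
# keeping a consecutive-count per condition and a latch that re-arms only
# after the condition breaks. Returns 0-based fire indices per kind.
oracle_scan <- function(accel, rate, ff_thr = 0.563, ff_dur_ms = 20,
                        mot_thr = 2.0, mot_dur_ms = 20,
                        zr_thr = 0.5, zr_dur_ms = 1000) {
  need <- function(ms) max(1, ceiling(ms / 1000 * rate))
  res <- list(free_fall = integer(), motion = integer(),
              zero_motion = integer())
  defs <- list(
    free_fall = list(n = need(ff_dur_ms),
                     f = function(a) all(abs(a) < ff_thr)),
    motion = list(n = need(mot_dur_ms),
                  f = function(a) any(abs(a) > mot_thr)),
    zero_motion = list(n = need(zr_dur_ms),
                       f = function(a) all(abs(a) < zr_thr)))
  for (kind in names(defs)) {
    cnt <- 0
    armed <- TRUE
    for (i in seq_len(nrow(accel))) {
      if (defs[[kind]]$f(accel[i, ])) {
        cnt <- cnt + 1
        if (armed && cnt >= defs[[kind]]$n) {
          res[[kind]] <- c(res[[kind]], i - 1L)
          armed <- FALSE
        }
      } else {
        cnt <- 0
        armed <- TRUE
      }
    }
  }
  res
}

# Brute-force transmission reference: event-driven simulation stepping one
# sample at a time with an explicit vector of buffered (not yet
# transmitted) 0-based sample indices.
oracle_fsm <- function(accel, rate, cap = 50, ff_thr = 0.563, ff_dur_ms = 20,
                       mot_thr = 2.0, mot_dur_ms = 20,
                       zr_thr = 0.5, zr_dur_ms = 1000) {
  need <- function(ms) max(1, ceiling(ms / 1000 * rate))
  n_ff <- need(ff_dur_ms); n_mot <- need(mot_dur_ms); n_zr <- need(zr_dur_ms)
  transmitted <- integer()
  buffer <- integer()
  state <- "idle"
  cff <- 0; aff <- TRUE; cmo <- 0; amo <- TRUE; czr <- 0; azr <- TRUE
  for (i in seq_len(nrow(accel))) {
    a <- abs(accel[i, ])
    buffer <- c(buffer, i - 1L)
    if (length(buffer) > cap) buffer <- buffer[-1]
    if (all(a < ff_thr)) cff <- cff + 1 else { cff <- 0; aff <- TRUE }
    if (any(a > mot_thr)) cmo <- cmo + 1 else { cmo <- 0; amo <- TRUE }
    fire_ff <- aff && cff >= n_ff
    fire_mot <- amo && cmo >= n_mot
    if (state == "idle") {
      czr <- 0; azr <- TRUE
      if (fire_ff || fire_mot) {
        if (fire_ff) aff <- FALSE
        if (fire_mot) amo <- FALSE
        transmitted <- c(transmitted, buffer)
        buffer <- integer()
        state <- "transmitting"
      }
    } else {
      if (fire_ff) aff <- FALSE
      if (fire_mot) amo <- FALSE
      if (all(a < zr_thr)) czr <- czr + 1 else { czr <- 0; azr <- TRUE }
      if (azr && czr >= n_zr) {
        azr <- FALSE
        state <- "idle"
      } else if (length(buffer) >= cap) {
        transmitted <- c(transmitted, buffer)
        buffer <- integer()
      }
    }
  }
  transmitted
}

# Random piecewise-constant test traces that exercise all three thresholds:
# short segments with levels straddling 0.5, 0.563 and 2.0 g.
random_threshold_trace <- function(seed, n = 300, rate = 100) {
  set.seed(seed)
  levels <- c(0.1, 0.3, 0.45, 0.52, 0.58, 0.8, 1.0, 1.8, 2.5)
  m <- matrix(0, n, 6)
  i <- 1
  while (i <= n) {
    len <- sample(1:60, 1)
    seg <- min(i + len - 1, n)
    for (ch in 1:3) m[i:seg, ch] <- sample(levels, 1) * sample(c(-1, 1), 1)
    i <- seg + 1
  }
  m[, 4:6] <- rnorm(3 * n, 0, 50)
  imu_trace(m, rate = rate)
}

# Published reference confusion matrix of a full-scale offline evaluation
# of this architecture (8 activity classes, 240 test windows per class);
# row/column order matches the package's activity encoding.
reference_offline_confusion <- function() {
  published_order <- c("falling", "standing_up", "walking", "jogging", "jumping",
                   "going_upstairs", "going_downstairs", "sitting_down")
  m <- rbind(
    c(239, 0, 0, 0, 0, 0, 0, 1),
    c(0, 234, 0, 0, 0, 0, 0, 6),
    c(0, 0, 240, 0, 0, 0, 0, 0),
    c(0, 0, 0, 239, 0, 1, 0, 0),
    c(0, 0, 0, 0, 240, 0, 0, 0),
    c(0, 0, 0, 0, 0, 238, 2, 0),
    c(0, 0, 0, 0, 0, 2, 238, 0),
    c(0, 4, 0, 0, 0, 0, 0, 236))
  ord <- match(activity_labels(), published_order)
  as_confusion(m[ord, ord])
}
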