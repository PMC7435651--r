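test_that("axis remapping applies signed permutations and composes", {
  tr <- generate_trace("walking", seed = 1)
  id <- axis_map(diag(3))
  expect_equal(remap_axes(tr, id)$samples, tr$samples)
  swap <- axis_map(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1)))
  inv <- axis_map(t(unclass(swap)))      # inverse of a signed permutation
  expect_equal(remap_axes(remap_axes(tr, swap), inv)$samples, tr$samples)
  # 1 g on X under an X -> Z map lands on Z
  g_on_x <- imu_trace(matrix(c(1, 0, 0, 0, 0, 0), 1), rate = 100)
  x_to_z <- axis_map(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  out <- remap_axes(g_on_x, x_to_z)
  expect_equal(unname(out$samples[1, 1:3]), c(0, 0, 1))
  expect_error(axis_map(matrix(1, 3, 3)), "signed permutation")
  expect_error(axis_map(diag(c(1, 1, 2))), "signed permutation")
})

test_that("downsampling decimates by index and rescales rate and segments", {
  tr <- generate_trace("jogging", generator_config(rate = 200), seed = 1)
  expect_identical(downsample(tr, 1), tr)
  half <- downsample(tr, 2)
  expect_equal(half$rate, 100)
  expect_identical(nrow(half$samples), 400L)
  expect_equal(half$samples[2, ], tr$samples[3, ])  # keeps every 2nd from 1st
  # alternating series becomes constant
  alt <- imu_trace(matrix(rep(c(1, 2), 300), nrow = 100, ncol = 6),
                   rate = 200)
  expect_true(all(downsample(alt, 2)$samples[, 1] ==
                    alt$samples[1, 1]))
  expect_error(downsample(tr, 0), ">= 1")
})

test_that("range normalization maps endpoints, midpoint and quartile correctly", {
  spec1 <- normalization_spec(mins = -16, maxs = 16)
  expect_equal(normalize_channels(-16, spec1), 0)
  expect_equal(normalize_channels(16, spec1), 1)
  expect_equal(normalize_channels(0, spec1), 0.5)
  expect_equal(normalize_channels(8, spec1), 0.75)
  expect_error(normalization_spec(mins = 1, maxs = 1), "exceed")
})

test_that("normalize then denormalize is the identity", {
  set.seed(1)
  x <- cbind(matrix(runif(300, -16, 16), 100), matrix(runif(300, -2000, 2000), 100))
  spec <- normalization_spec()
  y <- normalize_channels(x, spec)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(denormalize_channels(y, spec), x, tolerance = 1e-12)
})

test_that("the moving average matches its closed form and edge policy", {
  expect_equal(moving_average(c(1, 2, 3, 4), filter_spec(2)),
               c(1, 1.5, 2.5, 3.5))
  expect_equal(moving_average(rep(3.5, 20), filter_spec(7)), rep(3.5, 20))
  expect_identical(moving_average(c(2, 9, 4), filter_spec(1)), c(2, 9, 4))
  expect_identical(moving_average(numeric(), filter_spec(3)), numeric())
  # matches a direct windowed mean away from the edge
  set.seed(2)
  x <- rnorm(50)
  y <- moving_average(x, filter_spec(5))
  for (n in 5:50) expect_equal(y[n], mean(x[(n - 4):n]))
  # partial-history average at the start
  expect_equal(y[3], mean(x[1:3]))
})

test_that("the moving average commutes with constant offsets", {
  set.seed(3)
  x <- rnorm(100)
  for (m in c(2, 5, 9)) {
    expect_equal(moving_average(x + 7, filter_spec(m)),
                 moving_average(x, filter_spec(m)) + 7, tolerance = 1e-12)
  }
})

test_that("window assembly counts, shapes and labels windows correctly", {
  tr <- generate_trace("walking", seed = 1)   # 400 samples
  w <- assemble_windows(tr, window_spec(length = 200, stride = 100))
  expect_length(w, 3)
  expect_equal(dim(w[[1]]$data), c(200, 6))
  expect_true(all(vapply(w, `[[`, "", "label") == "walking"))
  one <- assemble_windows(generate_trace("jumping",
                                         generator_config(duration_s = 2),
                                         seed = 1))
  expect_length(one, 1)
  expect_equal(dim(one[[1]]$data), c(200, 6))
  short <- imu_trace(matrix(0, 100, 6), rate = 100)
  expect_length(assemble_windows(short), 0)
})

test_that("window counts follow floor((N - length)/stride) + 1", {
  for (n in c(200, 250, 399, 400, 401, 1000)) {
    tr <- imu_trace(matrix(0, n, 6), rate = 100)
    for (stride in c(50, 100, 200)) {
      w <- assemble_windows(tr, window_spec(length = 200, stride = stride))
      expect_length(w, floor((n - 200) / stride) + 1)
    }
  }
})

test_that("mixed windows take the majority label with ties broken to falling", {
  m <- matrix(0, 200, 6)
  seg <- data.frame(start = c(1L, 121L), end = c(120L, 200L),
                    label = c("falling", "walking"))
  tr <- imu_trace(m, rate = 100, segments = seg)
  w <- assemble_windows(tr, window_spec(length = 200, stride = 200))
  expect_identical(w[[1]]$label, "falling")       # 120 fall vs 80 walk
  seg2 <- data.frame(start = c(1L, 101L), end = c(100L, 200L),
                     label = c("walking", "falling"))
  tr2 <- imu_trace(m, rate = 100, segments = seg2)
  expect_identical(assemble_windows(tr2)[[1]]$label, "falling")  # tie
})

test_that("the conditioning chain is deterministic end to end", {
  run <- function() {
    tr <- generate_trace("going_downstairs",
                         generator_config(rate = 200), seed = 6)
    tr <- remap_axes(tr, axis_map(diag(3)))
    tr <- downsample(tr, 2)
    tr$samples <- moving_average(
      normalize_channels(tr$samples, normalization_spec()), filter_spec(5))
    assemble_windows(tr, window_spec())
  }
  expect_identical(run(), run())
})

test_that("delimited corpus adapter scales, maps and labels recordings", {
  f <- withr::local_tempfile(fileext = ".txt")
  # raw counts: accel at +-2048 counts/g style scale, gyro 16.4 counts/dps
  m <- cbind(2048, 0, -2048, 164, 0, 0)
  write.table(m[rep(1, 10), ], f, sep = ",", row.names = FALSE,
              col.names = FALSE)
  tr <- read_delimited_trace(f, accel_scale = 1 / 2048, gyro_scale = 1 / 16.4,
                             rate = 200, label = "falling")
  expect_equal(unname(tr$samples[1, ]), c(1, 0, -1, 10, 0, 0))
  expect_identical(tr$segments$label, "falling")
  expect_error(read_delimited_trace(f, columns = 2:7), "out of range")
})
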