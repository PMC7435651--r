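# small, fast fits: 1 conv block, short windows, few classes where possible

tiny_spec <- function(classes = 2, units = 8) {
  model_spec(list(layer_conv1d(4, 3), layer_maxpool1d(),
                  layer_reshape_split(), layer_lstm(units, dropout = 0.5),
                  layer_dense(classes)),
              input_length = 20, input_channels = 2, classes = classes)
}

# two trivially separable classes: constant level 0 vs 1 plus small noise
toy_data <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  x <- array(rnorm(n * 20 * 2, sd = 0.05), c(n, 20, 2))
  y <- rep(0:1, each = n_per)
  x[y == 1, , ] <- x[y == 1, , ] + 1
  list(x = x, y = y)
}

test_that("training is deterministic for a fixed seed", {
  d <- toy_data()
  f1 <- fdnn(d$x, d$y, tiny_spec(), fdnn_control(epochs = 2, batch_size = 8),
             classes = c("a", "b"), center = 0, seed = 5)
  f2 <- fdnn(d$x, d$y, tiny_spec(), fdnn_control(epochs = 2, batch_size = 8),
             classes = c("a", "b"), center = 0, seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  f3 <- fdnn(d$x, d$y, tiny_spec(), fdnn_control(epochs = 2, batch_size = 8),
             classes = c("a", "b"), center = 0, seed = 6)
  expect_false(identical(f1$params, f3$params))
})

test_that("a linearly separable toy reaches perfect training accuracy", {
  d <- toy_data()
  fit <- fdnn(d$x, d$y, tiny_spec(), fdnn_control(epochs = 40, batch_size = 10,
                                                  patience = Inf),
              classes = c("a", "b"), center = 0.5, seed = 2)
  pred <- predict(fit, d$x, type = "code")
  expect_equal(mean(pred == d$y), 1.0)
})

test_that("history follows the train/validation cadences", {
  d <- toy_data(n_per = 24)   # 48 samples, batch 8 -> 6 iters/epoch
  ctl <- fdnn_control(epochs = 5, batch_size = 8, train_every = 5,
                      validate_every = 25, patience = Inf)
  fit <- fdnn(d$x, d$y, tiny_spec(), ctl, classes = c("a", "b"),
              validation = list(x = d$x[1:4, , ], y = d$y[1:4]),
              center = 0, seed = 1)
  iters <- fit$iterations
  expect_identical(iters, 30L)
  h <- fit$history
  expect_identical(sum(h$split == "train"), iters %/% 5L)
  expect_identical(sum(h$split == "validation"), iters %/% 25L)
  expect_identical(h$iteration[h$split == "train"], seq(5L, 30L, by = 5L))
})

test_that("prediction is deterministic, normalized and shape-checked", {
  d <- toy_data(n_per = 6)
  fit <- fdnn(d$x, d$y, tiny_spec(), fdnn_control(epochs = 2, batch_size = 6),
              classes = c("a", "b"), center = 0, seed = 3)
  p1 <- predict(fit, d$x)
  p2 <- predict(fit, d$x)
  expect_identical(p1, p2)   # dropout is off at inference
  expect_equal(rowSums(p1), rep(1, nrow(p1)), tolerance = 1e-9)
  expect_identical(colnames(p1), c("a", "b"))
  lab <- predict(fit, d$x[1, , ], type = "class")   # single window promotes
  expect_true(lab %in% c("a", "b"))
  expect_error(predict(fit, array(0, c(2, 21, 2))), "does not match")
})

test_that("empty training sets and bad labels are rejected", {
  d <- toy_data(n_per = 2)
  expect_error(fdnn(array(0, c(0, 20, 2)), integer(), tiny_spec()), "empty")
  expect_error(fdnn(d$x, rep(5L, 4), tiny_spec(), classes = c("a", "b")),
               "lie in")
  expect_error(fdnn(d$x, d$y[1:3], tiny_spec(), classes = c("a", "b")),
               "lengths differ")
})

test_that("checkpoints are written on the epoch cadence", {
  d <- toy_data(n_per = 4)
  dir <- withr::local_tempdir()
  fit <- fdnn(d$x, d$y, tiny_spec(),
              fdnn_control(epochs = 4, batch_size = 8, checkpoint_every = 2),
              classes = c("a", "b"), center = 0, checkpoint_dir = dir,
              seed = 1)
  files <- list.files(dir)
  expect_setequal(files, c("epoch_002.rds", "epoch_004.rds"))
  ck <- readRDS(file.path(dir, "epoch_004.rds"))
  expect_identical(names(ck$params), names(fit$params))
})

test_that("fit methods print, summarise, plot and export", {
  d <- toy_data(n_per = 4)
  fit <- fdnn(d$x, d$y, tiny_spec(), fdnn_control(epochs = 4, batch_size = 2),
              classes = c("a", "b"), center = 0, seed = 1)
  expect_output(print(fit), "CNN-LSTM")
  expect_output(summary(fit), "Training control")
  expect_named(coef(fit), c("C1.W", "C1.b", "L1.W", "L1.b", "Fc.W", "Fc.b"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(fit, f)
  h <- read.csv(f)
  expect_identical(nrow(h), nrow(fit$history))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("training aborts with a diagnostic when the loss degenerates", {
  d <- toy_data(n_per = 4)
  x_bad <- d$x
  x_bad[1, 1, 1] <- NaN
  expect_error(
    fdnn(x_bad, d$y, tiny_spec(), fdnn_control(epochs = 1, batch_size = 8),
         classes = c("a", "b"), center = 0, seed = 1),
    "non-finite loss")
})
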