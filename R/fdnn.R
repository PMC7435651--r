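#' Training control parameters
#'
#' Hyperparameters of the supervised training loop. Defaults follow common
#' practice for this architecture: Adam with learning rate 1e-3 and
#' stability epsilon 1e-8, mini-batches of 128, up to 300 epochs with
#' LSTM-output dropout 0.5; training loss/accuracy recorded every 5
#' iterations and validation metrics every 25; a checkpoint every 10
#' epochs; early stop when validation accuracy plateaus.
#'
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param epsilon Adam numerical-stability constant.
#' @param epochs maximum number of epochs.
#' @param dropout LSTM output dropout probability (training only).
#' @param train_every record training metrics every this many iterations.
#' @param validate_every record validation metrics every this many
#'   iterations.
#' @param checkpoint_every save a checkpoint every this many epochs (only
#'   if a checkpoint directory is given to [fdnn()]).
#' @param patience early-stop patience, counted in validation checks with
#'   improvement below `min_delta`; `Inf` disables early stopping.
#' @param min_delta minimum validation-accuracy improvement that resets the
#'   patience counter.
#' @param clip_norm global gradient-norm ceiling: whenever the L2 norm of
#'   the full gradient exceeds it, the gradient is rescaled to that norm
#'   before the Adam step (the standard guard against exploding recurrent
#'   gradients). `Inf` disables clipping.
#' @param restore_best when a validation set is supplied, return the
#'   weights of the best validation-accuracy checkpoint rather than the
#'   last iterate.
#' @return a list of class `fdnn_control`.
#' @export
fdnn_control <- function(batch_size = 128, lr = 1e-3, epsilon = 1e-8,
                         epochs = 300, dropout = 0.5, train_every = 5,
                         validate_every = 25, checkpoint_every = 10,
                         patience = 20, min_delta = 1e-4, clip_norm = 5,
                         restore_best = TRUE) {
  stopifnot(batch_size >= 1, lr > 0, epsilon > 0, epochs >= 1,
            dropout >= 0, dropout < 1, train_every >= 1,
            validate_every >= 1, checkpoint_every >= 1, min_delta >= 0,
            clip_norm > 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 dropout = dropout, train_every = as.integer(train_every),
                 validate_every = as.integer(validate_every),
                 checkpoint_every = as.integer(checkpoint_every),
                 patience = patience, min_delta = min_delta,
                 clip_norm = clip_norm,
                 restore_best = isTRUE(restore_best)),
            class = "fdnn_control")
}

# compile a model spec into an executable op chain; weights only if init
.compile_model <- function(spec, init = TRUE) {
  shapes <- audit_shapes(spec)
  in_feat <- c(spec$input_channels, shapes$features[-nrow(shapes)])
  params <- list()
  ops <- list()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    id <- shapes$layer[i]
    op <- list(kind = ly$kind, id = id, spec = ly, in_dim = in_feat[i])
    if (init) {
      if (ly$kind == "conv1d") {
        params[[paste0(id, ".W")]] <-
          .glorot(ly$kernel * in_feat[i], ly$filters, ly$kernel * in_feat[i])
        params[[paste0(id, ".b")]] <- rep(0, ly$filters)
      } else if (ly$kind == "lstm") {
        wb <- .lstm_init(in_feat[i], ly$units, ly$forget_bias)
        params[[paste0(id, ".W")]] <- wb$W
        params[[paste0(id, ".b")]] <- wb$b
      } else if (ly$kind == "dense") {
        params[[paste0(id, ".W")]] <- .glorot(in_feat[i], ly$units, in_feat[i])
        params[[paste0(id, ".b")]] <- rep(0, ly$units)
      }
    }
    ops[[i]] <- op
  }
  list(ops = ops, params = params)
}

# forward pass; returns probabilities and (optionally) per-layer caches
.model_fwd <- function(ops, params, X, training = FALSE, dropout = 0,
                       keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(ops))
  A <- X
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    id <- op$id
    if (op$kind == "conv1d") {
      r <- .conv1d_fwd(A, params[[paste0(id, ".W")]],
                       params[[paste0(id, ".b")]], op$spec$kernel)
      A <- r$out
    } else if (op$kind == "maxpool1d") {
      r <- .maxpool_fwd(A)
      A <- r$out
    } else if (op$kind == "reshape_split") {
      r <- list(cache = NULL)            # pooled time axis becomes recurrent axis
    } else if (op$kind == "lstm") {
      r <- .lstm_fwd(A, params[[paste0(id, ".W")]],
                     params[[paste0(id, ".b")]], op$spec$units,
                     dropout = if (training) dropout else 0,
                     training = training)
      A <- r$out
    } else if (op$kind == "dense") {
      B <- dim(A)[1]
      H <- matrix(A[, dim(A)[2], ], nrow = B)   # last timestep
      logits <- sweep(H %*% params[[paste0(id, ".W")]], 2,
                      params[[paste0(id, ".b")]], "+")
      r <- list(cache = list(H = H, dimA = dim(A)))
      A <- softmax(logits)
    }
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(prob = A, caches = caches)
}

# backward pass from softmax + cross-entropy; returns gradient list
.model_bwd <- function(ops, params, caches, prob, y_onehot) {
  grads <- list()
  B <- nrow(prob)
  dA <- NULL
  for (i in rev(seq_along(ops))) {
    op <- ops[[i]]
    id <- op$id
    if (op$kind == "dense") {
      cache <- caches[[i]]
      dlogits <- (prob - y_onehot) / B
      grads[[paste0(id, ".W")]] <- crossprod(cache$H, dlogits)
      grads[[paste0(id, ".b")]] <- colSums(dlogits)
      dH <- dlogits %*% t(params[[paste0(id, ".W")]])
      dA <- array(0, cache$dimA)
      dA[, cache$dimA[2], ] <- dH
    } else if (op$kind == "lstm") {
      r <- .lstm_bwd(dA, params[[paste0(id, ".W")]], caches[[i]])
      grads[[paste0(id, ".W")]] <- r$dW
      grads[[paste0(id, ".b")]] <- r$db
      dA <- r$dX
    } else if (op$kind == "reshape_split") {
      # identity
    } else if (op$kind == "maxpool1d") {
      dA <- .maxpool_bwd(dA, caches[[i]])
    } else if (op$kind == "conv1d") {
      r <- .conv1d_bwd(dA, params[[paste0(id, ".W")]], caches[[i]])
      grads[[paste0(id, ".W")]] <- r$dW
      grads[[paste0(id, ".b")]] <- r$db
      dA <- r$dX
    }
  }
  grads
}

.as_label_codes <- function(y, classes) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    idx <- match(y, classes)
    if (anyNA(idx)) stop("unknown class label(s) in y", call. = FALSE)
    return(idx - 1L)
  }
  y <- as.integer(y)
  if (any(y < 0L | y >= length(classes))) {
    stop("integer labels must lie in [0, ", length(classes), ")", call. = FALSE)
  }
  y
}

#' Fit the CNN-LSTM fall-detection network
#'
#' Trains the network described by a [model_spec()] on labelled
#' fixed-length windows, fully supervised, with backpropagation (through
#' time in the recurrent layers) and Adam updates after every mini-batch.
#' LSTM cell and hidden states start at zero; the forget-gate bias starts
#' at its spec value (default 1.0); LSTM-output dropout is active during
#' training only, so prediction is deterministic. Training is reproducible:
#' the seed determines initialisation, batch order and dropout masks.
#'
#' @param x numeric array `n x length x channels` of input windows (an
#'   `imu_window_set`'s `x`), values typically range-normalized to
#'   \[0, 1\].
#' @param y labels: integer codes `0..k-1`, a factor, or characters
#'   matching `classes`.
#' @param spec an `fdnn_model_spec`; default the 4-block architecture.
#' @param control an [fdnn_control()].
#' @param validation optional `list(x =, y =)` used for the validation
#'   cadence, checkpoint selection and early stopping.
#' @param classes class labels in encoding order (default
#'   [activity_labels()]).
#' @param center scalar subtracted from every input value before the first
#'   convolution, stored in the fit and applied identically at prediction.
#'   Range-normalized windows live in \[0, 1\] around a near-constant
#'   gravity code of ~0.53, which leaves the optimization badly
#'   conditioned; the default 0.5 zero-centers them. Use 0 for data that
#'   is already centred.
#' @param checkpoint_dir optional directory; the model is saved there every
#'   `checkpoint_every` epochs as `epoch_<e>.rds`.
#' @param seed integer seed.
#' @param verbose print a line per epoch.
#' @return an object of class `fdnn`: the fitted weights, the spec, the
#'   training history (`data.frame` iteration/epoch/split/loss/accuracy)
#'   and the stop reason. Methods: [predict.fdnn()], `print`, `summary`,
#'   `coef` (weight list), `plot` (history curves).
#' @examples
#' \donttest{
#' ds <- generate_dataset(per_class = 6, seed = 1)
#' tr <- ds$split == "train"
#' fit <- fdnn(ds$x[tr, , ], ds$label[tr], spec = default_model_spec(1),
#'             control = fdnn_control(epochs = 2, batch_size = 16), seed = 1)
#' predict(fit, ds$x[!tr, , ], type = "class")
#' }
#' @export
fdnn <- function(x, y, spec = default_model_spec(),
                 control = fdnn_control(), validation = NULL,
                 classes = activity_labels(), center = 0.5,
                 checkpoint_dir = NULL, seed = 1, verbose = FALSE) {
  stopifnot(inherits(spec, "fdnn_model_spec"),
            inherits(control, "fdnn_control"), is.numeric(center))
  x <- .as_window_array(x, spec) - center
  n <- dim(x)[1]
  if (n < 1) stop("empty training set", call. = FALSE)
  y <- .as_label_codes(y, classes)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  k <- spec$classes
  Y <- one_hot(y, k)
  has_val <- !is.null(validation)
  if (has_val) {
    vx <- .as_window_array(validation$x, spec) - center
    vy <- .as_label_codes(validation$y, classes)
  }
  with_seed(seed, {
    model <- .compile_model(spec)
    ops <- model$ops
    params <- model$params
    adam <- .adam_init(params)
    hist <- list()
    iter <- 0L
    best_val <- -Inf
    best_params <- NULL
    stall <- 0L
    stop_reason <- "max_epochs"
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = control$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + control$batch_size - 1L, n)]
        xb <- x[idx, , , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        fw <- .model_fwd(ops, params, xb, training = TRUE,
                         dropout = control$dropout, keep_cache = TRUE)
        loss <- cross_entropy(yb, fw$prob)
        if (!is.finite(loss)) {
          stop("training aborted: non-finite loss at iteration ", iter + 1L,
               " (epoch ", epoch, "); consider a lower learning rate",
               call. = FALSE)
        }
        grads <- .model_bwd(ops, params, fw$caches, fw$prob, yb)
        if (is.finite(control$clip_norm)) {
          gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
          if (gn > control$clip_norm) {
            grads <- lapply(grads, `*`, control$clip_norm / gn)
          }
        }
        iter <- iter + 1L
        upd <- .adam_step(params, grads, adam, iter, control$lr,
                          eps = control$epsilon)
        params <- upd$params
        adam <- upd$state
        if (iter %% control$train_every == 0L) {
          acc <- mean(max.col(fw$prob, ties.method = "first") ==
                        max.col(yb, ties.method = "first"))
          hist[[length(hist) + 1L]] <-
            data.frame(iteration = iter, epoch = epoch, split = "train",
                       loss = loss, accuracy = acc)
        }
        if (has_val && iter %% control$validate_every == 0L) {
          vm <- .eval_split(ops, params, vx, vy, k)
          hist[[length(hist) + 1L]] <-
            data.frame(iteration = iter, epoch = epoch, split = "validation",
                       loss = vm$loss, accuracy = vm$accuracy)
          if (vm$accuracy > best_val + control$min_delta) {
            best_val <- vm$accuracy
            if (control$restore_best) best_params <- params
            stall <- 0L
          } else {
            stall <- stall + 1L
          }
          if (stall >= control$patience) stop_reason <- "early_stop"
        }
      }
      if (verbose) {
        message(sprintf("epoch %d/%d done (%d iterations)", epoch,
                        control$epochs, iter))
      }
      if (!is.null(checkpoint_dir) &&
          epoch %% control$checkpoint_every == 0L) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(list(params = params, epoch = epoch, iteration = iter),
                file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch)))
      }
      if (stop_reason == "early_stop") break
    }
    history <- if (length(hist)) do.call(rbind, hist) else
      data.frame(iteration = integer(), epoch = integer(),
                 split = character(), loss = numeric(), accuracy = numeric())
    if (!is.null(best_params)) params <- best_params
    structure(list(spec = spec, params = params, classes = classes,
                   center = center, best_validation_accuracy =
                     if (has_val && is.finite(best_val)) best_val,
                   control = control, history = history, seed = seed,
                   epochs_run = min(epoch, control$epochs),
                   iterations = iter, stop_reason = stop_reason,
                   call = match.call()),
              class = "fdnn")
  })
}

.as_window_array <- function(x, spec) {
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  if (length(dim(x)) != 3) {
    stop("x must be an n x length x channels array", call. = FALSE)
  }
  if (dim(x)[2] != spec$input_length || dim(x)[3] != spec$input_channels) {
    stop("window shape ", dim(x)[2], " x ", dim(x)[3],
         " does not match the spec input ", spec$input_length, " x ",
         spec$input_channels, call. = FALSE)
  }
  x
}

.eval_split <- function(ops, params, x, y, k) {
  fw <- .model_fwd(ops, params, x, training = FALSE)
  list(loss = cross_entropy(one_hot(y, k), fw$prob),
       accuracy = mean(max.col(fw$prob, ties.method = "first") - 1L == y))
}

#' Predict activity classes for new windows
#'
#' Runs the fitted network forward (dropout disabled, hence deterministic).
#' Probability rows sum to 1; the predicted class is the arg-max, ties
#' broken toward the lowest class code.
#'
#' @param object an [fdnn()] fit.
#' @param x array `n x length x channels` (a single `length x channels`
#'   matrix is promoted to `n = 1`).
#' @param type `"prob"` for the probability matrix, `"class"` for labels,
#'   `"code"` for integer codes.
#' @param ... unused.
#' @return per `type`: an `n x k` matrix, a character vector, or an
#'   integer vector.
#' @export
predict.fdnn <- function(object, x, type = c("prob", "class", "code"), ...) {
  type <- match.arg(type)
  x <- .as_window_array(x, object$spec) - (object$center %||% 0)
  model <- .compile_model(object$spec, init = FALSE)
  fw <- .model_fwd(model$ops, object$params, x, training = FALSE)
  prob <- fw$prob
  colnames(prob) <- object$classes[seq_len(ncol(prob))]
  if (type == "prob") return(prob)
  # max.col with ties.method "first" implements lowest-code tie-breaking
  code <- max.col(prob, ties.method = "first") - 1L
  if (type == "code") code else object$classes[code + 1L]
}

#' @export
print.fdnn <- function(x, ...) {
  pa <- audit_params(x$spec)
  cat(sprintf("<fdnn> %d-class CNN-LSTM, %s trainable parameters\n",
              x$spec$classes, format(attr(pa, "total"), big.mark = ",")))
  cat(sprintf("trained %d epochs (%d iterations), stop: %s\n",
              x$epochs_run, x$iterations, x$stop_reason))
  tr <- x$history[x$history$split == "train", ]
  if (nrow(tr)) {
    last <- tr[nrow(tr), ]
    cat(sprintf("final training batch: loss %.4f, accuracy %.3f\n",
                last$loss, last$accuracy))
  }
  invisible(x)
}

#' @export
summary.fdnn <- function(object, ...) {
  cat("Model architecture:\n")
  print(object$spec)
  cat("\nTraining control:\n")
  ctl <- object$control
  cat(sprintf("  batch %d, lr %g, epsilon %g, dropout %g, max epochs %d\n",
              ctl$batch_size, ctl$lr, ctl$epsilon, ctl$dropout, ctl$epochs))
  print.fdnn(object)
  v <- object$history[object$history$split == "validation", ]
  if (nrow(v)) {
    cat(sprintf("best validation accuracy: %.3f\n", max(v$accuracy)))
  }
  invisible(object)
}

#' @export
coef.fdnn <- function(object, ...) object$params

#' Plot training history
#'
#' Loss and accuracy against iteration for the training (and, when
#' recorded, validation) cadence.
#'
#' @param x an [fdnn()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fdnn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no history recorded")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (what in c("loss", "accuracy")) {
    tr <- h[h$split == "train", ]
    v <- h[h$split == "validation", ]
    rng <- range(h[[what]], finite = TRUE)
    graphics::plot(tr$iteration, tr[[what]], type = "l", xlab = "iteration",
                   ylab = what, ylim = rng, ...)
    if (nrow(v)) graphics::lines(v$iteration, v[[what]], col = 2, lty = 2)
    if (what == "loss" && nrow(v)) {
      graphics::legend("topright", c("train", "validation"), col = 1:2,
                       lty = 1:2, bty = "n")
    }
  }
  invisible(x)
}

#' Export training history as CSV
#'
#' @param object an [fdnn()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(object, path) {
  stopifnot(inherits(object, "fdnn"))
  utils::write.csv(object$history, path, row.names = FALSE)
  invisible(path)
}
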