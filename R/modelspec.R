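#' Declarative CNN-LSTM layer and model specifications
#'
#' The fall-detection network is described declaratively as an ordered list
#' of layer specifications, so its shapes and trainable-parameter counts
#' can be audited by plain arithmetic, independently of any learning
#' framework, and the same spec drives the package's training engine.
#'
#' Layer kinds: `conv1d` (1-D convolution over time spanning all input
#' channels, SAME padding, stride 1, ReLU), `maxpool1d` (pool 2, stride 2,
#' SAME padding: output length `ceiling(L / 2)`), `reshape_split` (the
#' pooled temporal axis becomes the recurrent axis), `lstm` (tanh
#' activation, optional output dropout, forget-gate bias init), and `dense`
#' (softmax output).
#'
#' @param filters,kernel,stride,padding,activation convolution fields:
#'   number of filters, temporal kernel length (the kernel spans all input
#'   channels), stride (only 1 supported), padding (only `"SAME"`),
#'   activation.
#' @param pool,units,dropout,forget_bias other layer fields.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
layer_conv1d <- function(filters, kernel, stride = 1, padding = "SAME",
                         activation = "relu", in_channels = NULL) {
  stopifnot(filters >= 1, kernel >= 1, stride == 1, padding == "SAME",
            activation %in% c("relu", "tanh"))
  structure(list(kind = "conv1d", filters = as.integer(filters),
                 kernel = as.integer(kernel), stride = 1L,
                 padding = "SAME", activation = activation,
                 in_channels = if (!is.null(in_channels))
                   as.integer(in_channels)),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_maxpool1d <- function(pool = 2, stride = 2, padding = "SAME") {
  stopifnot(pool >= 1, stride >= 1, padding == "SAME")
  structure(list(kind = "maxpool1d", pool = as.integer(pool),
                 stride = as.integer(stride), padding = "SAME"),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_reshape_split <- function() {
  structure(list(kind = "reshape_split"), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_lstm <- function(units, dropout = 0.5, forget_bias = 1.0,
                       activation = "tanh") {
  stopifnot(units >= 1, dropout >= 0, dropout < 1, activation == "tanh")
  structure(list(kind = "lstm", units = as.integer(units), dropout = dropout,
                 forget_bias = forget_bias, activation = activation),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_dense <- function(units, activation = "softmax") {
  stopifnot(units >= 1, activation %in% c("softmax", "relu"))
  structure(list(kind = "dense", units = as.integer(units),
                 activation = activation), class = "layer_spec")
}

#' @rdname layer_spec
#' @param layers list of layer specs.
#' @param input_length input window length in timesteps (default 200, the
#'   2 s window at 100 Hz).
#' @param input_channels input channel count (default 6).
#' @param classes number of output classes (default 8).
#' @export
model_spec <- function(layers, input_length = 200, input_channels = 6,
                       classes = 8) {
  stopifnot(all(vapply(layers, inherits, TRUE, "layer_spec")))
  structure(list(layers = layers, input_length = as.integer(input_length),
                 input_channels = as.integer(input_channels),
                 classes = as.integer(classes)),
            class = "fdnn_model_spec")
}

#' The default fall-detection network architecture
#'
#' Builds the CNN-LSTM specification used throughout the package: a 200
#' timestep x 6 channel input; `conv_layers` convolution + max-pooling
#' blocks with 32/64/128/200 filters and temporal kernels 3/5/7/9 (SAME
#' padding, stride 1, ReLU; each pool halves the temporal axis with
#' ceiling rounding); a reshape that turns the pooled temporal axis into
#' the recurrent axis; two LSTM layers of 200 units each (tanh, dropout
#' 0.5, forget-gate bias 1.0); and a softmax dense layer over the 8
#' activity classes. With the default 4 blocks the temporal axis contracts
#' 200 -> 100 -> 50 -> 25 -> 13 and the LSTM input is 13 timesteps of 200
#' features.
#'
#' Fewer blocks truncate the sequence; a 5th or 6th block replicates the
#' 4th block's shape (200 filters, kernel 9).
#'
#' @param conv_layers number of convolution + pooling blocks, 1--6.
#' @param input_length,classes see [model_spec()].
#' @return an `fdnn_model_spec`.
#' @examples
#' spec <- default_model_spec()
#' audit_shapes(spec)
#' audit_params(spec)
#' @export
default_model_spec <- function(conv_layers = 4, input_length = 200,
                               classes = 8) {
  if (conv_layers < 1 || conv_layers > 6) {
    stop("conv_layers must be between 1 and 6", call. = FALSE)
  }
  filters <- c(32, 64, 128, 200, 200, 200)[seq_len(conv_layers)]
  kernels <- c(3, 5, 7, 9, 9, 9)[seq_len(conv_layers)]
  layers <- list()
  for (i in seq_len(conv_layers)) {
    layers <- c(layers, list(layer_conv1d(filters[i], kernels[i]),
                             layer_maxpool1d()))
  }
  layers <- c(layers, list(layer_reshape_split(),
                           layer_lstm(200), layer_lstm(200),
                           layer_dense(classes)))
  model_spec(layers, input_length = input_length, input_channels = 6,
             classes = classes)
}

#' Audit layer output shapes
#'
#' Propagates the input shape through the spec by arithmetic alone:
#' SAME-padded stride-1 convolutions preserve the temporal length and set
#' the feature count to the filter count; SAME-padded stride-2 pooling
#' yields `ceiling(L / 2)`; the reshape swaps nothing away (timesteps x
#' features pass through to the recurrent stack); each LSTM keeps the
#' timestep count and sets features to its unit count; the dense layer
#' consumes the last timestep.
#'
#' @param spec an `fdnn_model_spec`.
#' @return a `data.frame` with one row per layer: `layer`, `kind`,
#'   `timesteps`, `features`.
#' @export
audit_shapes <- function(spec) {
  stopifnot(inherits(spec, "fdnn_model_spec"))
  len <- spec$input_length
  feat <- spec$input_channels
  rows <- list()
  conv_i <- 0L; pool_i <- 0L; lstm_i <- 0L
  for (ly in spec$layers) {
    name <- switch(ly$kind,
      conv1d = { conv_i <- conv_i + 1L; paste0("C", conv_i) },
      maxpool1d = { pool_i <- pool_i + 1L; paste0("S", pool_i) },
      reshape_split = "reshape",
      lstm = { lstm_i <- lstm_i + 1L; paste0("L", lstm_i) },
      dense = "Fc")
    switch(ly$kind,
      conv1d = {
        if (!is.null(ly$in_channels) && ly$in_channels != feat) {
          stop("layer ", name, " declares ", ly$in_channels,
               " input channels but receives ", feat, call. = FALSE)
        }
        feat <- ly$filters                         # SAME, stride 1
      },
      maxpool1d = { len <- ceiling(len / ly$stride) },
      reshape_split = {},
      lstm = { feat <- ly$units },
      dense = { len <- 1L; feat <- ly$units })
    rows[[length(rows) + 1L]] <-
      data.frame(layer = name, kind = ly$kind, timesteps = as.integer(len),
                 features = as.integer(feat))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Audit trainable parameter counts
#'
#' Framework-independent parameter arithmetic per layer:
#' \itemize{
#'   \item conv1d: `filters * (kernel * in_channels) + filters`
#'   \item lstm: `4 * units * (input_dim + units + 1)` (four gates, input
#'     and recurrent weights, biases)
#'   \item dense: `units * input_dim + units`
#'   \item pooling and reshape layers: 0
#' }
#' For the default architecture this gives 608 parameters for the first
#' convolution (32 x 3 x 6 + 32) and 320,800 per LSTM layer
#' (4 x 200 x (200 + 200 + 1)).
#'
#' @param spec an `fdnn_model_spec`.
#' @return a `data.frame` with columns `layer`, `kind`, `params`, plus a
#'   `"total"` attribute; `sum(out$params)` equals the total.
#' @export
audit_params <- function(spec) {
  stopifnot(inherits(spec, "fdnn_model_spec"))
  shapes <- audit_shapes(spec)
  in_feat <- c(spec$input_channels, shapes$features[-nrow(shapes)])
  params <- integer(nrow(shapes))
  for (i in seq_len(nrow(shapes))) {
    ly <- spec$layers[[i]]
    params[i] <- switch(ly$kind,
      conv1d = ly$filters * (ly$kernel * in_feat[i]) + ly$filters,
      lstm = 4L * ly$units * (in_feat[i] + ly$units + 1L),
      dense = ly$units * in_feat[i] + ly$units,
      0L)
  }
  out <- data.frame(layer = shapes$layer, kind = shapes$kind, params = params)
  attr(out, "total") <- sum(params)
  out
}

#' @export
print.fdnn_model_spec <- function(x, ...) {
  sh <- audit_shapes(x)
  pa <- audit_params(x)
  cat(sprintf("<fdnn_model_spec> input %d x %d, %d classes\n",
              x$input_length, x$input_channels, x$classes))
  tab <- cbind(sh, params = pa$params)
  print(tab, row.names = FALSE)
  cat(sprintf("total trainable parameters: %s\n",
              format(attr(pa, "total"), big.mark = ",")))
  invisible(x)
}

#' Serialize a model spec to a structured text document
#'
#' Writes/reads the layer list as JSON so architectures can be exchanged
#' and audited outside R.
#'
#' @param spec an `fdnn_model_spec`.
#' @param path file path.
#' @return `read_model_spec()` returns an `fdnn_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "fdnn_model_spec"))
  obj <- list(input_length = spec$input_length,
              input_channels = spec$input_channels, classes = spec$classes,
              layers = lapply(spec$layers, unclass))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(obj$layers, function(l) {
    switch(l$kind,
      conv1d = layer_conv1d(l$filters, l$kernel, l$stride, l$padding,
                            l$activation),
      maxpool1d = layer_maxpool1d(l$pool, l$stride, l$padding),
      reshape_split = layer_reshape_split(),
      lstm = layer_lstm(l$units, l$dropout, l$forget_bias, l$activation),
      dense = layer_dense(l$units, l$activation),
      stop("unknown layer kind: ", l$kind, call. = FALSE))
  })
  model_spec(layers, input_length = obj$input_length,
             input_channels = obj$input_channels, classes = obj$classes)
}
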