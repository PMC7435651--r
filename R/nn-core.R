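#' Numerically stable softmax
#'
#' `softmax(x)_i = exp(x_i) / sum_j exp(x_j)`, computed with the row
#' maximum subtracted first so no finite input overflows. Rows of a matrix
#' are treated as independent logit vectors. Softmax is invariant to adding
#' a constant to all logits; outputs are positive and sum to 1.
#'
#' @param x numeric vector of logits, or matrix with one logit vector per
#'   row.
#' @return probabilities with the same shape as `x`.
#' @examples
#' softmax(c(0, log(2)))  # 1/3, 2/3
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) {
    e <- exp(x - max(x))
    e / sum(e)
  } else {
    e <- exp(x - apply(x, 1, max))
    e / rowSums(e)
  }
}

#' One-hot encoding of class labels
#'
#' @param labels integer vector of class codes in `[0, k)`.
#' @param k number of classes.
#' @return an `n x k` 0/1 matrix whose rows sum to 1; `argmax` of each row
#'   recovers the label.
#' @export
one_hot <- function(labels, k) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= k)) {
    stop("labels must lie in [0, ", k, ")", call. = FALSE)
  }
  m <- matrix(0, length(labels), k)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Mean cross-entropy loss
#'
#' `loss = -(1/n) * sum_i sum_k y'_ik * log(y_ik)` for one-hot targets
#' `y'` and predicted probabilities `y`. The log argument is clamped at
#' `floor` so a confidently wrong prediction yields a large finite loss
#' rather than infinity.
#'
#' @param y_true one-hot `n x k` matrix.
#' @param y_pred probability `n x k` matrix (rows sum to 1).
#' @param floor lower clamp for the log argument.
#' @return non-negative scalar loss.
#' @examples
#' p <- matrix(1 / 8, 1, 8)
#' cross_entropy(one_hot(3L, 8), p)  # log(8)
#' @export
cross_entropy <- function(y_true, y_pred, floor = 1e-12) {
  if (!all(dim(y_true) == dim(y_pred))) {
    stop("y_true and y_pred shapes differ", call. = FALSE)
  }
  -sum(y_true * log(pmax(y_pred, floor))) / nrow(y_true)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nin, nout, nr, nc = nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- conv1d, SAME padding, stride 1 ------------------------------------
# X: array (B, T, C). Weights W: (kernel*C, F) matrix; bias length F.
# im2col: rows enumerate (batch, timestep) pairs, batch fastest, so
# matrix(A, nrow = B*T) and array(Y, c(B, T, F)) are exact inverses.

.conv1d_fwd <- function(X, W, b, kernel, relu = TRUE) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  pl <- (kernel - 1L) %/% 2L
  Ap <- array(0, c(B, T + kernel - 1L, C))
  Ap[, pl + seq_len(T), ] <- X
  cols <- matrix(0, B * T, kernel * C)
  for (j in seq_len(kernel)) {
    cols[, (j - 1L) * C + seq_len(C)] <-
      matrix(Ap[, j:(j + T - 1L), , drop = FALSE], nrow = B * T)
  }
  Z <- cols %*% W
  Z <- sweep(Z, 2, b, "+")
  A <- if (relu) pmax(Z, 0) else Z
  list(out = array(A, c(B, T, ncol(W))),
       cache = list(cols = cols, Z = Z, dimX = d, kernel = kernel,
                    pl = pl, relu = relu))
}

.conv1d_bwd <- function(dOut, W, cache) {
  d <- cache$dimX; B <- d[1]; T <- d[2]; C <- d[3]
  kernel <- cache$kernel
  dA <- matrix(dOut, nrow = B * T)
  dZ <- if (cache$relu) dA * (cache$Z > 0) else dA
  dW <- crossprod(cache$cols, dZ)
  db <- colSums(dZ)
  dcols <- dZ %*% t(W)
  dAp <- array(0, c(B, T + kernel - 1L, C))
  for (j in seq_len(kernel)) {
    dAp[, j:(j + T - 1L), ] <- dAp[, j:(j + T - 1L), , drop = FALSE] +
      array(dcols[, (j - 1L) * C + seq_len(C)], c(B, T, C))
  }
  list(dX = dAp[, cache$pl + seq_len(T), , drop = FALSE], dW = dW, db = db)
}

# ---- max pooling, pool 2 stride 2, SAME (ceiling length) ---------------

.maxpool_fwd <- function(X) {
  d <- dim(X); B <- d[1]; T <- d[2]; F_ <- d[3]
  T2 <- as.integer(ceiling(T / 2))
  X1 <- X[, seq(1L, by = 2L, length.out = T2), , drop = FALSE]
  idx2 <- seq(2L, by = 2L, length.out = T2)
  pad <- idx2 > T
  idx2[pad] <- T  # placeholder, masked to -Inf below
  X2 <- X[, idx2, , drop = FALSE]
  if (any(pad)) X2[, pad, ] <- -Inf
  mask <- X1 >= X2
  list(out = ifelse(mask, X1, X2),
       cache = list(mask = mask, dimX = d, T2 = T2, pad = pad))
}

.maxpool_bwd <- function(dOut, cache) {
  d <- cache$dimX; B <- d[1]; T <- d[2]; F_ <- d[3]
  T2 <- cache$T2
  dX <- array(0, d)
  d1 <- dOut * cache$mask
  d2 <- dOut * !cache$mask
  dX[, seq(1L, by = 2L, length.out = T2), ] <- d1
  even_in <- seq(2L, by = 2L, length.out = T2)
  keep <- !cache$pad
  if (any(keep)) {
    dX[, even_in[keep], ] <- dX[, even_in[keep], , drop = FALSE] +
      d2[, keep, , drop = FALSE]
  }
  dX
}

# ---- LSTM ---------------------------------------------------------------
# Gate order in the fused weight matrix: input, forget, candidate, output.
# W: (in + units) x 4*units; bias: 4*units with the forget slice
# initialised to forget_bias. Cell and hidden state start at zero.
# Inverted dropout is applied to the emitted output sequence only (the
# recurrent path is undropped), active during training only.

.lstm_init <- function(in_dim, units, forget_bias) {
  W <- .glorot(in_dim + units, units, in_dim + units, 4L * units)
  b <- rep(0, 4L * units)
  b[units + seq_len(units)] <- forget_bias
  list(W = W, b = b)
}

# The fused weight matrix is split into its input rows (Wx) and recurrent
# rows (Wh); input projections for all timesteps are computed in one BLAS
# call, so only the recurrent half runs inside the time loop. Rows of the
# (B*T) matrices enumerate (batch, timestep) pairs, batch fastest, matching
# the column-major flattening of the (B, T, .) arrays.

.lstm_fwd <- function(X, W, b, units, dropout = 0, training = FALSE) {
  d <- dim(X); B <- d[1]; T <- d[2]; in_dim <- d[3]
  Wx <- W[seq_len(in_dim), , drop = FALSE]
  Wh <- W[in_dim + seq_len(units), , drop = FALSE]
  Xmat <- matrix(X, B * T, in_dim)
  Zx <- sweep(Xmat %*% Wx, 2, b, "+")
  h <- matrix(0, B, units)
  cc <- matrix(0, B, units)
  Ymat <- matrix(0, B * T, units)
  Hprev <- matrix(0, B * T, units)
  mask <- if (training && dropout > 0) {
    matrix(stats::runif(B * T * units) >= dropout, B * T, units)
  }
  steps <- vector("list", T)
  iU <- seq_len(units)
  for (t in seq_len(T)) {
    rows <- (t - 1L) * B + seq_len(B)
    z <- Zx[rows, , drop = FALSE] + h %*% Wh
    gi <- .sigmoid(z[, iU, drop = FALSE])
    gf <- .sigmoid(z[, units + iU, drop = FALSE])
    gg <- tanh(z[, 2L * units + iU, drop = FALSE])
    go <- .sigmoid(z[, 3L * units + iU, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    hc <- tanh(cc)
    Hprev[rows, ] <- h
    h <- go * hc
    Ymat[rows, ] <- if (is.null(mask)) h else {
      h * mask[rows, , drop = FALSE] / (1 - dropout)
    }
    steps[[t]] <- list(c_prev = c_prev, gi = gi, gf = gf, gg = gg,
                       go = go, hc = hc)
  }
  list(out = array(Ymat, c(B, T, units)),
       cache = list(steps = steps, mask = mask, Xmat = Xmat, Hprev = Hprev,
                    dimX = d, units = units, dropout = dropout))
}

.lstm_bwd <- function(dOut, W, cache) {
  d <- cache$dimX; B <- d[1]; T <- d[2]; in_dim <- d[3]
  units <- cache$units
  Wx <- W[seq_len(in_dim), , drop = FALSE]
  Wh <- W[in_dim + seq_len(units), , drop = FALSE]
  tWh <- t(Wh)
  dYmat <- matrix(dOut, B * T, units)
  if (!is.null(cache$mask)) {
    dYmat <- dYmat * cache$mask / (1 - cache$dropout)
  }
  dZmat <- matrix(0, B * T, 4L * units)
  dh_next <- matrix(0, B, units)
  dc_next <- matrix(0, B, units)
  for (t in rev(seq_len(T))) {
    s <- cache$steps[[t]]
    rows <- (t - 1L) * B + seq_len(B)
    dh <- dYmat[rows, , drop = FALSE] + dh_next
    dgo <- dh * s$hc
    dc <- dc_next + dh * s$go * (1 - s$hc^2)
    dz <- cbind(dc * s$gg * s$gi * (1 - s$gi),
                dc * s$c_prev * s$gf * (1 - s$gf),
                dc * s$gi * (1 - s$gg^2),
                dgo * s$go * (1 - s$go))
    dZmat[rows, ] <- dz
    dh_next <- dz %*% tWh
    dc_next <- dc * s$gf
  }
  dW <- rbind(crossprod(cache$Xmat, dZmat), crossprod(cache$Hprev, dZmat))
  list(dX = array(dZmat %*% t(Wx), d), dW = dW, db = colSums(dZmat))
}

# ---- Adam ---------------------------------------------------------------

.adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

.adam_step <- function(params, grads, state, t, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  for (k in names(params)) {
    g <- grads[[k]]
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    state[[k]] <- st
  }
  list(params = params, state = state)
}
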