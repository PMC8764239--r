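# Compact CNN-LSTM classifier for 1-D feature vectors, built from base
# matrix algebra. Stack (for the default length-66 connectivity input):
#   input (L x 1) -> conv1d(16, k3, same, relu) -> conv1d(32, k3, same, relu)
#   -> LSTM(32, sequences) -> LSTM(32, last state) -> batch normalization
#   -> flatten (width 32) -> dense(16, relu) -> dropout(0.2)
#   -> dense(8, relu) -> dropout(0.2) -> softmax over classes.
# Trained with Adam on cross-entropy. Gradients for every layer are
# verified against numerical differentiation in the test suite.

#' CNN-LSTM architecture configuration
#'
#' Declares the layer stack and training hyperparameters. [cnn_lstm_fit()]
#' validates the configured `input_length` against the data and reports a
#' configuration error listing expected vs got on mismatch.
#'
#' @param input_length Expected feature-vector length (default 66, the
#'   undirected 12-channel connectivity layout).
#' @param filters Two conv1d filter counts, default `c(16, 32)`.
#' @param kernel Conv kernel size, default 3 (stride 1, same padding).
#' @param lstm_units Two recurrent layer widths, default `c(32, 32)`.
#' @param dense Two dense widths, default `c(16, 8)`.
#' @param dropout Dropout rate after each dense layer, default 0.2.
#' @param learning_rate Adam learning rate, default 1e-3.
#' @param epochs Training epochs, default 30.
#' @param batch_size Minibatch size, default 32.
#' @return An object of class `cnn_lstm_config`.
#' @export
cnn_lstm_config <- function(input_length = 66, filters = c(16, 32),
                            kernel = 3, lstm_units = c(32, 32),
                            dense = c(16, 8), dropout = 0.2,
                            learning_rate = 1e-3, epochs = 30,
                            batch_size = 32) {
  stopifnot(length(filters) == 2, length(lstm_units) == 2, length(dense) == 2)
  structure(as.list(environment()), class = "cnn_lstm_config")
}

#' Layer-by-layer output shapes of a CNN-LSTM configuration
#'
#' Builds the model symbolically and returns the per-layer output widths;
#' useful to verify the stack (e.g. flatten width 32 for the default).
#'
#' @param config A [cnn_lstm_config()].
#' @param n_classes Number of output classes.
#' @return Data.frame of layer names and output shapes.
#' @export
cnn_lstm_shapes <- function(config, n_classes) {
  L <- config$input_length
  data.frame(
    layer = c("input", "conv1", "conv2", "lstm1", "lstm2", "batchnorm",
              "flatten", "dense1", "dropout1", "dense2", "dropout2",
              "output"),
    shape = c(paste0(L, "x1"),
              paste0(L, "x", config$filters[1]),
              paste0(L, "x", config$filters[2]),
              paste0(L, "x", config$lstm_units[1]),
              as.character(config$lstm_units[2]),
              as.character(config$lstm_units[2]),
              as.character(config$lstm_units[2]),
              as.character(config$dense[1]),
              as.character(config$dense[1]),
              as.character(config$dense[2]),
              as.character(config$dense[2]),
              as.character(n_classes)),
    stringsAsFactors = FALSE
  )
}

#' Fit the CNN-LSTM classifier
#'
#' @param x Samples x features matrix; `ncol(x)` must equal
#'   `config$input_length`.
#' @param y Class labels.
#' @param config A [cnn_lstm_config()].
#' @param seed Integer seed (initialization, shuffling, dropout).
#' @param verbose Print per-epoch loss.
#' @return An object of class `cnn_lstm`.
#' @export
cnn_lstm_fit <- function(x, y, config = cnn_lstm_config(ncol(x)), seed = 1,
                         verbose = FALSE) {
  if (ncol(x) != config$input_length) {
    stop_config("input shape mismatch: expected 1 x ", config$input_length,
                ", got 1 x ", ncol(x))
  }
  y <- as.factor(y)
  classes <- levels(droplevels(y))
  if (length(classes) < 2L) stop_input("need at least 2 classes")
  yi <- match(as.character(y), classes)
  n <- nrow(x)
  withr::with_seed(seed, {
    params <- .cl_init(config, n_classes = length(classes))
    state <- .cl_bn_state(config$lstm_units[2])
    opt <- adam_init(params)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      loss <- 0; nb <- 0L
      for (s in seq(1, n, by = config$batch_size)) {
        idx <- perm[s:min(s + config$batch_size - 1, n)]
        fw <- .cl_forward(x[idx, , drop = FALSE], params, config,
                          state = state, training = TRUE)
        state <- fw$state
        m <- length(idx)
        loss <- loss - mean(log(pmax(fw$probs[cbind(seq_len(m), yi[idx])],
                                     1e-12)))
        nb <- nb + 1L
        grads <- .cl_backward(fw, yi[idx], params, config)
        upd <- adam_step(opt, params, grads, config$learning_rate)
        opt <- upd$opt
        params <- upd$params
      }
      if (verbose) message(sprintf("epoch %d loss %.4f", epoch, loss / nb))
    }
    structure(list(params = params, state = state, config = config,
                   classes = classes), class = "cnn_lstm")
  })
}

#' @rdname cnn_lstm_fit
#' @param object A fitted `cnn_lstm`.
#' @param newdata Samples x features matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @export
predict.cnn_lstm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (ncol(newdata) != object$config$input_length) {
    stop_config("input shape mismatch: expected 1 x ",
                object$config$input_length, ", got 1 x ", ncol(newdata))
  }
  probs <- .cl_forward(newdata, object$params, object$config,
                       state = object$state, training = FALSE)$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, "first")]
}

# ---- parameters -------------------------------------------------------------

.glorot <- function(nr, nc) {
  bound <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -bound, bound), nr, nc)
}

.cl_init <- function(cfg, n_classes) {
  k <- cfg$kernel
  f1 <- cfg$filters[1]; f2 <- cfg$filters[2]
  u1 <- cfg$lstm_units[1]; u2 <- cfg$lstm_units[2]
  d1 <- cfg$dense[1]; d2 <- cfg$dense[2]
  lstm_b <- function(u) {            # unit forget-gate bias
    b <- numeric(4 * u); b[(u + 1):(2 * u)] <- 1; b
  }
  list(
    cW1 = .glorot(k * 1, f1),  cb1 = numeric(f1),
    cW2 = .glorot(k * f1, f2), cb2 = numeric(f2),
    l1Wx = .glorot(f2, 4 * u1), l1Wh = .glorot(u1, 4 * u1), l1b = lstm_b(u1),
    l2Wx = .glorot(u1, 4 * u2), l2Wh = .glorot(u2, 4 * u2), l2b = lstm_b(u2),
    bn_gamma = rep(1, u2), bn_beta = numeric(u2),
    dW1 = .glorot(u2, d1), db1 = numeric(d1),
    dW2 = .glorot(d1, d2), db2 = numeric(d2),
    dW3 = .glorot(d2, n_classes), db3 = numeric(n_classes)
  )
}

.cl_bn_state <- function(u) list(mean = numeric(u), var = rep(1, u))

# ---- conv1d (same padding, stride 1) ---------------------------------------

.im2col <- function(a, k) {        # a: [B, L, C] zero-padded internally
  d <- dim(a); B <- d[1]; L <- d[2]; C <- d[3]
  pad <- (k - 1) / 2
  ap <- array(0, c(B, L + 2 * pad, C))
  ap[, pad + seq_len(L), ] <- a
  cols <- lapply(seq_len(k), function(j) {
    matrix(ap[, j:(j + L - 1), , drop = FALSE], B * L, C)
  })
  do.call(cbind, cols)
}

.col2im <- function(dcol, k, B, L, C) {
  pad <- (k - 1) / 2
  dap <- array(0, c(B, L + 2 * pad, C))
  for (j in seq_len(k)) {
    block <- array(dcol[, ((j - 1) * C + 1):(j * C), drop = FALSE], c(B, L, C))
    dap[, j:(j + L - 1), ] <- dap[, j:(j + L - 1), , drop = FALSE] + block
  }
  dap[, pad + seq_len(L), , drop = FALSE]
}

.conv_fwd <- function(a, W, b, k) {
  d <- dim(a); B <- d[1]; L <- d[2]
  xc <- .im2col(a, k)
  z <- sweep(xc %*% W, 2, b, "+")
  list(out = array(z, c(B, L, ncol(W))), xcol = xc)
}

.conv_bwd <- function(dz, cache_xcol, W, k, B, L, Cin) {
  dz_m <- matrix(dz, B * L, dim(dz)[3])
  list(dW = crossprod(cache_xcol, dz_m),
       db = colSums(dz_m),
       dx = .col2im(dz_m %*% t(W), k, B, L, Cin))
}

# ---- LSTM ------------------------------------------------------------------

.sigm <- function(z) 1 / (1 + exp(-z))

.lstm_fwd <- function(x, Wx, Wh, b, return_sequences) {
  d <- dim(x); B <- d[1]; L <- d[2]
  U <- nrow(Wh)
  h <- matrix(0, B, U); cc <- matrix(0, B, U)
  cache <- vector("list", L)
  H <- if (return_sequences) array(0, c(B, L, U)) else NULL
  for (t in seq_len(L)) {
    xt <- matrix(x[, t, , drop = FALSE], B, d[3])
    z <- sweep(xt %*% Wx + h %*% Wh, 2, b, "+")
    i <- .sigm(z[, 1:U, drop = FALSE])
    f <- .sigm(z[, (U + 1):(2 * U), drop = FALSE])
    g <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
    o <- .sigm(z[, (3 * U + 1):(4 * U), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev_cache <- h
    h <- o * tc
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc, h_prev = h_prev_cache)
    if (return_sequences) H[, t, ] <- h
  }
  list(out = if (return_sequences) H else h, cache = cache, last = h)
}

# dH: [B, L, U] when the layer returned sequences, else dlast [B, U]
.lstm_bwd <- function(dH, dlast, x, Wx, Wh, cache) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  U <- nrow(Wh)
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * U)
  dx <- array(0, c(B, L, Cin))
  dh_next <- if (is.null(dlast)) matrix(0, B, U) else dlast
  dc_next <- matrix(0, B, U)
  for (t in rev(seq_len(L))) {
    ca <- cache[[t]]
    dh <- dh_next
    if (!is.null(dH)) dh <- dh + matrix(dH[, t, , drop = FALSE], B, U)
    do_ <- dh * ca$tc
    dc <- dc_next + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    dc_next <- dc * ca$f
    dz <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dWx <- dWx + crossprod(ca$xt, dz)
    dWh <- dWh + crossprod(ca$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

# ---- batch normalization ----------------------------------------------------

.bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.9,
                    eps = 1e-5) {
  if (training && nrow(x) > 1) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  ivstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, ivstd, "*")
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, ivstd = ivstd, state = state,
       batch_stats = training && nrow(x) > 1)
}

.bn_bwd <- function(dy, cache, gamma) {
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  if (!cache$batch_stats) {
    return(list(dx = sweep(dxhat, 2, cache$ivstd, "*"),
                dgamma = dgamma, dbeta = dbeta))
  }
  dx <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dy), byrow = TRUE) -
                sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*"),
              2, cache$ivstd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- full network -----------------------------------------------------------

.cl_forward <- function(x, p, cfg, state, training = FALSE) {
  B <- nrow(x); L <- ncol(x); k <- cfg$kernel
  a0 <- array(x, c(B, L, 1))
  cv1 <- .conv_fwd(a0, p$cW1, p$cb1, k)
  r1 <- pmax(cv1$out, 0)
  cv2 <- .conv_fwd(r1, p$cW2, p$cb2, k)
  r2 <- pmax(cv2$out, 0)
  ls1 <- .lstm_fwd(r2, p$l1Wx, p$l1Wh, p$l1b, return_sequences = TRUE)
  ls2 <- .lstm_fwd(ls1$out, p$l2Wx, p$l2Wh, p$l2b, return_sequences = FALSE)
  bn <- .bn_fwd(ls2$out, p$bn_gamma, p$bn_beta, state, training)
  z1 <- sweep(bn$out %*% p$dW1, 2, p$db1, "+")
  a1 <- pmax(z1, 0)
  dm1 <- if (training && cfg$dropout > 0) {
    (matrix(runif(length(a1)), nrow(a1)) >= cfg$dropout) / (1 - cfg$dropout)
  } else 1
  a1d <- a1 * dm1
  z2 <- sweep(a1d %*% p$dW2, 2, p$db2, "+")
  a2 <- pmax(z2, 0)
  dm2 <- if (training && cfg$dropout > 0) {
    (matrix(runif(length(a2)), nrow(a2)) >= cfg$dropout) / (1 - cfg$dropout)
  } else 1
  a2d <- a2 * dm2
  zo <- sweep(a2d %*% p$dW3, 2, p$db3, "+")
  zo <- zo - apply(zo, 1, max)
  e <- exp(zo)
  probs <- e / rowSums(e)
  list(probs = probs, state = bn$state,
       cache = list(x = x, a0 = a0, cv1 = cv1, r1 = r1, cv2 = cv2, r2 = r2,
                    ls1 = ls1, ls2 = ls2, bn = bn, a1 = a1, dm1 = dm1,
                    a1d = a1d, a2 = a2, dm2 = dm2, a2d = a2d))
}

.cl_backward <- function(fw, yi, p, cfg) {
  ca <- fw$cache
  B <- nrow(ca$x); L <- ncol(ca$x); k <- cfg$kernel
  m <- length(yi)
  delta <- fw$probs
  delta[cbind(seq_len(m), yi)] <- delta[cbind(seq_len(m), yi)] - 1
  delta <- delta / m
  g <- list()
  g$dW3 <- crossprod(ca$a2d, delta); g$db3 <- colSums(delta)
  d2 <- (delta %*% t(p$dW3)) * ca$dm2 * (ca$a2 > 0)
  g$dW2 <- crossprod(ca$a1d, d2); g$db2 <- colSums(d2)
  d1 <- (d2 %*% t(p$dW2)) * ca$dm1 * (ca$a1 > 0)
  g$dW1 <- crossprod(ca$bn$out, d1); g$db1 <- colSums(d1)
  dbn_out <- d1 %*% t(p$dW1)
  bnb <- .bn_bwd(dbn_out, ca$bn, p$bn_gamma)
  g$bn_gamma <- bnb$dgamma; g$bn_beta <- bnb$dbeta
  l2b <- .lstm_bwd(NULL, bnb$dx, ca$ls1$out, p$l2Wx, p$l2Wh, ca$ls2$cache)
  g$l2Wx <- l2b$dWx; g$l2Wh <- l2b$dWh; g$l2b <- l2b$db
  l1b <- .lstm_bwd(l2b$dx, NULL, ca$r2, p$l1Wx, p$l1Wh, ca$ls1$cache)
  g$l1Wx <- l1b$dWx; g$l1Wh <- l1b$dWh; g$l1b <- l1b$db
  dr2 <- l1b$dx * (ca$cv2$out > 0)
  c2b <- .conv_bwd(dr2, ca$cv2$xcol, p$cW2, k, B, L, cfg$filters[1])
  g$cW2 <- c2b$dW; g$cb2 <- c2b$db
  dr1 <- c2b$dx * (ca$cv1$out > 0)
  c1b <- .conv_bwd(dr1, ca$cv1$xcol, p$cW1, k, B, L, 1)
  g$cW1 <- c1b$dW; g$cb1 <- c1b$db
  g[names(p)]
}
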