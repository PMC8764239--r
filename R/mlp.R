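# Two-hidden-layer perceptron trained with Adam on softmax cross-entropy.
# Defaults mirror the evaluation protocol: hidden layers 200/200 (relu),
# L2 penalty alpha = 1e-7, initial learning rate 1e-3, at most 380 epochs
# over minibatches of <= 200, early stopping when the epoch training loss
# stalls (tol 1e-4 for 10 consecutive epochs).

#' Fit a multi-layer perceptron classifier
#'
#' @param x Numeric matrix, samples x features (standardize first).
#' @param y Class labels.
#' @param hidden Hidden layer widths, default `c(200, 200)`.
#' @param alpha L2 penalty, default `1e-7`.
#' @param learning_rate Initial Adam learning rate, default `1e-3`.
#' @param max_iter Maximum training epochs, default 380.
#' @param batch_size Minibatch size, default `min(200, n)`.
#' @param tol,n_iter_no_change Early-stopping rule on the training loss.
#' @param seed Integer seed (initialization and shuffling).
#' @return An object of class `mlp`, with `converged` flagging whether the
#'   loss stalled before `max_iter` (non-convergence is flagged, not an
#'   error).
#' @export
mlp_fit <- function(x, y, hidden = c(200, 200), alpha = 1e-7,
                    learning_rate = 1e-3, max_iter = 380,
                    batch_size = NULL, tol = 1e-4, n_iter_no_change = 10,
                    seed = 1) {
  y <- as.factor(y)
  classes <- levels(droplevels(y))
  if (length(classes) < 2L) stop_input("need at least 2 classes")
  n <- nrow(x)
  yi <- match(as.character(y), classes)
  sizes <- c(ncol(x), hidden, length(classes))
  if (is.null(batch_size)) batch_size <- min(200L, n)
  withr::with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      bound <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -bound, bound),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    opt <- adam_init(c(W, b))
    best_loss <- Inf
    stall <- 0L
    n_epochs <- 0L
    converged <- FALSE
    for (epoch in seq_len(max_iter)) {
      n_epochs <- epoch
      perm <- sample.int(n)
      epoch_loss <- 0
      n_batches <- 0L
      for (s in seq(1, n, by = batch_size)) {
        idx <- perm[s:min(s + batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        fw <- mlp_forward(xb, W, b)
        m <- length(idx)
        ll <- -mean(log(pmax(fw$probs[cbind(seq_len(m), yi[idx])], 1e-12)))
        l2 <- alpha * 0.5 * sum(vapply(W, function(w) sum(w^2), 0)) / m
        epoch_loss <- epoch_loss + ll + l2
        n_batches <- n_batches + 1L
        # backward
        delta <- fw$probs
        delta[cbind(seq_len(m), yi[idx])] <-
          delta[cbind(seq_len(m), yi[idx])] - 1
        delta <- delta / m
        gW <- vector("list", length(W)); gb <- gW
        for (l in rev(seq_along(W))) {
          a_prev <- if (l == 1) xb else fw$acts[[l - 1]]
          gW[[l]] <- crossprod(a_prev, delta) + (alpha / m) * W[[l]]
          gb[[l]] <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(W[[l]])) * (fw$acts[[l - 1]] > 0)
          }
        }
        upd <- adam_step(opt, c(W, b), c(gW, gb), learning_rate)
        opt <- upd$opt
        W <- upd$params[seq_along(W)]
        b <- upd$params[length(W) + seq_along(b)]
      }
      epoch_loss <- epoch_loss / n_batches
      if (epoch_loss > best_loss - tol) stall <- stall + 1L else stall <- 0L
      best_loss <- min(best_loss, epoch_loss)
      if (stall >= n_iter_no_change) { converged <- TRUE; break }
    }
    structure(list(W = W, b = b, classes = classes, p = ncol(x),
                   n_epochs = n_epochs, loss = best_loss,
                   converged = converged),
              class = "mlp")
  })
}

mlp_forward <- function(x, W, b) {
  acts <- vector("list", length(W) - 1)
  a <- x
  for (l in seq_len(length(W) - 1)) {
    a <- pmax(sweep(a %*% W[[l]], 2, b[[l]], "+"), 0)
    acts[[l]] <- a
  }
  z <- sweep(a %*% W[[length(W)]], 2, b[[length(W)]], "+")
  z <- z - apply(z, 1, max)
  e <- exp(z)
  list(acts = acts, probs = e / rowSums(e))
}

#' @rdname mlp_fit
#' @param object A fitted `mlp`.
#' @param newdata Samples x features matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @export
predict.mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (ncol(newdata) != object$p) {
    stop_input("expected ", object$p, " features, got ", ncol(newdata))
  }
  probs <- mlp_forward(newdata, object$W, object$b)$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs, "first")]
}

# ---- shared Adam optimizer state -------------------------------------------

adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(params)) {
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * grads[[i]]
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}
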