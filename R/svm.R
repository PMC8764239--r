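# Linear support vector machine, one-vs-one multiclass, trained by dual
# coordinate descent (compiled in src/). Features are expected standardized
# by the caller (the evaluators handle per-fold standardization).

#' Fit a linear SVM
#'
#' L2-regularized hinge-loss linear SVM. Multiclass problems use one-vs-one
#' majority voting (ties broken by the summed decision values).
#'
#' @param x Numeric matrix, samples x features.
#' @param y Class labels (factor or character), >= 2 classes.
#' @param C Soft-margin cost (default 1).
#' @param max_passes Maximum coordinate-descent passes.
#' @param seed Integer seed controlling the coordinate order.
#' @return An object of class `linear_svm`.
#' @export
svm_fit <- function(x, y, C = 1, max_passes = 200, seed = 1) {
  y <- as.factor(y)
  classes <- levels(droplevels(y))
  if (length(classes) < 2L) stop_input("need at least 2 classes")
  if (!all(is.finite(x))) stop_input("features must be finite")
  xa <- cbind(x, bias = 1)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(seq_along(pairs), function(pi) {
    pr <- pairs[[pi]]
    sel <- y %in% pr
    yy <- ifelse(y[sel] == pr[1], 1, -1)
    w <- svm_dcd_train(xa[sel, , drop = FALSE], yy, C, max_passes,
                       1e-3, seed + pi)
    list(pair = pr, w = w)
  })
  structure(list(models = models, classes = classes, p = ncol(x)),
            class = "linear_svm")
}

#' @rdname svm_fit
#' @param object A fitted `linear_svm`.
#' @param newdata Samples x features matrix.
#' @param ... Unused.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  if (ncol(newdata) != object$p) {
    stop_input("expected ", object$p, " features, got ", ncol(newdata))
  }
  xa <- cbind(newdata, 1)
  votes <- matrix(0, nrow(xa), length(object$classes),
                  dimnames = list(NULL, object$classes))
  margin <- votes
  for (m in object$models) {
    d <- drop(xa %*% m$w)
    pos <- d >= 0
    votes[pos, m$pair[1]] <- votes[pos, m$pair[1]] + 1
    votes[!pos, m$pair[2]] <- votes[!pos, m$pair[2]] + 1
    margin[, m$pair[1]] <- margin[, m$pair[1]] + d
    margin[, m$pair[2]] <- margin[, m$pair[2]] - d
  }
  # majority vote, ties by summed decision value
  object$classes[max.col(votes + 1e-9 * margin, ties.method = "first")]
}
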