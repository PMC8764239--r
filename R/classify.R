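# Evaluation protocol: stratified splits and cross-validation, per-fold
# feature standardization (fit on training data only), repeat-averaged
# accuracy and wall time per classifier.

#' Stratified train/validation split
#'
#' Disjoint, exhaustive, uniformly random under `seed`, stratified so each
#' class's proportion in the training set tracks the full set. With the
#' protocol's sizes, 2,312 epochs split into 1,622 training and 690
#' validation samples.
#'
#' @param labels Class label per sample.
#' @param n_train Training-set size, `0 < n_train < length(labels)`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
train_validation_split <- function(labels, n_train, seed = 1) {
  n <- length(labels)
  if (n_train >= n || n_train < 1) {
    stop_input("`n_train` must be in [1, ", n - 1, "]; got ", n_train)
  }
  labels <- as.character(labels)
  withr::with_seed(seed, {
    classes <- unique(labels)
    # largest-remainder apportionment of n_train over classes
    counts <- table(labels)[classes]
    exact <- as.numeric(counts) * n_train / n
    take <- floor(exact)
    rem <- n_train - sum(take)
    if (rem > 0) {
      extra <- order(exact - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1
    }
    train <- integer(0)
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      train <- c(train, sample(idx, min(take[ci], length(idx))))
    }
    train <- sort(train)
    list(train = train, validation = setdiff(seq_len(n), train))
  })
}

# standardization fit on the training rows only (leakage guard)
fit_scaler <- function(x_train) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(x, sc) {
  sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")
}

new_evaluation_result <- function(feature_name, classifier, accuracies,
                                  times, n_train, n_validation,
                                  flags = character(0)) {
  structure(list(feature_name = feature_name, classifier = classifier,
                 accuracies = accuracies, mean_accuracy = mean(accuracies),
                 sd_accuracy = if (length(accuracies) > 1) stats::sd(accuracies) else 0,
                 times = times, mean_time = mean(times),
                 n_train = n_train, n_validation = n_validation,
                 flags = flags),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s / %s: %.2f%% (sd %.2f, %d run%s, %.2fs)\n",
              x$feature_name, x$classifier, x$mean_accuracy, x$sd_accuracy,
              length(x$accuracies), if (length(x$accuracies) > 1) "s" else "",
              x$mean_time))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Cross-validated linear SVM accuracy
#'
#' Linear-kernel SVM under leave-one-out (`"loocv"`) or stratified 10-fold
#' (`"kfold10"`) cross-validation. Reported accuracy is the mean over folds
#' of the fold validation accuracy, in percent. Standardization is fit on
#' each training fold only.
#'
#' @param x Samples x features matrix.
#' @param labels Class labels (>= 2 classes).
#' @param cv `"kfold10"` or `"loocv"`.
#' @param seed Integer seed (fold assignment and solver order).
#' @param C Soft-margin cost.
#' @param feature_name Name recorded in the result.
#' @return An `evaluation_result` (single run; `accuracies` has length 1).
#' @export
evaluate_svm <- function(x, labels, cv = c("kfold10", "loocv"), seed = 1,
                         C = 1, feature_name = "features") {
  cv <- match.arg(cv)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop_input("need >= 2 classes")
  n <- nrow(x)
  folds <- if (cv == "loocv") as.list(seq_len(n)) else
    stratified_folds(labels, 10, seed)
  t0 <- proc.time()[["elapsed"]]
  acc <- vapply(seq_along(folds), function(fi) {
    test <- folds[[fi]]
    train <- setdiff(seq_len(n), test)
    sc <- fit_scaler(x[train, , drop = FALSE])
    fit <- svm_fit(apply_scaler(x[train, , drop = FALSE], sc),
                   labels[train], C = C, seed = seed + fi)
    pred <- predict(fit, apply_scaler(x[test, , drop = FALSE], sc))
    100 * mean(pred == labels[test])
  }, numeric(1))
  elapsed <- proc.time()[["elapsed"]] - t0
  res <- new_evaluation_result(feature_name,
                               if (cv == "loocv") "svm_loocv" else "svm_10cv",
                               mean(acc), elapsed,
                               n_train = n - length(folds[[1]]),
                               n_validation = length(folds[[1]]))
  res$fold_accuracies <- acc
  res
}

stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    assignment <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      assignment[idx] <- sample(rep_len(sample.int(k), length(idx)))
    }
    folds <- lapply(seq_len(k), function(f) which(assignment == f))
    folds[lengths(folds) > 0]   # k > n per stratum can leave empty folds
  })
}

#' MLP validation accuracy on a stratified split
#'
#' Single stratified train/validation split (fraction 1622/2312 of the
#' data, the protocol's ratio), per-split standardization, MLP per
#' [mlp_fit()] defaults. Non-convergence within `max_iter` is flagged in
#' the result, not raised.
#'
#' @param x,labels Data.
#' @param seed Integer seed.
#' @param train_fraction Training fraction, default `1622/2312`.
#' @param feature_name Name recorded in the result.
#' @param ... Passed to [mlp_fit()].
#' @return An `evaluation_result`.
#' @export
evaluate_mlp <- function(x, labels, seed = 1, train_fraction = 1622 / 2312,
                         feature_name = "features", ...) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop_input("need >= 2 classes")
  sp <- train_validation_split(labels, round(nrow(x) * train_fraction), seed)
  sc <- fit_scaler(x[sp$train, , drop = FALSE])
  t0 <- proc.time()[["elapsed"]]
  fit <- mlp_fit(apply_scaler(x[sp$train, , drop = FALSE], sc),
                 labels[sp$train], seed = seed, ...)
  pred <- predict(fit, apply_scaler(x[sp$validation, , drop = FALSE], sc))
  elapsed <- proc.time()[["elapsed"]] - t0
  new_evaluation_result(feature_name, "mlp",
                        100 * mean(pred == labels[sp$validation]), elapsed,
                        n_train = length(sp$train),
                        n_validation = length(sp$validation),
                        flags = if (!fit$converged) "did_not_converge"
                                else character(0))
}

#' CNN-LSTM validation accuracy on a stratified split
#'
#' Same split protocol as [evaluate_mlp()]; the network is the fixed stack
#' of [cnn_lstm_config()].
#'
#' @param x,labels Data.
#' @param config A [cnn_lstm_config()]; its `input_length` must match
#'   `ncol(x)`.
#' @param seed Integer seed.
#' @param train_fraction Training fraction.
#' @param feature_name Name recorded in the result.
#' @return An `evaluation_result`.
#' @export
evaluate_cnn_lstm <- function(x, labels, config = cnn_lstm_config(ncol(x)),
                              seed = 1, train_fraction = 1622 / 2312,
                              feature_name = "features") {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop_input("need >= 2 classes")
  sp <- train_validation_split(labels, round(nrow(x) * train_fraction), seed)
  sc <- fit_scaler(x[sp$train, , drop = FALSE])
  t0 <- proc.time()[["elapsed"]]
  fit <- cnn_lstm_fit(apply_scaler(x[sp$train, , drop = FALSE], sc),
                      labels[sp$train], config = config, seed = seed)
  pred <- predict(fit, apply_scaler(x[sp$validation, , drop = FALSE], sc))
  elapsed <- proc.time()[["elapsed"]] - t0
  new_evaluation_result(feature_name, "cnn_lstm",
                        100 * mean(pred == labels[sp$validation]), elapsed,
                        n_train = length(sp$train),
                        n_validation = length(sp$validation))
}

#' Repeat-averaged evaluation of several classifiers
#'
#' Runs each requested classifier `n_repeats` times with fresh seed-derived
#' splits and aggregates mean/sd accuracy and timing; the per-repeat table
#' is retained for the downstream ANOVA.
#'
#' @param x,labels Data.
#' @param feature_name Name recorded in the results.
#' @param classifiers Subset of
#'   `c("svm_loocv", "svm_10cv", "mlp", "cnn_lstm")`.
#' @param n_repeats Repeats per classifier, default 10.
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param cnn_config Optional [cnn_lstm_config()].
#' @return List of `evaluation_result`, one per classifier, each holding
#'   `n_repeats` per-repeat accuracies (sd reported as 0 with a flag when
#'   `n_repeats = 1`).
#' @export
repeated_evaluation <- function(x, labels, feature_name = "features",
                                classifiers = c("svm_10cv", "mlp"),
                                n_repeats = 10, seed = 1,
                                cnn_config = NULL) {
  known <- c("svm_loocv", "svm_10cv", "mlp", "cnn_lstm")
  bad <- setdiff(classifiers, known)
  if (length(bad)) stop_input("unknown classifier(s): ",
                              paste(bad, collapse = ", "))
  if (n_repeats < 1) stop_input("`n_repeats` must be >= 1")
  out <- lapply(classifiers, function(cl) {
    accs <- numeric(n_repeats)
    times <- numeric(n_repeats)
    flags <- character(0)
    nt <- nv <- NA_integer_
    for (r in seq_len(n_repeats)) {
      rs <- seed + r
      res <- switch(cl,
        svm_loocv = evaluate_svm(x, labels, "loocv", seed = rs,
                                 feature_name = feature_name),
        svm_10cv = evaluate_svm(x, labels, "kfold10", seed = rs,
                                feature_name = feature_name),
        mlp = evaluate_mlp(x, labels, seed = rs, feature_name = feature_name),
        cnn_lstm = evaluate_cnn_lstm(
          x, labels,
          config = if (is.null(cnn_config)) cnn_lstm_config(ncol(x))
                   else cnn_config,
          seed = rs, feature_name = feature_name)
      )
      accs[r] <- res$mean_accuracy
      times[r] <- res$mean_time
      flags <- union(flags, res$flags)
      nt <- res$n_train; nv <- res$n_validation
    }
    if (n_repeats == 1) flags <- union(flags, "single_repeat_sd_zero")
    new_evaluation_result(feature_name, cl, accs, times, nt, nv, flags)
  })
  names(out) <- classifiers
  out
}

#' Tabulate evaluation results
#'
#' Collapses a list of `evaluation_result` objects into the
#' feature x classifier accuracy/time table.
#'
#' @param results List (possibly nested) of `evaluation_result`.
#' @return Data.frame with columns feature, classifier, mean_accuracy,
#'   sd_accuracy, mean_time_s, n_repeats, n_train, n_validation.
#' @export
results_table <- function(results) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "evaluation_result")) flat[[length(flat) + 1]] <<- x
    else if (is.list(x)) lapply(x, collect)
    invisible(NULL)
  }
  collect(results)
  do.call(rbind, lapply(flat, function(r) {
    data.frame(feature = r$feature_name, classifier = r$classifier,
               mean_accuracy = r$mean_accuracy, sd_accuracy = r$sd_accuracy,
               mean_time_s = r$mean_time, n_repeats = length(r$accuracies),
               n_train = r$n_train, n_validation = r$n_validation,
               stringsAsFactors = FALSE)
  }))
}
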