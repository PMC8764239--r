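# Group-level statistics: per-channel-pair difference maps between groups,
# classifier-comparison ANOVA / Kruskal-Wallis, and channel clustering by
# multidimensional scaling of the connectivity matrix.

#' Per-channel-pair group difference map
#'
#' For every connectivity-matrix entry, a two-sided Welch two-sample t-test
#' of the per-epoch values between two groups. Entries with `p < alpha`
#' form the significance mask. No multiple-comparison correction is applied
#' by default (per-cell alpha, as in the protocol this mirrors); set
#' `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param mats_a,mats_b Lists (or n x n x m arrays) of per-epoch
#'   connectivity matrices for the two groups, >= 2 epochs each.
#' @param alpha Significance level, default 0.05.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return A `difference_map`: list with `p_values` (n x n), `mask`
#'   (boolean n x n), `alpha`, `degenerate` (entries with zero variance in
#'   both groups, reported as p = 1 with a warning).
#' @export
difference_map <- function(mats_a, mats_b, alpha = 0.05, p_adjust = "none") {
  a <- as_mat_array(mats_a)
  b <- as_mat_array(mats_b)
  if (!all(dim(a)[1:2] == dim(b)[1:2])) stop_input("matrix shapes differ")
  if (dim(a)[3] < 2 || dim(b)[3] < 2) stop_input("need >= 2 epochs per group")
  n <- dim(a)[1]
  ma <- apply(a, c(1, 2), mean); va <- apply(a, c(1, 2), stats::var)
  mb <- apply(b, c(1, 2), mean); vb <- apply(b, c(1, 2), stats::var)
  na <- dim(a)[3]; nb <- dim(b)[3]
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- va == 0 & vb == 0
  if (any(degenerate)) {
    p[degenerate] <- 1
    deg_off <- degenerate; diag(deg_off) <- FALSE
    if (any(deg_off)) {
      warning(sum(deg_off), " constant off-diagonal entr",
              if (sum(deg_off) == 1) "y" else "ies",
              " (p set to 1)")
    }
  }
  if (p_adjust != "none") {
    adj <- p
    ut <- upper.tri(p, diag = FALSE)
    adj[ut] <- stats::p.adjust(p[ut], method = p_adjust)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    p <- adj
  }
  dimnames(p) <- dimnames(a)[1:2]
  structure(list(p_values = p, mask = p < alpha, alpha = alpha,
                 degenerate = degenerate),
            class = "difference_map")
}

as_mat_array <- function(mats) {
  if (is.array(mats) && length(dim(mats)) == 3) return(mats)
  if (!is.list(mats) || !length(mats)) stop_input("need a list of matrices")
  n <- nrow(mats[[1]])
  arr <- array(NA_real_, c(n, n, length(mats)),
               dimnames = c(dimnames(mats[[1]])[1:2], list(NULL)))
  for (i in seq_along(mats)) arr[, , i] <- unclass(mats[[i]])
  arr
}

#' Intersection of difference masks
#'
#' Element-wise AND across difference maps: the entries that differ from
#' the reference group in every comparison (the "common difference" area).
#'
#' @param maps List of `difference_map` objects (or boolean matrices) of
#'   identical shape.
#' @return Boolean matrix.
#' @export
common_difference_mask <- function(maps) {
  masks <- lapply(maps, function(m) {
    if (inherits(m, "difference_map")) m$mask else m
  })
  d1 <- dim(masks[[1]])
  out <- masks[[1]]
  for (m in masks[-1]) {
    if (!all(dim(m) == d1)) stop_input("mask shapes differ")
    out <- out & m
  }
  out
}

#' Classical MDS embedding of a connectivity matrix
#'
#' Converts connectivity to dissimilarity
#' `d = 1 - (value - min) / (max - min)` (computed over off-diagonal
#' entries; high connectivity maps to low distance, the diagonal to 0),
#' then embeds channels by classical multidimensional scaling.
#' Directed matrices are symmetrized by averaging the two directions first.
#'
#' @param m Connectivity matrix (mean over epochs of a group, typically).
#' @param dims Embedding dimension, default 2.
#' @return An `mds_embedding`: list with `points` (channels x dims),
#'   `stress` (normalized residual of embedded vs target distances),
#'   `dissimilarity`, `channel_labels`.
#' @export
mds_embed <- function(m, dims = 2) {
  v <- unclass(m)
  if (!all(is.finite(v))) stop_input("non-finite entries in matrix")
  if (isTRUE(attr(m, "directed")) || max(abs(v - t(v))) > 1e-12) {
    v <- (v + t(v)) / 2
  }
  labels <- attr(m, "channel_labels")
  if (is.null(labels)) labels <- rownames(v)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(v)))
  off <- v[row(v) != col(v)]
  rng <- range(off)
  d <- if (rng[2] > rng[1]) 1 - (v - rng[1]) / (rng[2] - rng[1])
       else matrix(1, nrow(v), ncol(v))
  diag(d) <- 0
  pts <- stats::cmdscale(stats::as.dist(d), k = dims)
  if (ncol(pts) < dims) {      # degenerate geometry: pad zero coordinates
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  }
  emb_d <- as.matrix(stats::dist(pts))
  stress <- sqrt(sum((emb_d - d)^2) / max(sum(d^2), .Machine$double.eps))
  rownames(pts) <- labels
  structure(list(points = pts, stress = stress, dissimilarity = d,
                 channel_labels = labels),
            class = "mds_embedding")
}

#' Cluster channels in an MDS embedding
#'
#' Single-linkage agglomeration on the Euclidean distances between embedded
#' channels, cut at `threshold_fraction` of the maximum pairwise distance.
#' Channels left in singleton clusters are reported as unclustered
#' (`NA`); surviving cluster ids are renumbered contiguously in order of
#' first channel appearance. With all distances equal (tie case) the cut
#' at `threshold_fraction < 1` merges nothing, so every channel is
#' unclustered -- deterministic by construction.
#'
#' @param embedding An `mds_embedding` (or a channels x dims coordinate
#'   matrix).
#' @param threshold_fraction Cut height as a fraction of the maximum
#'   pairwise distance, in (0, 1).
#' @return A `cluster_assignment`: list with `cluster` (named integer,
#'   `NA` = unclustered), `n_clusters`, `threshold`.
#' @export
cluster_channels <- function(embedding, threshold_fraction = 0.5) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points
         else as.matrix(embedding)
  if (nrow(pts) < 2) stop_input("need >= 2 channels to cluster")
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop_input("`threshold_fraction` must be in (0, 1)")
  }
  d <- stats::dist(pts)
  h <- max(d) * threshold_fraction
  tree <- stats::hclust(d, method = "single")
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= 2]
  cl <- ifelse(as.character(raw) %in% keep, raw, NA_integer_)
  # renumber contiguously by first appearance
  ids <- unique(stats::na.omit(cl))
  cl <- match(cl, ids)
  names(cl) <- rownames(pts)
  structure(list(cluster = cl, n_clusters = length(ids), threshold = h),
            class = "cluster_assignment")
}

#' One-way ANOVA over per-repeat classifier accuracies
#'
#' Closed-form one-way fixed-effects F test across groups. Degenerate
#' inputs are flagged rather than raised: zero between- and within-group
#' variance gives `F = 0, p = 1`; separated means with zero within-group
#' variance give `F = Inf, p = 0`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each), e.g. per-classifier accuracy vectors.
#' @return List with `F`, `p`, `df` and `flag` (`""` when regular).
#' @export
anova_models <- function(groups) {
  if (length(groups) < 2) stop_input("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) {
    stop_input("every group needs >= 2 values")
  }
  k <- length(groups)
  ns <- vapply(groups, length, 0L)
  n <- sum(ns)
  means <- vapply(groups, mean, 0)
  grand <- sum(ns * means) / n
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- n - k
  if (ssw == 0 && ssb == 0) {
    return(list(F = 0, p = 1, df = c(df1, df2), flag = "no_variance"))
  }
  if (ssw == 0) {
    return(list(F = Inf, p = 0, df = c(df1, df2),
                flag = "zero_within_group_variance"))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), flag = "")
}

#' Kruskal-Wallis test over per-repeat computing times
#'
#' Rank-based analogue of [anova_models()] for wall-time comparisons
#' (wraps [stats::kruskal.test()]). Identical constant groups are flagged
#' with `H = 0, p = 1`.
#'
#' @param groups Named list of numeric vectors.
#' @return List with `H`, `p`, `df`, `flag`.
#' @export
kruskal_times <- function(groups) {
  if (length(groups) < 2) stop_input("need >= 2 groups")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1, flag = "no_variance"))
  }
  g <- factor(rep(names_or_index(groups), vapply(groups, length, 0L)))
  kt <- stats::kruskal.test(vals, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), flag = "")
}

names_or_index <- function(x) {
  nm <- names(x)
  if (is.null(nm) || any(nm == "")) as.character(seq_along(x)) else nm
}

#' Low- vs high-frequency tinnitus comparison
#'
#' Runs the classification protocol separately on the `{low-frequency
#' subgroup vs reference}` and `{high-frequency subgroup vs reference}`
#' subsets of a labeled feature set, for every requested classifier, then
#' tests the per-repeat accuracy difference with [anova_models()].
#'
#' @param x Samples x features matrix.
#' @param labels Label per sample; must contain `lft_label`, `hft_label`
#'   and `reference`.
#' @param lft_label,hft_label,reference The sub-group and reference labels.
#' @param classifiers Classifier kinds as in [repeated_evaluation()].
#' @param n_repeats,seed Evaluation protocol parameters.
#' @param feature_name Recorded in the results.
#' @return Data.frame with one row per classifier: mean accuracy on each
#'   subset, their difference, and the ANOVA p-value over per-repeat
#'   accuracies.
#' @export
lft_hft_comparison <- function(x, labels, lft_label = "left_lft",
                               hft_label = "left_hft",
                               reference = "healthy",
                               classifiers = c("svm_10cv", "mlp"),
                               n_repeats = 10, seed = 1,
                               feature_name = "features") {
  labels <- as.character(labels)
  for (lb in c(lft_label, hft_label, reference)) {
    if (!lb %in% labels) stop_input("label \"", lb, "\" absent from data")
  }
  run <- function(sub_label) {
    sel <- labels %in% c(sub_label, reference)
    repeated_evaluation(x[sel, , drop = FALSE], labels[sel],
                        feature_name = feature_name,
                        classifiers = classifiers,
                        n_repeats = n_repeats, seed = seed)
  }
  res_l <- run(lft_label)
  res_h <- run(hft_label)
  do.call(rbind, lapply(classifiers, function(cl) {
    a <- res_l[[cl]]$accuracies
    b <- res_h[[cl]]$accuracies
    p <- anova_models(list(lft = a, hft = b))$p
    data.frame(feature = feature_name, classifier = cl,
               lft_accuracy = mean(a), hft_accuracy = mean(b),
               difference = mean(b) - mean(a), p_value = p,
               stringsAsFactors = FALSE)
  }))
}
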