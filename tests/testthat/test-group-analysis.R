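# Group statistics: difference maps, mask intersection, MDS clustering,
# ANOVA / Kruskal-Wallis, LFT/HFT comparison.

rand_sym_mats <- function(m, n = 6, shift = NULL, pair = NULL, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(m), function(i) {
      s <- matrix(rnorm(n * n), n)
      s <- (s + t(s)) / 2
      diag(s) <- 1
      if (!is.null(shift)) {
        s[pair[1], pair[2]] <- s[pair[1], pair[2]] + shift
        s[pair[2], pair[1]] <- s[pair[1], pair[2]]
      }
      s
    })
  })
}

test_that("difference_map flags a strongly shifted pair and only it often", {
  a <- rand_sym_mats(50, seed = 60)
  b <- rand_sym_mats(50, shift = 5, pair = c(2, 5), seed = 61)
  dm <- difference_map(a, b)
  expect_true(dm$mask[2, 5])
  expect_true(dm$mask[5, 2])
  expect_equal(dim(dm$p_values), c(6, 6))
  expect_lt(dm$p_values[2, 5], 1e-6)
  expect_error(difference_map(a[1], b), class = "tinnconn_input_error")
})

test_that("identical groups flag about alpha of entries", {
  a <- rand_sym_mats(40, seed = 62)
  b <- rand_sym_mats(40, seed = 63)
  dm <- difference_map(a, b, alpha = 0.05)
  off <- dm$mask[upper.tri(dm$mask)]
  expect_lt(mean(off), 0.05 + 3 * sqrt(0.05 * 0.95 / length(off)))
})

test_that("degenerate constant entries give p = 1 with a warning", {
  a <- rand_sym_mats(10, seed = 64)
  b <- rand_sym_mats(10, seed = 65)
  for (i in seq_along(a)) { a[[i]][1, 2] <- a[[i]][2, 1] <- 0.5
                            b[[i]][1, 2] <- b[[i]][2, 1] <- 0.5 }
  expect_warning(dm <- difference_map(a, b), "constant")
  expect_equal(dm$p_values[1, 2], 1)
  expect_false(dm$mask[1, 2])
})

test_that("common mask is the element-wise AND and catches the shared pair", {
  a <- rand_sym_mats(50, seed = 66)
  groups <- lapply(1:3, function(g) {
    rand_sym_mats(50, shift = 5, pair = c(1, 4), seed = 70 + g)
  })
  maps <- lapply(groups, function(g) difference_map(a, g))
  cm <- common_difference_mask(maps)
  expect_true(cm[1, 4] && cm[4, 1])
  # oracle: brute-force AND over random masks
  withr::with_seed(67, {
    m1 <- matrix(runif(36) < 0.5, 6)
    m2 <- matrix(runif(36) < 0.5, 6)
    m3 <- matrix(runif(36) < 0.5, 6)
  })
  expect_identical(common_difference_mask(list(m1, m2, m3)), m1 & m2 & m3)
  allt <- matrix(TRUE, 6, 6)
  expect_true(all(common_difference_mask(list(allt, allt, allt))))
  expect_false(any(common_difference_mask(list(allt, !allt, allt))))
  expect_error(common_difference_mask(list(m1, matrix(TRUE, 5, 5))),
               class = "tinnconn_input_error")
})

block_matrix <- function(within = 1, between = 0) {
  m <- matrix(between, 12, 12,
              dimnames = list(auditory_channels(), auditory_channels()))
  m[1:6, 1:6] <- within
  m[7:12, 7:12] <- within
  diag(m) <- 1
  m
}

test_that("MDS embedding separates a two-block connectivity structure", {
  emb <- mds_embed(block_matrix())
  expect_equal(dim(emb$points), c(12, 2))
  d <- as.matrix(dist(emb$points))
  within <- c(d[1:6, 1:6][upper.tri(diag(6))],
              d[7:12, 7:12][upper.tri(diag(6))])
  between <- d[1:6, 7:12]
  expect_gt(min(between), 5 * max(max(within), 1e-12))
  # all-equal connectivity: equidistant channels need n - 1 dimensions;
  # there the embedded distances are all equal
  flat <- matrix(0.5, 12, 12)
  diag(flat) <- 1
  ef <- mds_embed(flat, dims = 11)
  df <- as.matrix(dist(ef$points))
  off <- df[row(df) != col(df)]
  expect_lt(max(off) - min(off), 1e-6)
  bad <- block_matrix()
  bad[1, 2] <- NA
  expect_error(mds_embed(bad), class = "tinnconn_input_error")
})

test_that("cluster_channels recovers the two blocks exactly", {
  emb <- mds_embed(block_matrix())
  cl <- cluster_channels(emb, 0.5)
  expect_equal(cl$n_clusters, 2)
  expect_length(unique(cl$cluster[1:6]), 1)
  expect_length(unique(cl$cluster[7:12]), 1)
  expect_false(cl$cluster[1] == cl$cluster[7])
  expect_error(cluster_channels(emb, 1.5), class = "tinnconn_input_error")
  expect_error(cluster_channels(emb$points[1, , drop = FALSE], 0.5),
               class = "tinnconn_input_error")
})

test_that("cluster ids are invariant to channel relabeling", {
  withr::with_seed(68, {
    pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
                 matrix(rnorm(10, 5, 0.1), 5, 2))
    rownames(pts) <- paste0("c", 1:10)
  })
  cl <- cluster_channels(pts, 0.5)$cluster
  perm <- c(7, 2, 9, 4, 1, 10, 3, 8, 5, 6)
  cl_p <- cluster_channels(pts[perm, ], 0.5)$cluster
  # same partition: co-membership preserved under the permutation
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(cl[perm[i]] == cl[perm[j]], cl_p[i] == cl_p[j])
  }
  # all-equal distances at threshold 0.5: nothing merges, all unclustered
  sq <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2)  # not equidistant; use 2 pts
  eq <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_true(all(is.na(cluster_channels(eq, 0.5)$cluster)))
})

test_that("MCS recovers template-driven channel-cluster patterns", {
  # right-sided template couples two left-hemisphere groups; the clustered
  # channels should lie mostly in the left hemisphere (channels 1-6)
  tpl <- build_class_templates("default")$right
  cfg <- sim_config(250, 100, epoch_s = 10, seed = 13)
  rec <- simulate_recording(tpl, cfg, seed = 13)
  mats <- lapply(segment_epochs(rec, 10), connectivity_matrix,
                 measure = "plv")
  mean_plv <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  cl <- cluster_channels(mds_embed(mean_plv), 0.35)$cluster
  # the two coupled groups ({FT7 FC5 C5} and {T7 TP7 TP8}) each land in
  # one cluster, distinct from each other: mostly-left-hemisphere SCAs
  expect_length(unique(cl[c("FT7", "FC5", "C5")]), 1)
  expect_length(unique(cl[c("T7", "TP7", "TP8")]), 1)
  expect_false(cl[["FT7"]] == cl[["T7"]])
  members <- c("FT7", "FC5", "C5", "T7", "TP7", "TP8")
  expect_gt(mean(members %in% auditory_channels()[1:6]), 0.5)
  # healthy template: homologous interhemispheric pairs co-cluster
  tplh <- build_class_templates("default")$healthy
  rech <- simulate_recording(tplh, cfg, seed = 14)
  matsh <- lapply(segment_epochs(rech, 10), connectivity_matrix,
                  measure = "plv")
  mean_h <- Reduce(`+`, lapply(matsh, unclass)) / length(matsh)
  clh <- cluster_channels(mds_embed(mean_h), 0.35)$cluster
  expect_equal(clh[["FT7"]], clh[["FT8"]])
  expect_equal(clh[["T7"]], clh[["T8"]])
  expect_equal(clh[["CP5"]], clh[["CP6"]])
})

test_that("one-way ANOVA matches the hand-computed oracle", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5 (df 1), SSW = 4 (df 4) -> F = 1.5
  res <- anova_models(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  same <- anova_models(list(a = c(9, 9), b = c(9, 9), c = c(9, 9)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_identical(same$flag, "no_variance")
  sep <- anova_models(list(a = rep(90, 10), b = rep(99, 10)))
  expect_identical(sep$flag, "zero_within_group_variance")
  expect_lt(sep$p, 0.005)
  withr::with_seed(69, {
    noisy <- anova_models(list(a = rnorm(10, 90, 0.5),
                               b = rnorm(10, 99, 0.5)))
  })
  expect_lt(noisy$p, 1e-6)
  expect_error(anova_models(list(a = 1:3)), class = "tinnconn_input_error")
  expect_error(anova_models(list(a = 1, b = 2)),
               class = "tinnconn_input_error")
})

test_that("Kruskal-Wallis on times: identical, separated, rank-sum check", {
  same <- kruskal_times(list(a = rep(5, 10), b = rep(5, 10)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  sep <- kruskal_times(list(a = 1:10, b = 11:20, c = 21:30, d = 31:40))
  expect_lt(sep$p, 0.001)
  # two groups: equivalent to the Wilcoxon rank-sum test (chi-square link)
  withr::with_seed(70, {
    a <- rnorm(12)
    b <- rnorm(12, 1)
  })
  kw <- kruskal_times(list(a = a, b = b))
  wx <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(kw$p, wx$p.value, tolerance = 1e-9)
})

test_that("LFT/HFT comparison runs per subset and reports p-values", {
  # three labels, sub-groups differ in separability from the reference
  withr::with_seed(71, {
    n <- 30
    x_ref <- matrix(rnorm(n * 8), n, 8)
    x_lft <- matrix(rnorm(n * 8, 1.0), n, 8)
    x_hft <- matrix(rnorm(n * 8, 3.0), n, 8)
  })
  x <- rbind(x_ref, x_lft, x_hft)
  labels <- rep(c("healthy", "left_lft", "left_hft"), each = n)
  res <- lft_hft_comparison(x, labels, classifiers = "svm_10cv",
                            n_repeats = 3, seed = 2)
  expect_equal(nrow(res), 1)
  expect_true(all(c("lft_accuracy", "hft_accuracy", "p_value") %in%
                    names(res)))
  # the stronger-shifted subgroup classifies at least as well
  expect_gte(res$hft_accuracy, res$lft_accuracy)
  expect_error(lft_hft_comparison(x, rep("healthy", nrow(x))),
               class = "tinnconn_input_error")
})
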