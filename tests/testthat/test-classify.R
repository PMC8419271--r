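test_that("edge vectorization walks the upper triangle row by row", {
  R <- as_adj(matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3))
  expect_equal(vectorize_edges(R), c(.2, .3, .4))

  set.seed(31)
  V <- random_correlation(116)
  expect_length(vectorize_edges(V), 116 * 115 / 2)

  # round trip through the inverse mapping restores the off-diagonals
  v <- vectorize_edges(V)
  W <- diag(116)
  idx <- 0
  for (i in 1:115) {
    for (j in (i + 1):116) {
      idx <- idx + 1
      W[i, j] <- W[j, i] <- v[idx]
    }
  }
  expect_equal(W, V, tolerance = 0, ignore_attr = TRUE)
})

test_that("t-test edge selection matches the from-scratch statistic", {
  set.seed(32)
  labels <- rep(c("positive", "negative"), each = 20)
  F <- matrix(rnorm(40 * 100), 40, 100)
  planted <- c(3, 17, 42, 68, 99)
  F[labels == "positive", planted] <- F[labels == "positive", planted] + 1.5

  sel <- ttest_select(F, labels, p_threshold = 0.001,
                      positive_class = "positive")
  oracle_p <- apply(F, 2, function(col) {
    stats::t.test(col[labels == "positive"], col[labels == "negative"],
                  var.equal = TRUE)$p.value
  })
  expect_equal(sort(as.integer(sel)), which(oracle_p < 0.001))
  expect_equal(attr(sel, "p_values"), oracle_p, tolerance = 1e-12)

  # Welch variant against t.test's default
  selw <- ttest_select(F, labels, p_threshold = 0.001,
                       positive_class = "positive", var_equal = FALSE)
  oracle_w <- apply(F, 2, function(col) {
    stats::t.test(col[labels == "positive"], col[labels == "negative"])$p.value
  })
  expect_equal(attr(selw, "p_values"), oracle_w, tolerance = 1e-12)

  # null case: identical groups select (near) nothing
  F0 <- matrix(rnorm(40 * 200), 40, 200)
  sel0 <- ttest_select(F0, labels, p_threshold = 0.001)
  expect_lte(length(sel0), 2)

  # overwhelming single effect is always found
  F1 <- matrix(rnorm(100 * 10), 100, 10)
  lab1 <- rep(c("positive", "negative"), each = 50)
  F1[lab1 == "positive", 7] <- F1[lab1 == "positive", 7] + 10
  expect_true(7 %in% ttest_select(F1, lab1, 0.001, positive_class = "positive"))

  expect_error(ttest_select(F, rep("positive", 40), 0.001), "two classes")
})

test_that("fold splitting is subject-coherent, balanced and deterministic", {
  # 143 subjects over 5 folds -> sizes {29, 29, 29, 28, 28}
  scans <- lapply(1:143, function(i) {
    list(networks = list(), scan_id = paste0("sc", i),
         subject_id = sprintf("sub%03d", i),
         label = if (i <= 71) "positive" else "negative")
  })
  ds <- labeled_dataset(scans, positive_class = "positive")
  f <- subject_level_folds(ds, k = 5, seed = 7)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(29, 29, 29, 28, 28))

  # multiple scans of a subject always share a fold
  sp <- synthetic_spec(N_rois = 8, M_timepoints = 30,
                       n_subjects_per_group = 6, scans_per_subject = 3,
                       block_sizes = 8, n_differing_edges = 0,
                       preset = "none", seed = 33)
  ds2 <- simulate_dataset(sp, orders = "1")
  f2 <- subject_level_folds(ds2, k = 3, seed = 1)
  subjects <- vapply(ds2$scans, function(s) s$subject_id, character(1))
  per_scan <- f2[subjects]
  for (s in unique(subjects)) {
    expect_length(unique(per_scan[subjects == s]), 1)
  }

  # determinism and seed sensitivity
  expect_identical(subject_level_folds(ds, 5, seed = 7),
                   subject_level_folds(ds, 5, seed = 7))
  expect_false(identical(subject_level_folds(ds, 5, seed = 7),
                         subject_level_folds(ds, 5, seed = 8)))
  expect_error(subject_level_folds(ds2, k = 20, seed = 1), "fewer subjects")
})

test_that("the calibrated linear classifier behaves sensibly", {
  set.seed(34)
  n <- 30
  F <- rbind(cbind(rnorm(n, 2), rnorm(n, 2)),
             cbind(rnorm(n, -2), rnorm(n, -2)))
  labels <- rep(c("positive", "negative"), each = n)
  clf <- train_probabilistic_classifier(F, labels, "positive", C = 1)
  p <- predict(clf, F)
  expect_equal(mean((p >= 0.5) == (labels == "positive")), 1)

  # flipping the labels reflects the probabilities about 0.5
  flipped <- ifelse(labels == "positive", "negative", "positive")
  clf2 <- train_probabilistic_classifier(F, flipped, "positive", C = 1)
  p2 <- predict(clf2, F)
  expect_equal(p2, 1 - p, tolerance = 0.02)

  # determinism: refitting on identical data reproduces the probabilities
  clf3 <- train_probabilistic_classifier(F, labels, "positive", C = 1)
  expect_identical(predict(clf3, F), p)

  # empty feature set falls back to the training prior, with a warning
  expect_warning(
    clf0 <- train_probabilistic_classifier(F[, integer(0), drop = FALSE],
                                           labels, "positive"),
    "majority-class"
  )
  expect_equal(predict(clf0, F[, integer(0), drop = FALSE]), rep(0.5, 2 * n))
})

test_that("metrics follow the confusion-count definitions", {
  # TP=3, TN=2, FP=1, FN=2 -> ACC .625, SEN .6, SPE 2/3
  labels <- c(rep("positive", 5), rep("negative", 3))
  probs <- c(.9, .8, .7, .2, .1, .6, .3, .2)
  m <- evaluate_metrics(probs, labels, "positive")
  expect_equal(list(m$TP, m$TN, m$FP, m$FN), list(3L, 2L, 1L, 2L))
  expect_equal(m$ACC, 0.625)
  expect_equal(m$SEN, 0.6)
  expect_equal(m$SPE, 2 / 3)
  expect_equal(m$ACC, (m$TP + m$TN) / (m$TP + m$TN + m$FP + m$FN))

  # perfect predictions
  mp <- evaluate_metrics(c(1, 1, 0, 0), c("positive", "positive",
                                          "negative", "negative"), "positive")
  expect_equal(c(mp$ACC, mp$SEN, mp$SPE), c(1, 1, 1))

  # everything predicted positive
  ma <- evaluate_metrics(rep(1, 4), c("positive", "positive", "negative",
                                      "negative"), "positive")
  expect_equal(c(ma$SEN, ma$SPE), c(1, 0))

  # zero-denominator metrics are NaN and flagged
  mz <- evaluate_metrics(c(.9, .1), c("negative", "negative"), "positive")
  expect_true(is.nan(mz$SEN))
  expect_equal(mz$undefined, "SEN")
})

test_that("probability fusion is the stated convex combination", {
  O1 <- c(0.8, 0.2, 0.5)
  O2 <- c(0.4, 0.6, 0.5)
  expect_identical(fuse_probabilities(O1, O2, 1), O1)
  expect_equal(fuse_probabilities(O1, O2, 0.5), c(0.6, 0.4, 0.5))
  expect_equal(fuse_probabilities(O1, O1, 0.37), O1)
  expect_error(fuse_probabilities(O1, O2[1:2], 0.5), "align")
  expect_error(fuse_probabilities(O1, O2, 1.2), "lam")
})

test_that("lambda selection favors the informative channel", {
  set.seed(35)
  picks <- vapply(1:10, function(i) {
    n <- 40
    labels <- rep(c("positive", "negative"), each = n / 2)
    subjects <- sprintf("s%02d", seq_len(n))
    informative <- matrix(rnorm(n * 20), n, 20)
    informative[labels == "positive", 1:5] <-
      informative[labels == "positive", 1:5] + 2
    noise <- matrix(rnorm(n * 20), n, 20)
    as.numeric(select_lambda(informative, noise, labels, subjects,
                             "positive", p_threshold = 0.05,
                             inner_k = 5, seed = 3500 + i))
  }, numeric(1))
  expect_gte(mean(picks >= 0.5), 0.7)

  # identical channels tie every lambda; the tie-break returns 0.5
  n <- 20
  labels <- rep(c("positive", "negative"), each = n / 2)
  subjects <- sprintf("s%02d", seq_len(n))
  F <- matrix(rnorm(n * 10), n, 10)
  F[labels == "positive", 1:3] <- F[labels == "positive", 1:3] + 3
  lam <- select_lambda(F, F, labels, subjects, "positive",
                       p_threshold = 0.05, inner_k = 4, seed = 1)
  expect_equal(as.numeric(lam), 0.5)

  # a one-element grid short-circuits
  expect_equal(as.numeric(select_lambda(F, F, labels, subjects, "positive",
                                        grid = 0.3, seed = 1)), 0.3)
})

test_that("the cross-validated experiment is leakage-free and bookkeeps correctly", {
  sp <- small_study_spec(seed = 36, n_per_group = 12, N = 24, M = 60,
                         n_edges = 8)
  ds <- simulate_dataset(sp, orders = c("1", "conv"))
  res <- run_experiment(ds, orders = c("1", "conv"), p_grid = 0.05,
                        mode = "single", k = 4, seed = 9)

  for (entry in res) {
    m <- entry$metrics
    expect_equal(m$ACC, (m$TP + m$TN) / (m$TP + m$TN + m$FP + m$FN))
    expect_equal(m$TP + m$TN + m$FP + m$FN, length(ds$scans))
    folds_total <- Reduce(`+`, lapply(entry$per_fold, function(f)
      c(f$TP, f$TN, f$FP, f$FN)))
    expect_equal(folds_total, c(m$TP, m$TN, m$FP, m$FN))
    expect_length(entry$n_features_selected, 4)
  }

  # determinism under the master seed
  res2 <- run_experiment(ds, orders = c("1", "conv"), p_grid = 0.05,
                         mode = "single", k = 4, seed = 9)
  expect_equal(res[["order=1,p=0.05"]]$probabilities,
               res2[["order=1,p=0.05"]]$probabilities)

  # leakage canary: corrupting a TEST-fold scan (features and label) must
  # not change the training-fold feature selection of that fold
  folds <- subject_level_folds(ds, k = 4, seed = pcn:::derive_seeds(9, 5)[1])
  subjects <- vapply(ds$scans, function(s) s$subject_id, character(1))
  victim <- which(folds[subjects] == 1)[1]
  ds_bad <- ds
  bad_vals <- ds_bad$scans[[victim]]$networks[["1"]]$values
  bad_vals[upper.tri(bad_vals)] <- 0.999
  bad_vals[lower.tri(bad_vals)] <- 0.999
  ds_bad$scans[[victim]]$networks[["1"]] <- adjacency_matrix(bad_vals)
  ds_bad$scans[[victim]]$label <-
    if (ds$scans[[victim]]$label == "positive") "negative" else "positive"

  F_clean <- pcn:::edge_feature_matrix(ds, "1")
  F_bad <- pcn:::edge_feature_matrix(ds_bad, "1")
  train <- folds[subjects] != 1
  labels <- vapply(ds$scans, function(s) s$label, character(1))
  labels_bad <- vapply(ds_bad$scans, function(s) s$label, character(1))
  sel_clean <- ttest_select(F_clean[train, ], labels[train], 0.05,
                            positive_class = "positive")
  sel_bad <- ttest_select(F_bad[train, ], labels_bad[train], 0.05,
                          positive_class = "positive")
  expect_identical(as.integer(sel_clean), as.integer(sel_bad))

  # fusion mode returns lambdas from the grid and consistent bookkeeping
  resf <- run_experiment(ds, orders = c("1", "conv"), p_grid = 0.05,
                         mode = "fusion", k = 4, seed = 9, inner_k = 4)
  entry <- resf[["fusion=conv&1,p=0.05"]]
  expect_length(entry$lambda_selected, 4)
  expect_true(all(entry$lambda_selected %in% seq(0.1, 0.9, by = 0.1)))
  expect_equal(entry$metrics$TP + entry$metrics$TN + entry$metrics$FP +
                 entry$metrics$FN, length(ds$scans))
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(37)
  sp <- synthetic_spec(N_rois = 24, M_timepoints = 60,
                       n_subjects_per_group = 30, block_sizes = rep(8, 3),
                       n_differing_edges = 0, preset = "none", seed = 38)
  ds <- simulate_dataset(sp, orders = "1")
  labs0 <- vapply(ds$scans, function(s) s$label, character(1))
  # shuffle labels across scans (one scan per subject, so subject-coherent)
  # and average over replicates to tighten the chance band
  accs <- vapply(1:3, function(r) {
    labs <- labs0[sample(length(labs0))]
    for (i in seq_along(ds$scans)) ds$scans[[i]]$label <- labs[i]
    res <- run_experiment(ds, orders = "1", p_grid = 0.05, mode = "single",
                          k = 5, seed = 39 + r)
    res[["order=1,p=0.05"]]$metrics$ACC
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})
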