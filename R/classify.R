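#' Labeled dataset of network matrices
#'
#' Collection of scans, each carrying the network matrices computed at one
#' or more orders, a subject identifier and a binary class label. Subjects
#' may own several scans; fold splitting is always done at the subject
#' level so no subject straddles the train/test boundary.
#'
#' @param scans List of scans; each scan is a list with fields `networks`
#'   (named list of [adjacency_matrix()] objects, names are order tags such
#'   as `"1"`, `"2"`, `"conv"`), `scan_id`, `subject_id` and `label`.
#' @param positive_class Label value treated as the positive class for
#'   sensitivity/specificity.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(scans, positive_class) {
  stopifnot(is.list(scans), length(scans) >= 2L)
  labels <- vapply(scans, function(s) as.character(s$label), character(1))
  subjects <- vapply(scans, function(s) as.character(s$subject_id), character(1))
  if (any(!nzchar(subjects))) stop_validation("every scan needs a subject_id")
  if (length(unique(labels)) != 2L) {
    stop_validation("dataset must contain exactly two classes, got: ",
                    paste(unique(labels), collapse = ", "))
  }
  if (!positive_class %in% labels) {
    stop_validation("positive_class '", positive_class,
                    "' not present among labels")
  }
  structure(
    list(scans = scans, positive_class = as.character(positive_class)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  subjects <- vapply(x$scans, function(s) s$subject_id, character(1))
  labels <- vapply(x$scans, function(s) s$label, character(1))
  cat(sprintf("<labeled_dataset> %d scans / %d subjects; positive class '%s' (%d scans)\n",
              length(x$scans), length(unique(subjects)), x$positive_class,
              sum(labels == x$positive_class)))
  cat("  orders available:", paste(names(x$scans[[1]]$networks), collapse = ", "), "\n")
  invisible(x)
}

dataset_labels <- function(ds) {
  vapply(ds$scans, function(s) s$label, character(1))
}

dataset_subjects <- function(ds) {
  vapply(ds$scans, function(s) s$subject_id, character(1))
}

#' Flatten a network into an edge-weight feature vector
#'
#' Extracts the strict upper triangle in row-major order, i.e. edges
#' (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N); length N(N-1)/2. This
#' fixed ordering makes edge indices comparable across scans and orders.
#'
#' @param R An [adjacency_matrix()] (or plain symmetric matrix).
#' @return Numeric vector of edge weights.
#' @export
#' @examples
#' R <- adjacency_matrix(matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3))
#' vectorize_edges(R)  # c(.2, .3, .4)
vectorize_edges <- function(R) {
  V <- if (inherits(R, "adjacency_matrix")) R$values else as.matrix(R)
  # column-major lower.tri of the transpose walks the upper triangle in
  # row-major (i, j) order: (1,2),(1,3),...,(1,N),(2,3),...
  t(V)[lower.tri(V)]
}

# Feature matrix (scans x edges) for one order tag.
edge_feature_matrix <- function(ds, order_tag) {
  order_tag <- as.character(order_tag)
  rows <- lapply(ds$scans, function(s) {
    net <- s$networks[[order_tag]]
    if (is.null(net)) {
      stop_validation("order '", order_tag, "' not available for scan ",
                      s$scan_id)
    }
    vectorize_edges(net)
  })
  do.call(rbind, rows)
}

# Vectorized two-sample t-test p-values over feature columns. Pooled
# variance by default (classic two-sample t); Welch optional. Columns with
# zero pooled variance get p = 1 when the group means agree and p = 0 when
# they differ (an infinitely strong effect on a noiseless feature).
edge_ttest_pvalues <- function(features, is_positive, var_equal = TRUE) {
  x <- features[is_positive, , drop = FALSE]
  y <- features[!is_positive, , drop = FALSE]
  n1 <- nrow(x); n2 <- nrow(y)
  if (n1 < 2L || n2 < 2L) {
    stop_validation("need at least two scans per class for the t-test")
  }
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colSums(sweep(x, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(y, 2L, m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- rep(1, ncol(features))
  ok <- se2 > 0 & is.finite(df) & df > 0
  tt <- (m1 - m2)[ok] / sqrt(se2[ok])
  p[ok] <- 2 * stats::pt(-abs(tt), df[ok])
  p[!ok & m1 != m2] <- 0
  p
}

#' Select discriminative edges by two-sample t-test
#'
#' Applies an independent two-sample t-test to every edge feature and keeps
#' those with p-value below the threshold. Because the number of edges far
#' exceeds the number of scans, this filtering precedes classification.
#'
#' @param features Numeric matrix, scans x edges (training scans only, to
#'   avoid information leakage into the test fold).
#' @param labels Character vector of scan labels.
#' @param p_threshold Significance threshold in (0, 1).
#' @param positive_class Label treated as group 1.
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return Integer vector of selected edge indices, with the full p-value
#'   vector attached as attribute `"p_values"`. An empty selection is
#'   allowed (flagged with a warning by callers that cannot proceed).
#' @export
ttest_select <- function(features, labels, p_threshold = 0.05,
                         positive_class = NULL, var_equal = TRUE) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop_validation("p_threshold must lie in (0, 1)")
  }
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop_validation("t-test selection needs exactly two classes in labels")
  }
  positive_class <- positive_class %||% classes[1L]
  p <- edge_ttest_pvalues(features, labels == positive_class,
                          var_equal = var_equal)
  structure(which(p < p_threshold), p_values = p)
}

#' Subject-level cross-validation folds
#'
#' Randomly assigns subjects (not scans) to `k` folds so that all scans of
#' one subject share a fold and fold sizes in subjects differ by at most
#' one. Folds are stratified by subject label (subjects with mixed-label
#' scans are stratified by their majority label), and the assignment is
#' deterministic given the seed.
#'
#' @param ds A [labeled_dataset()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the subject permutation.
#' @return Object of class `fold_split`: named integer vector mapping
#'   subject_id to fold index in 1..k.
#' @export
subject_level_folds <- function(ds, k = 5L, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  k <- as.integer(k)
  if (k < 2L) stop_validation("k must be >= 2")
  subjects <- dataset_subjects(ds)
  labels <- dataset_labels(ds)
  uniq <- unique(subjects)
  if (length(uniq) < k) {
    stop_validation("fewer subjects (", length(uniq), ") than folds (", k, ")")
  }
  # majority label per subject (ties broken by label order for determinism)
  subj_label <- vapply(uniq, function(s) {
    tab <- sort(table(labels[subjects == s]), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
  assignment <- integer(length(uniq))
  names(assignment) <- uniq
  with_seed(seed, {
    at <- 0L
    for (lab in sort(unique(subj_label))) {
      members <- sample(uniq[subj_label == lab])
      assignment[members] <- ((at + seq_along(members) - 1L) %% k) + 1L
      at <- at + length(members)
    }
  })
  structure(assignment, k = k, class = "fold_split")
}

#' Train a linear max-margin classifier with sigmoid calibration
#'
#' Fits a linear support vector machine (cost parameter `C`, default 1) on
#' the selected edge features and calibrates its decision values into
#' positive-class probabilities with a Platt-style sigmoid fitted on the
#' training data (soft targets to avoid saturation on separable data). If
#' the feature matrix is empty (no edges survived selection) the classifier
#' degrades, with a warning, to the training-set positive-class frequency.
#'
#' @param features Numeric matrix, scans x selected edges.
#' @param labels Character vector of scan labels.
#' @param positive_class Label of the positive class.
#' @param C Regularization parameter of the SVM (kept at the default 1).
#' @return Object of class `pcn_classifier` with a [predict][stats::predict]
#'   method returning positive-class probabilities.
#' @export
train_probabilistic_classifier <- function(features, labels, positive_class,
                                           C = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) {
    stop_validation("classifier training needs exactly two classes")
  }
  y <- factor(labels == positive_class, levels = c(FALSE, TRUE))
  if (is.null(dim(features)) || ncol(features) == 0L) {
    warning("empty feature set after selection; falling back to the ",
            "majority-class probability")
    return(structure(list(type = "prior", prior = mean(y == TRUE)),
                     class = "pcn_classifier"))
  }
  fit <- e1071::svm(x = features, y = y, kernel = "linear", cost = C,
                    scale = FALSE, probability = FALSE)
  dv <- as.numeric(attr(stats::predict(fit, features, decision.values = TRUE),
                        "decision.values"))
  calib <- platt_sigmoid(dv, y == TRUE)
  structure(list(type = "svm", fit = fit, calibration = calib),
            class = "pcn_classifier")
}

# Platt scaling: logistic fit of the positive-class indicator on the SVM
# decision value, with the classic smoothed targets t+ = (n+ + 1)/(n+ + 2),
# t- = 1/(n- + 2) so a separable training set does not saturate the slope.
platt_sigmoid <- function(decision_values, is_positive) {
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  target <- ifelse(is_positive, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  if (stats::var(decision_values) <= 0) {
    return(list(a = 0, b = stats::qlogis(mean(is_positive)), degenerate = TRUE))
  }
  fit <- suppressWarnings(
    stats::glm(target ~ decision_values, family = stats::quasibinomial())
  )
  co <- stats::coef(fit)
  if (anyNA(co)) {
    return(list(a = 0, b = stats::qlogis(mean(is_positive)), degenerate = TRUE))
  }
  list(a = unname(co[2L]), b = unname(co[1L]), degenerate = FALSE)
}

#' @export
predict.pcn_classifier <- function(object, newdata, ...) {
  if (object$type == "prior") {
    return(rep(object$prior, if (is.null(dim(newdata))) 1L else nrow(newdata)))
  }
  dv <- as.numeric(attr(stats::predict(object$fit, newdata,
                                       decision.values = TRUE),
                        "decision.values"))
  stats::plogis(object$calibration$a * dv + object$calibration$b)
}

#' Classification metrics from probabilities
#'
#' Thresholds positive-class probabilities (predicted positive when
#' probability >= `threshold`) and computes the confusion counts together
#' with accuracy ACC = (TP+TN)/(TP+TN+FP+FN), sensitivity SEN = TP/(TP+FN)
#' and specificity SPE = TN/(TN+FP). Zero-denominator metrics are reported
#' as `NaN` and flagged.
#'
#' @param probabilities Positive-class probabilities, one per scan.
#' @param labels Character vector of true labels.
#' @param positive_class Label of the positive class.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `metrics_report` with fields `TP`, `TN`, `FP`,
#'   `FN`, `ACC`, `SEN`, `SPE`, `undefined` (names of metrics with zero
#'   denominator) and `threshold`.
#' @export
evaluate_metrics <- function(probabilities, labels, positive_class,
                             threshold = 0.5) {
  labels <- as.character(labels)
  if (length(probabilities) != length(labels)) {
    stop_validation("probabilities and labels must be aligned")
  }
  truth <- labels == positive_class
  pred <- probabilities >= threshold
  TP <- sum(pred & truth); TN <- sum(!pred & !truth)
  FP <- sum(pred & !truth); FN <- sum(!pred & truth)
  safe_div <- function(num, den) if (den == 0) NaN else num / den
  out <- list(TP = TP, TN = TN, FP = FP, FN = FN,
              ACC = safe_div(TP + TN, TP + TN + FP + FN),
              SEN = safe_div(TP, TP + FN),
              SPE = safe_div(TN, TN + FP),
              threshold = threshold)
  out$undefined <- names(Filter(is.nan, out[c("ACC", "SEN", "SPE")]))
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> ACC %.3f | SEN %.3f | SPE %.3f  (TP %d, TN %d, FP %d, FN %d)\n",
              x$ACC, x$SEN, x$SPE, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Convex fusion of two classifiers' probabilities
#'
#' Late fusion of the low-order and higher-order network classifiers:
#' elementwise `lam * O1 + (1 - lam) * O2`.
#'
#' @param O1,O2 Probability vectors of equal length.
#' @param lam Mixing weight in \[0, 1\] on `O1`.
#' @return Fused probability vector.
#' @export
fuse_probabilities <- function(O1, O2, lam) {
  if (length(O1) != length(O2)) stop_validation("O1 and O2 must align")
  if (!is.numeric(lam) || lam < 0 || lam > 1) {
    stop_validation("lam must lie in [0, 1]")
  }
  lam * O1 + (1 - lam) * O2
}

# Fit the two per-order classifiers on training scans and score a test set.
# Returns list(O1, O2, n_selected). Selection and calibration only ever see
# the training rows.
fuse_channel_probs <- function(f1_train, f2_train, train_labels,
                               f1_test, f2_test, positive_class,
                               p_threshold, C = 1, var_equal = TRUE) {
  score <- function(f_train, f_test) {
    sel <- ttest_select(f_train, train_labels, p_threshold,
                        positive_class = positive_class, var_equal = var_equal)
    clf <- suppressWarnings(
      train_probabilistic_classifier(f_train[, sel, drop = FALSE],
                                     train_labels, positive_class, C = C))
    list(probs = predict(clf, f_test[, sel, drop = FALSE]),
         n_selected = length(sel))
  }
  s1 <- score(f1_train, f1_test)
  s2 <- score(f2_train, f2_test)
  list(O1 = s1$probs, O2 = s2$probs,
       n_selected = c(s1$n_selected, s2$n_selected))
}

#' Select the fusion weight by inner cross-validation
#'
#' Runs an inner subject-level k-fold cross-validation of the full fusion
#' pipeline (edge selection, two classifiers, convex fusion) on the
#' training scans only, and returns the grid value of lambda with the
#' highest pooled inner accuracy. Ties are broken toward 0.5, then toward
#' the smaller value.
#'
#' @param features1,features2 Training feature matrices (scans x edges) for
#'   the low-order and higher-order channel.
#' @param labels,subject_ids Per-scan labels and subject identifiers.
#' @param positive_class Label of the positive class.
#' @param p_threshold Edge-selection threshold used inside the inner folds.
#' @param grid Candidate lambda values (default 0.1, 0.2, ..., 0.9).
#' @param inner_k Number of inner folds (default 5).
#' @param seed Seed for the inner fold split.
#' @param C SVM cost.
#' @param var_equal Pooled-variance t-test if `TRUE`.
#' @return Selected lambda, with the per-lambda mean inner accuracies as
#'   attribute `"inner_acc"`.
#' @export
select_lambda <- function(features1, features2, labels, subject_ids,
                          positive_class, p_threshold = 0.05,
                          grid = seq(0.1, 0.9, by = 0.1), inner_k = 5L,
                          seed = 1L, C = 1, var_equal = TRUE) {
  if (any(grid <= 0 | grid >= 1)) stop_validation("grid values must lie in (0,1)")
  if (length(grid) == 1L) return(structure(grid, inner_acc = NA_real_))
  scans <- lapply(seq_along(labels), function(i) {
    list(networks = list(), scan_id = as.character(i),
         subject_id = subject_ids[i], label = labels[i])
  })
  inner_ds <- labeled_dataset(scans, positive_class = positive_class)
  folds <- subject_level_folds(inner_ds, k = inner_k, seed = seed)
  O1 <- O2 <- rep(NA_real_, length(labels))
  for (fold in seq_len(attr(folds, "k"))) {
    test <- folds[subject_ids] == fold
    if (!any(test)) next
    if (length(unique(labels[!test])) != 2L) next
    ch <- fuse_channel_probs(features1[!test, , drop = FALSE],
                             features2[!test, , drop = FALSE],
                             labels[!test],
                             features1[test, , drop = FALSE],
                             features2[test, , drop = FALSE],
                             positive_class, p_threshold, C = C,
                             var_equal = var_equal)
    O1[test] <- ch$O1
    O2[test] <- ch$O2
  }
  scored <- !is.na(O1)
  acc <- vapply(grid, function(lam) {
    m <- evaluate_metrics(fuse_probabilities(O1[scored], O2[scored], lam),
                          labels[scored], positive_class)
    m$ACC
  }, numeric(1))
  best <- which(acc == max(acc))
  if (length(best) > 1L) {
    best <- best[order(abs(grid[best] - 0.5), grid[best])][1L]
  }
  structure(grid[best], inner_acc = stats::setNames(acc, grid))
}

#' Run the cross-validated classification experiment
#'
#' The full evaluation protocol: outer subject-level k-fold
#' cross-validation; within every training fold, two-sample t-test edge
#' selection at each threshold of `p_grid` and linear-SVM training (plus
#' inner selection of the fusion weight lambda and retraining, in fusion
#' mode); test predictions pooled over the outer folds into one
#' `metrics_report` per condition. All data-dependent choices (selection,
#' calibration, lambda) are fitted on training folds only.
#'
#' @param ds A [labeled_dataset()] whose scans carry matrices at the
#'   requested orders.
#' @param orders Order tags to evaluate (e.g. `c("1", "2", "conv")`). In
#'   fusion mode each tag other than the first is fused with the first
#'   (low-order) tag.
#' @param p_grid Edge-selection thresholds (default 0.05, 0.01, 0.005,
#'   0.001).
#' @param mode `"single"` (one classifier per order) or `"fusion"`
#'   (probability fusion of order tag 1 with each higher tag).
#' @param k Outer folds (default 5).
#' @param seed Master seed controlling the outer split and inner splits.
#' @param lambda_grid Fusion-weight grid (default 0.1..0.9).
#' @param inner_k Inner folds for lambda selection (default 5).
#' @param C SVM cost (default 1).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @param selection_scope `"fold"` (default; edges selected inside each
#'   training fold) or `"global"` (edges selected once on the full dataset
#'   before cross-validation; reports larger feature counts but leaks the
#'   test scans into selection, so use it only for feature-count audits).
#' @return Object of class `experiment_result`: list keyed
#'   `"order=<tag>,p=<p>"` (or `"fusion=<tag>&1,p=<p>"`), each entry a list
#'   with `metrics` (pooled `metrics_report`), `per_fold` metrics,
#'   `n_features_selected` per fold, `probabilities`, `labels` and, for
#'   fusion, `lambda_selected` per fold. The seed and configuration are
#'   attached.
#' @export
run_experiment <- function(ds, orders = c("1", "conv"),
                           p_grid = c(0.05, 0.01, 0.005, 0.001),
                           mode = c("single", "fusion"), k = 5L, seed = 1L,
                           lambda_grid = seq(0.1, 0.9, by = 0.1),
                           inner_k = 5L, C = 1, var_equal = TRUE,
                           selection_scope = c("fold", "global")) {
  stopifnot(inherits(ds, "labeled_dataset"))
  mode <- match.arg(mode)
  selection_scope <- match.arg(selection_scope)
  orders <- as.character(orders)
  labels <- dataset_labels(ds)
  subjects <- dataset_subjects(ds)
  pos <- ds$positive_class

  feats <- lapply(stats::setNames(orders, orders),
                  function(o) edge_feature_matrix(ds, o))
  seeds <- derive_seeds(seed, 1L + k)
  folds <- subject_level_folds(ds, k = k, seed = seeds[1L])
  fold_of_scan <- folds[subjects]

  results <- list()
  run_single <- function(order_tag, p) {
    F <- feats[[order_tag]]
    global_sel <- if (selection_scope == "global") {
      ttest_select(F, labels, p, positive_class = pos, var_equal = var_equal)
    } else NULL
    probs <- rep(NA_real_, length(labels))
    per_fold <- list(); n_sel <- integer(0)
    for (fold in seq_len(k)) {
      test <- fold_of_scan == fold
      sel <- global_sel %||%
        ttest_select(F[!test, , drop = FALSE], labels[!test], p,
                     positive_class = pos, var_equal = var_equal)
      clf <- suppressWarnings(
        train_probabilistic_classifier(F[!test, sel, drop = FALSE],
                                       labels[!test], pos, C = C))
      probs[test] <- predict(clf, F[test, sel, drop = FALSE])
      per_fold[[fold]] <- evaluate_metrics(probs[test], labels[test], pos)
      n_sel <- c(n_sel, length(sel))
    }
    list(metrics = evaluate_metrics(probs, labels, pos),
         per_fold = per_fold, n_features_selected = n_sel,
         probabilities = probs, labels = labels)
  }
  run_fusion <- function(order_tag, p) {
    F1 <- feats[[orders[1L]]]
    F2 <- feats[[order_tag]]
    probs <- rep(NA_real_, length(labels))
    per_fold <- list(); n_sel <- list(); lam_sel <- numeric(0)
    for (fold in seq_len(k)) {
      test <- fold_of_scan == fold
      lam <- select_lambda(F1[!test, , drop = FALSE], F2[!test, , drop = FALSE],
                           labels[!test], subjects[!test], pos,
                           p_threshold = p, grid = lambda_grid,
                           inner_k = inner_k, seed = seeds[1L + fold],
                           C = C, var_equal = var_equal)
      ch <- fuse_channel_probs(F1[!test, , drop = FALSE],
                               F2[!test, , drop = FALSE], labels[!test],
                               F1[test, , drop = FALSE],
                               F2[test, , drop = FALSE],
                               pos, p, C = C, var_equal = var_equal)
      probs[test] <- fuse_probabilities(ch$O1, ch$O2, as.numeric(lam))
      per_fold[[fold]] <- evaluate_metrics(probs[test], labels[test], pos)
      n_sel[[fold]] <- ch$n_selected
      lam_sel <- c(lam_sel, as.numeric(lam))
    }
    list(metrics = evaluate_metrics(probs, labels, pos),
         per_fold = per_fold, n_features_selected = n_sel,
         lambda_selected = lam_sel, probabilities = probs, labels = labels)
  }

  for (p in p_grid) {
    if (mode == "single") {
      for (o in orders) {
        results[[sprintf("order=%s,p=%g", o, p)]] <- run_single(o, p)
      }
    } else {
      for (o in orders[-1L]) {
        results[[sprintf("fusion=%s&%s,p=%g", o, orders[1L], p)]] <-
          run_fusion(o, p)
      }
    }
  }
  structure(results, class = "experiment_result", seed = seed, k = k,
            mode = mode, orders = orders, p_grid = p_grid)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> mode '%s', k = %d, seed = %d\n",
              attr(x, "mode"), attr(x, "k"), attr(x, "seed")))
  for (key in names(x)) {
    m <- x[[key]]$metrics
    cat(sprintf("  %-24s ACC %.3f  SEN %.3f  SPE %.3f\n",
                key, m$ACC, m$SEN, m$SPE))
  }
  invisible(x)
}
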