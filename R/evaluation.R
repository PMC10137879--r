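#' Cross-validation scheme
#'
#' Repeated stratified k-fold cross-validation over the labeled subjects.
#' Unlabeled subjects never enter a test fold; with
#' `include_unlabeled = TRUE` they are present in the training graph as
#' feature-only nodes. Defaults follow the evaluation protocol of the
#' motivating study: 5 folds repeated 50 times, both the fold assignment and
#' the model initialization re-randomized each repeat.
#'
#' @param n_folds Number of folds (default 5).
#' @param n_repeats Number of repetitions (default 50).
#' @param stratified Stratify folds by class (default TRUE; a non-stratified
#'   mode exists for protocol comparison).
#' @param include_unlabeled Keep unlabeled subjects in the training graph.
#' @param base_seed Seed from which every repeat's fold shuffle and model
#'   seed are derived.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_folds = 5, n_repeats = 50, stratified = TRUE,
                      include_unlabeled = TRUE, base_seed = 1L) {
  if (n_folds < 2) stop_user("n_folds must be at least 2")
  if (n_repeats < 1) stop_user("n_repeats must be at least 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified),
                 include_unlabeled = isTRUE(include_unlabeled),
                 base_seed = as.integer(base_seed)),
            class = "cv_scheme")
}

# Near-equal fold sizes per class, spreading each class's remainder onto the
# folds currently holding the fewest subjects, so overall fold sizes differ by
# at most one (119 labeled subjects -> sizes 24,24,24,24,23).
stratified_fold_sizes <- function(class_counts, n_folds) {
  totals <- integer(n_folds)
  sizes <- matrix(0L, length(class_counts), n_folds)
  for (k in seq_along(class_counts)) {
    base <- class_counts[k] %/% n_folds
    rem <- class_counts[k] %% n_folds
    sizes[k, ] <- base
    if (rem > 0) {
      take <- order(totals, seq_len(n_folds))[seq_len(rem)]
      sizes[k, take] <- sizes[k, take] + 1L
    }
    totals <- totals + sizes[k, ]
  }
  sizes
}

#' Assign labeled subjects to cross-validation folds
#'
#' Per repeat, partitions the labeled subjects into `n_folds` near-equal
#' portions (stratified by class when `scheme$stratified`), deterministically
#' from `base_seed` and the repeat index. Every labeled subject lands in
#' exactly one fold; unlabeled subjects are never assigned.
#'
#' @param manifest A `cohort_manifest`.
#' @param scheme A `cv_scheme`.
#' @return List of length `n_repeats`; each element is a named integer vector
#'   (names = labeled subject ids, values = fold index).
#' @export
make_folds <- function(manifest, scheme) {
  labeled <- manifest$label != "unlabeled"
  ids <- manifest$subject_id[labeled]
  cls <- manifest$label[labeled]
  if (scheme$stratified) {
    counts <- table(cls)
    if (any(counts < scheme$n_folds)) {
      stop_user("class '%s' has %d labeled subjects, fewer than %d folds",
                names(counts)[which.min(counts)], min(counts), scheme$n_folds)
    }
  } else if (length(ids) < scheme$n_folds) {
    stop_user("%d labeled subjects, fewer than %d folds", length(ids), scheme$n_folds)
  }
  lapply(seq_len(scheme$n_repeats), function(r) {
    with_seed(derive_seed(scheme$base_seed, 101L, r), {
      assign <- integer(length(ids))
      if (scheme$stratified) {
        classes <- sort(unique(cls))
        sizes <- stratified_fold_sizes(as.integer(table(factor(cls, classes))),
                                       scheme$n_folds)
        for (k in seq_along(classes)) {
          members <- sample(which(cls == classes[k]))
          assign[members] <- rep(seq_len(scheme$n_folds), sizes[k, ])
        }
      } else {
        sizes <- stratified_fold_sizes(length(ids), scheme$n_folds)
        assign[sample(seq_along(ids))] <- rep(seq_len(scheme$n_folds), sizes[1, ])
      }
      stats::setNames(assign, ids)
    })
  })
}

#' Classification metrics for binary risk prediction
#'
#' Computes accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' balanced accuracy (sensitivity + specificity)/2, and AUC by the
#' Mann-Whitney rank statistic with midranks for tied scores. Positive
#' (high-risk) is the event class. If `truth` holds a single class, AUC is
#' `NA` and the remaining metrics are still computed.
#'
#' @param truth Integer (1 positive / 0 negative) or character labels.
#' @param predicted Predicted labels, same coding.
#' @param scores Positive-class probabilities or decision scores.
#' @return Named list: `accuracy`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
compute_metrics <- function(truth, predicted, scores) {
  to01 <- function(x) {
    if (is.character(x) || is.factor(x)) as.integer(as.character(x) == "positive")
    else as.integer(x)
  }
  y <- to01(truth)
  yhat <- to01(predicted)
  if (length(y) == 0L || length(y) != length(yhat) || length(y) != length(scores)) {
    stop_user("truth, predicted and scores must be non-empty and aligned")
  }
  tp <- sum(y == 1 & yhat == 1); fn <- sum(y == 1 & yhat == 0)
  tn <- sum(y == 0 & yhat == 0); fp <- sum(y == 0 & yhat == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- if (any(y == 1) && any(y == 0)) {
    r <- rank(scores)                 # midranks average ties
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  list(accuracy = mean(y == yhat),
       balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec, auc = auc)
}

metric_names <- c("accuracy", "balanced_accuracy", "sensitivity",
                  "specificity", "auc")

new_report <- function(rows) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("evaluation_report", "data.frame")
  df
}

#' Run repeated cross-validation for one model
#'
#' For every repeat and fold: the held-out labeled portion becomes the test
#' set, the remaining labeled subjects train the model, and (for the GCN with
#' `include_unlabeled = TRUE`) the unlabeled subjects stay in the graph as
#' feature-only nodes. For GCN models the test-fold nodes are present in the
#' graph with their labels masked (transductive evaluation); baselines are
#' fitted on the labeled training features only. The kernel graph is built
#' once per cohort and only the masks change across folds.
#'
#' @param cohort List with `connectomes` and `manifest` (as returned by
#'   [read_cohort()] or [generate_cohort()]).
#' @param scheme A `cv_scheme`.
#' @param model `"gcn"` or a baseline name
#'   (`"logistic"`, `"ridge"`, `"svm_linear"`, `"svm_rbf"`, `"dnn"`).
#' @param config `gcn_config` used when `model = "gcn"` (also provides the
#'   architecture of the `"dnn"` baseline).
#' @param sigma,kernel,standardize Graph construction settings, see
#'   [build_graph()].
#' @param folds Optional precomputed [make_folds()] output, to evaluate
#'   several models under identical fold assignments.
#' @return An `evaluation_report`: one row per (repeat, fold) with the five
#'   metrics; aggregate with [aggregate_report()].
#' @export
run_cv <- function(cohort, scheme = cv_scheme(), model = "gcn",
                   config = gcn_config(), sigma = 1.6, kernel = "gaussian",
                   standardize = FALSE, folds = NULL) {
  manifest <- cohort$manifest
  X <- feature_matrix(cohort$connectomes)
  folds <- folds %||% make_folds(manifest, scheme)
  is_gcn <- identical(model, "gcn")
  if (is_gcn) {
    keep <- if (scheme$include_unlabeled) rep(TRUE, nrow(manifest)) else
      manifest$label != "unlabeled"
    sub_manifest <- manifest[keep, , drop = FALSE]
    class(sub_manifest) <- c("cohort_manifest", "data.frame")
    graph <- build_graph(X[keep, , drop = FALSE], sub_manifest, sigma = sigma,
                         kernel = kernel, standardize = standardize)
  }
  labeled_ids <- manifest$subject_id[manifest$label != "unlabeled"]
  y_all <- stats::setNames(as.integer(manifest$label == "positive"),
                           manifest$subject_id)
  rows <- list()
  for (r in seq_len(scheme$n_repeats)) {
    fold_assign <- folds[[r]]
    for (f in sort(unique(fold_assign))) {
      test_ids <- names(fold_assign)[fold_assign == f]
      train_ids <- setdiff(labeled_ids, test_ids)
      seed_rf <- derive_seed(scheme$base_seed, r, f)
      if (is_gcn) {
        g <- set_graph_masks(graph, test_ids)
        cfg <- config
        cfg$seed <- seed_rf
        fit <- train_gcn(g, cfg)
        pred <- predict_gcn(fit, test_ids)
        m <- compute_metrics(y_all[test_ids], pred$label,
                             pred$probability_positive)
      } else {
        fit <- fit_baseline(model, X[train_ids, , drop = FALSE],
                            y_all[train_ids], seed = seed_rf, config = config)
        pred <- predict_baseline(fit, X[test_ids, , drop = FALSE])
        m <- compute_metrics(y_all[test_ids], pred$label, pred$score)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_id = r, fold = f, model = model,
                   accuracy = m$accuracy, balanced_accuracy = m$balanced_accuracy,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   auc = m$auc, stringsAsFactors = FALSE)
    }
  }
  new_report(rows)
}

#' Run all supervised baselines under shared folds
#'
#' Evaluates the class-weighted logistic regression, ridge classifier, linear
#' and RBF SVMs, and the feed-forward network on the labeled subjects'
#' feature vectors, under exactly the fold assignments used for the GCN so
#' paired per-fold comparisons are possible.
#'
#' @inheritParams run_cv
#' @param models Character vector of baseline names.
#' @return A combined `evaluation_report`.
#' @export
run_baselines <- function(cohort, scheme = cv_scheme(),
                          models = c("logistic", "ridge", "svm_linear",
                                     "svm_rbf", "dnn"),
                          config = gcn_config(), folds = NULL) {
  folds <- folds %||% make_folds(cohort$manifest, scheme)
  reports <- lapply(models, function(m) {
    run_cv(cohort, scheme, model = m, config = config, folds = folds)
  })
  new_report(reports)
}

#' Aggregate an evaluation report
#'
#' @param report An `evaluation_report`.
#' @return `data.frame` with one row per model and `mean`/`sd` columns per
#'   metric, mirroring the usual mean ± SD results-table layout.
#' @export
aggregate_report <- function(report) {
  out <- lapply(split(report, report$model), function(d) {
    stats_row <- data.frame(model = d$model[1L], stringsAsFactors = FALSE)
    for (m in metric_names) {
      stats_row[[paste0(m, "_mean")]] <- mean(d[[m]], na.rm = TRUE)
      stats_row[[paste0(m, "_sd")]] <- stats::sd(d[[m]], na.rm = TRUE)
    }
    stats_row
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Paired comparison of two evaluation reports
#'
#' Averages the chosen metric per repeat in each report, then applies a
#' paired two-sided test across repeats: a paired t-test by default, the
#' Wilcoxon signed-rank test as an alternative. Both reports must share the
#' (repeat, fold) structure, which [run_cv()] guarantees when the same folds
#' and scheme are used.
#'
#' @param report_a,report_b `evaluation_report`s with identical
#'   (repeat, fold) rows.
#' @param metric One of accuracy, balanced_accuracy, sensitivity,
#'   specificity, auc.
#' @param method `"t"` or `"wilcoxon"`.
#' @return List: `metric`, `mean_a`, `mean_b`, `mean_difference` (a - b),
#'   `conf_int` (t-test only), `p_value`, `method`, `n_repeats`.
#' @export
compare_reports <- function(report_a, report_b, metric = "accuracy",
                            method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (!metric %in% metric_names) stop_user("unknown metric '%s'", metric)
  key_a <- paste(report_a$repeat_id, report_a$fold)
  key_b <- paste(report_b$repeat_id, report_b$fold)
  if (!identical(sort(key_a), sort(key_b))) {
    stop_user("reports do not share the same (repeat, fold) structure")
  }
  per_rep <- function(rep) {
    vapply(split(rep[[metric]], rep$repeat_id), mean, numeric(1), na.rm = TRUE)
  }
  a <- per_rep(report_a)
  b <- per_rep(report_b)
  d <- a - b
  if (stats::sd(d) == 0 || length(d) < 2) {
    p <- if (all(d == 0)) 1 else 0
    ci <- c(mean(d), mean(d))
  } else if (method == "t") {
    tt <- stats::t.test(a, b, paired = TRUE)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  } else {
    p <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
    ci <- c(NA_real_, NA_real_)
  }
  list(metric = metric, mean_a = mean(a), mean_b = mean(b),
       mean_difference = mean(d), conf_int = ci, p_value = p,
       method = method, n_repeats = length(d))
}

#' Write an evaluation report to disk
#'
#' Writes the tidy per-fold CSV
#' (`repeat,fold,model,accuracy,balanced_accuracy,sensitivity,specificity,auc`),
#' the aggregated mean ± SD table, and a JSON summary.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tidy <- as.data.frame(report)
  names(tidy)[names(tidy) == "repeat_id"] <- "repeat"
  utils::write.csv(tidy, file.path(dir, "metrics_per_fold.csv"), row.names = FALSE)
  agg <- aggregate_report(report)
  utils::write.csv(agg, file.path(dir, "metrics_aggregated.csv"), row.names = FALSE)
  jsonlite::write_json(agg, file.path(dir, "metrics_aggregated.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
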