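make_manifest <- function(n_pos, n_neg, n_unl = 0) {
  n <- n_pos + n_neg + n_unl
  cohort_manifest(sprintf("s%03d", seq_len(n)),
                  motor_score = NA_real_,
                  label = c(rep("positive", n_pos), rep("negative", n_neg),
                            rep("unlabeled", n_unl)))
}

test_that("stratified folds are near-equal, exhaustive and deterministic", {
  man <- make_manifest(37, 82, 105)
  scheme <- cv_scheme(n_folds = 5, n_repeats = 3, base_seed = 2)
  folds <- make_folds(man, scheme)
  labeled_ids <- man$subject_id[man$label != "unlabeled"]
  for (f in folds) {
    expect_setequal(names(f), labeled_ids)          # every labeled subject once
    expect_identical(sort(as.integer(table(f)), decreasing = TRUE),
                     as.integer(c(24, 24, 24, 24, 23)))
    # stratification: positives spread 8/8/7/7/7
    pos <- f[man$label[match(names(f), man$subject_id)] == "positive"]
    expect_identical(sort(as.integer(table(factor(pos, 1:5))), decreasing = TRUE),
                     as.integer(c(8, 8, 7, 7, 7)))
    expect_false(any(man$subject_id[man$label == "unlabeled"] %in% names(f)))
  }
  expect_identical(make_folds(man, scheme), folds)  # same seed, same folds
  expect_false(identical(folds[[1]], folds[[2]]))   # repeats re-randomize

  man10 <- make_manifest(5, 5)
  f10 <- make_folds(man10, cv_scheme(n_folds = 5, n_repeats = 1, base_seed = 1))[[1]]
  for (k in 1:5) {
    cls <- man10$label[match(names(f10)[f10 == k], man10$subject_id)]
    expect_identical(sort(cls), c("negative", "positive"))
  }

  expect_error(make_folds(make_manifest(3, 40),
                          cv_scheme(n_folds = 5, n_repeats = 1)),
               "fewer than 5 folds")
})

test_that("metrics match hand-computed confusion and rank oracles", {
  m <- compute_metrics(truth = c(1, 1, 0, 0), predicted = c(1, 0, 0, 0),
                       scores = c(0.9, 0.4, 0.3, 0.2))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$balanced_accuracy, 0.75)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$auc, 1.0)

  perfect <- compute_metrics(c(1, 0), c(1, 0), c(0.9, 0.1))
  expect_true(all(unlist(perfect) == 1))

  # score reversal flips the AUC
  set.seed(3)
  truth <- rbinom(40, 1, 0.4)
  sc <- runif(40)
  a1 <- compute_metrics(truth, round(sc), sc)$auc
  a2 <- compute_metrics(truth, round(sc), 1 - sc)$auc
  expect_equal(a2, 1 - a1)

  # midrank AUC equals the all-pairs oracle (with ties) and pROC
  for (k in 1:10) {
    n <- sample(10:50, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # heavy ties
    got <- compute_metrics(truth, truth, sc)$auc
    expect_equal(got, brute_auc(truth, sc), tolerance = 1e-12)
    proc <- suppressMessages(pROC::auc(pROC::roc(truth, sc, quiet = TRUE,
                                                 direction = "<")))
    expect_equal(got, as.numeric(proc), tolerance = 1e-12)
  }

  single <- compute_metrics(c(1, 1), c(1, 0), c(0.9, 0.2))
  expect_true(is.na(single$auc))
  expect_equal(single$sensitivity, 0.5)
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  set.seed(17)
  for (k in 1:20) {
    truth <- c(1, 0, rbinom(20, 1, 0.5))
    pred <- rbinom(22, 1, 0.5)
    m <- compute_metrics(truth, pred, runif(22))
    expect_identical(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  }
})

test_that("report comparison recovers injected differences", {
  base <- expand.grid(repeat_id = 1:6, fold = 1:3)
  mk <- function(acc) {
    df <- data.frame(base, model = "m", accuracy = acc, balanced_accuracy = acc,
                     sensitivity = acc, specificity = acc, auc = acc)
    class(df) <- c("evaluation_report", "data.frame")
    df
  }
  set.seed(8)
  acc <- runif(18, 0.5, 0.9)
  ra <- mk(acc)
  self <- compare_reports(ra, ra, "accuracy")
  expect_equal(self$mean_difference, 0)
  expect_equal(self$p_value, 1)

  shifted <- compare_reports(mk(acc + 0.05), ra, "accuracy")
  expect_equal(shifted$mean_difference, 0.05, tolerance = 1e-12)
  expect_lt(shifted$p_value, 0.01)
  wil <- compare_reports(mk(acc + 0.05), ra, "accuracy", method = "wilcoxon")
  expect_lt(wil$p_value, 0.05)

  rb <- mk(acc)
  rb$fold <- rb$fold + 10
  expect_error(compare_reports(ra, rb), "structure")
})

test_that("cross-validation is deterministic and excludes unlabeled from testing", {
  co <- separable_cohort(seed = 10, n_labeled = 25, n_unlabeled = 10, n_rois = 8)
  scheme <- cv_scheme(n_folds = 5, n_repeats = 2, base_seed = 3)
  cfg <- gcn_config(max_epochs = 40, seed = 1)
  r1 <- run_cv(co, scheme, model = "gcn", config = cfg, sigma = 1.6)
  r2 <- run_cv(co, scheme, model = "gcn", config = cfg, sigma = 1.6)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10)
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))

  folds <- make_folds(co$manifest, scheme)
  unl <- co$manifest$subject_id[co$manifest$label == "unlabeled"]
  for (f in folds) expect_length(intersect(names(f), unl), 0)
})

test_that("baselines learn a separable cohort under shared folds", {
  co <- separable_cohort(seed = 12, n_labeled = 30, n_unlabeled = 0, n_rois = 8)
  scheme <- cv_scheme(n_folds = 3, n_repeats = 1, base_seed = 5)
  folds <- make_folds(co$manifest, scheme)
  cfg <- gcn_config(max_epochs = 60, seed = 2)
  rep <- run_baselines(co, scheme, config = cfg, folds = folds)
  agg <- aggregate_report(rep)
  expect_setequal(agg$model, c("logistic", "ridge", "svm_linear", "svm_rbf", "dnn"))
  for (i in seq_len(nrow(agg))) {
    expect_gt(agg$accuracy_mean[i], 0.9)
  }
  # shared folds give a pairable (repeat, fold) structure
  gcn_rep <- run_cv(co, scheme, model = "gcn", config = cfg, folds = folds)
  cmp <- compare_reports(gcn_rep, rep[rep$model == "svm_rbf", ], "accuracy")
  expect_true(is.finite(cmp$p_value))
})

test_that("reports are written in tidy and aggregated form", {
  dir <- withr::local_tempdir()
  df <- data.frame(repeat_id = rep(1:2, each = 2), fold = rep(1:2, 2),
                   model = "gcn", accuracy = c(0.6, 0.7, 0.65, 0.7),
                   balanced_accuracy = 0.6, sensitivity = 0.5,
                   specificity = 0.7, auc = 0.66)
  class(df) <- c("evaluation_report", "data.frame")
  write_report(df, dir)
  tidy <- utils::read.csv(file.path(dir, "metrics_per_fold.csv"))
  expect_identical(names(tidy)[1:3], c("repeat.", "fold", "model"))
  agg <- utils::read.csv(file.path(dir, "metrics_aggregated.csv"))
  expect_equal(agg$accuracy_mean, mean(df$accuracy))
  expect_true(file.exists(file.path(dir, "metrics_aggregated.json")))
})
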