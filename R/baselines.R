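# Supervised baseline models on the labeled subjects' feature vectors.
# All handle the ~1:2 class imbalance through class weights where the
# estimator supports them, mirroring the weighted variants used in the
# model-comparison protocol.

baseline_names <- c("logistic", "ridge", "svm_linear", "svm_rbf", "dnn")

#' Fit a supervised baseline classifier
#'
#' * `logistic` — ridge-penalized logistic regression (glmnet, alpha = 0,
#'   fixed lambda = 1/n) with inverse-frequency observation weights.
#' * `ridge` — ridge regression on +/-1 targets (glmnet gaussian, alpha = 0,
#'   lambda = 1/n), classifying by the sign of the fitted value.
#' * `svm_linear`, `svm_rbf` — e1071 SVMs with `class.weights` set to the
#'   inverse class frequencies; decision values serve as ROC scores.
#' * `dnn` — a feed-forward network (two hidden layers of `config$n_filters`
#'   units, batch norm, ReLU, dropout) trained with the same weighted
#'   cross-entropy and Adam loop as the GCN but with an identity propagation
#'   operator, i.e. no node mixing, on the labeled training subjects only.
#'
#' @param model Baseline name.
#' @param X Training feature matrix (rows = subjects).
#' @param y Integer labels, 1 positive / 0 negative.
#' @param seed Seed for the stochastic fits (`dnn`).
#' @param config `gcn_config` supplying the `dnn` width/epochs/dropout.
#' @return A fitted baseline of class `cohortgcn_baseline`.
#' @export
fit_baseline <- function(model, X, y, seed = 1L, config = gcn_config()) {
  if (!model %in% baseline_names) {
    stop_user("unknown baseline '%s' (choose from %s)", model,
              paste(baseline_names, collapse = ", "))
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_user("baseline training labels hold a single class")
  n <- length(y)
  w <- ifelse(y == 1L, n / (2 * sum(y == 1L)), n / (2 * sum(y == 0L)))
  fit <- switch(
    model,
    logistic = glmnet::glmnet(X, factor(y, levels = 0:1), family = "binomial",
                              alpha = 0, lambda = 1 / n, weights = w,
                              standardize = FALSE),
    ridge = glmnet::glmnet(X, ifelse(y == 1L, 1, -1), family = "gaussian",
                           alpha = 0, lambda = 1 / n, weights = w,
                           standardize = FALSE),
    svm_linear = e1071::svm(X, factor(y, levels = 0:1), kernel = "linear",
                            class.weights = c("0" = n / (2 * sum(y == 0L)),
                                              "1" = n / (2 * sum(y == 1L))),
                            scale = FALSE),
    svm_rbf = e1071::svm(X, factor(y, levels = 0:1), kernel = "radial",
                         # variance-scaled bandwidth ("scale" heuristic):
                         # 1/(p * mean feature variance)
                         gamma = 1 / (ncol(X) * max(mean(apply(X, 2, stats::var)), 1e-12)),
                         class.weights = c("0" = n / (2 * sum(y == 0L)),
                                           "1" = n / (2 * sum(y == 1L))),
                         scale = FALSE),
    dnn = fit_mlp(X, y, seed = seed, config = config)
  )
  structure(list(model = model, fit = fit), class = "cohortgcn_baseline")
}

#' Predict from a fitted baseline
#'
#' @param object A `cohortgcn_baseline`.
#' @param X Feature matrix of subjects to score.
#' @return `data.frame` with `label` ("positive"/"negative") and `score`
#'   (probability or decision value oriented so larger means more positive).
#' @export
predict_baseline <- function(object, X) {
  m <- object$model
  fit <- object$fit
  if (m == "logistic") {
    p <- as.numeric(stats::predict(fit, X, type = "response"))
    lab <- ifelse(p >= 0.5, "positive", "negative")
    score <- p
  } else if (m == "ridge") {
    s <- as.numeric(stats::predict(fit, X))
    lab <- ifelse(s >= 0, "positive", "negative")
    score <- s
  } else if (m %in% c("svm_linear", "svm_rbf")) {
    pr <- stats::predict(fit, X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient the decision value toward the positive class
    score <- if (grepl("^1", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
    lab <- ifelse(as.character(pr) == "1", "positive", "negative")
  } else {
    p <- predict_mlp(fit, X)
    lab <- ifelse(p >= 0.5, "positive", "negative")
    score <- p
  }
  data.frame(label = lab, score = as.numeric(score), stringsAsFactors = FALSE)
}

# Feed-forward baseline: reuse the graph-learning machinery with S = I over
# the training subjects only (identity propagation = plain dense layers).
fit_mlp <- function(X, y, seed = 1L, config = gcn_config()) {
  manifest <- cohort_manifest(subject_id = paste0("n", seq_along(y)),
                              motor_score = NA_real_,
                              label = ifelse(y == 1L, "positive", "negative"))
  n <- nrow(X)
  graph <- list(X = unname(X), A = matrix(0, n, n), S = diag(n),
                sigma = NA_real_, kernel = "gaussian",
                node_ids = manifest$subject_id,
                labels = as.integer(y),
                masks = list(train_labeled = rep(TRUE, n),
                             test_labeled = rep(FALSE, n),
                             unlabeled = rep(FALSE, n)))
  class(graph) <- "population_graph"
  cfg <- config
  cfg$seed <- seed
  res <- train_gcn(graph, cfg)
  res$model
}

# With S = I each node is scored independently, so the trained dense layers
# apply to any feature matrix in evaluation mode.
predict_mlp <- function(model, X) {
  n <- nrow(X)
  graph <- structure(list(X = unname(X), S = diag(n)), class = "population_graph")
  probs <- gcn_forward(model, graph, training = FALSE)
  as.numeric(probs[, 2L])
}
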