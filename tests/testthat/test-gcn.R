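test_that("forward pass matches the per-node aggregation oracle", {
  # hand example: 2-node graph, S = [[.5,.5],[.5,.5]], X = [[1],[3]], W = [[1]]
  # -> pre-activation S X W = [[2],[2]]
  cfg <- gcn_config(n_layers = 2, n_filters = 1, dropout_rate = 0, seed = 1)
  model <- with(list(), {
    m <- cohortgcn:::init_gcn(cfg, 1L)
    m$W[[1]] <- matrix(1, 1, 1)
    m
  })
  S <- matrix(0.5, 2, 2)
  graph <- structure(list(S = S, X = matrix(c(1, 3), 2, 1)),
                     class = "population_graph")
  fw <- gcn_forward(model, graph, keep_cache = TRUE)
  expect_equal(fw$cache[[1]]$SH %*% model$W[[1]], matrix(2, 2, 1))

  # isolated nodes (S = I): output depends on own features only
  cfg1 <- gcn_config(n_layers = 1, dropout_rate = 0, seed = 2)
  m1 <- cohortgcn:::init_gcn(cfg1, 4L)
  X <- matrix(rnorm(12), 3, 4)
  gI <- structure(list(S = diag(3), X = X), class = "population_graph")
  pI <- gcn_forward(m1, gI)
  X2 <- X; X2[3, ] <- X2[3, ] + 5
  gI2 <- structure(list(S = diag(3), X = X2), class = "population_graph")
  pI2 <- gcn_forward(m1, gI2)
  expect_equal(pI[1:2, ], pI2[1:2, ])
  expect_false(isTRUE(all.equal(pI[3, ], pI2[3, ])))

  # random 6-node graph, 3 layers, fixed weights: brute-force neighbor sums
  set.seed(11)
  A <- random_symmetric(6)
  S6 <- propagation_operator(A)
  X6 <- matrix(rnorm(6 * 5), 6, 5)
  cfg3 <- gcn_config(n_layers = 3, n_filters = 4, dropout_rate = 0, seed = 3)
  m3 <- cohortgcn:::init_gcn(cfg3, 5L)
  for (l in 1:3) {  # non-trivial batch-norm parameters
    m3$bn[[l]]$gamma <- runif(length(m3$bn[[l]]$gamma), 0.5, 1.5)
    m3$bn[[l]]$beta <- rnorm(length(m3$bn[[l]]$beta), 0, 0.2)
    m3$bn[[l]]$running_mean <- rnorm(length(m3$bn[[l]]$running_mean), 0, 0.3)
    m3$bn[[l]]$running_var <- runif(length(m3$bn[[l]]$running_var), 0.5, 2)
  }
  g6 <- structure(list(S = S6, X = X6), class = "population_graph")
  expect_equal(gcn_forward(m3, g6), brute_forward_eval(m3, S6, X6),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("probability rows sum to one on varied graphs", {
  set.seed(21)
  for (k in 1:5) {
    n <- sample(3:8, 1)
    A <- random_symmetric(n)
    g <- structure(list(S = propagation_operator(A),
                        X = matrix(rnorm(n * 6), n, 6)),
                   class = "population_graph")
    cfg <- gcn_config(n_layers = sample(1:4, 1), n_filters = 8,
                      dropout_rate = 0, seed = k)
    p <- gcn_forward(cohortgcn:::init_gcn(cfg, 6L), g)
    expect_equal(rowSums(p), rep(1, n), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("weighted cross-entropy follows the inverse-frequency algebra", {
  probs <- matrix(0.5, 2, 2)
  labels <- c(1L, 0L)
  mask <- c(TRUE, TRUE)
  expect_equal(weighted_loss(probs, labels, mask, "unweighted"), log(2))
  # equal class counts: every beta is 2, so weighted = 2 x unweighted
  set.seed(5)
  p4 <- t(apply(matrix(runif(8), 4, 2), 1, function(r) r / sum(r)))
  lab4 <- c(1L, 1L, 0L, 0L)
  m4 <- rep(TRUE, 4)
  expect_equal(weighted_loss(p4, lab4, m4, "weighted"),
               2 * weighted_loss(p4, lab4, m4, "unweighted"))

  # the published cohort's counts: 37 positive / 82 negative of 119
  bet <- cohortgcn:::class_weights(c(rep(1L, 37), rep(0L, 82)),
                                   rep(TRUE, 119), "weighted")
  expect_equal(bet[["pos"]], 119 / 37)
  expect_equal(bet[["neg"]], 119 / 82)

  expect_error(weighted_loss(p4, c(1L, 1L, 1L, 1L), m4, "weighted"),
               "single class")
  expect_error(weighted_loss(p4, c(1L, NA, 0L, 0L), m4, "weighted"),
               "missing label")
  # probabilities at 0/1 are clamped, never -Inf
  pext <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_true(is.finite(weighted_loss(pext, labels, mask, "unweighted")))
})

test_that("training is deterministic, masked, and reduces the loss", {
  co <- separable_cohort(seed = 7)
  sp <- split_labeled(co$manifest, seed = 7)
  g <- build_graph(co$connectomes, co$manifest, sigma = 1.6,
                   test_ids = sp$test)
  cfg <- gcn_config(max_epochs = 60, seed = 9)
  r1 <- train_gcn(g, cfg)
  r2 <- train_gcn(g, cfg)
  expect_identical(r1$probabilities, r2$probabilities)
  expect_identical(r1$loss_trajectory, r2$loss_trajectory)

  # labels of unlabeled/test nodes never enter training
  g_perm <- g
  flip <- g$masks$unlabeled | g$masks$test_labeled
  g_perm$labels[flip] <- sample(c(0L, 1L, NA), sum(flip), replace = TRUE)
  r3 <- train_gcn(g_perm, cfg)
  expect_identical(r1$probabilities, r3$probabilities)

  expect_lt(tail(r1$loss_trajectory, 1), r1$loss_trajectory[1])
  expect_length(r1$loss_trajectory, 60)

  # descent on separable data across seeds
  for (s in c(2, 12)) {
    rs <- train_gcn(g, gcn_config(max_epochs = 40, seed = s))
    expect_lt(tail(rs$loss_trajectory, 1), rs$loss_trajectory[1])
  }

  g_bad <- g
  g_bad$labels[g$masks$train_labeled] <- 1L
  expect_error(train_gcn(g_bad, cfg), "inverse-frequency")
})

test_that("a separable cohort is recovered almost perfectly", {
  co <- separable_cohort(seed = 8)
  sp <- split_labeled(co$manifest, frac = 0.3, seed = 8)
  g <- build_graph(co$connectomes, co$manifest, sigma = 1.6, test_ids = sp$test)
  res <- train_gcn(g, gcn_config(max_epochs = 150, seed = 4))
  pred <- predict_gcn(res, sp$test)
  truth <- co$manifest$label[match(sp$test, co$manifest$subject_id)]
  expect_gt(mean(pred$label == truth), 0.9)
  # training accuracy reaches 100%
  tr_pred <- predict_gcn(res, g$masks$train_labeled)
  tr_truth <- co$manifest$label[match(tr_pred$subject_id, co$manifest$subject_id)]
  expect_equal(mean(tr_pred$label == tr_truth), 1.0)
})

test_that("predict resolves ties toward the positive class", {
  res <- structure(list(probabilities = matrix(c(0.2, 0.5, 0.8, 0.5), 2, 2),
                        node_ids = c("a", "b")),
                   class = "gcn_training_result")
  out <- predict_gcn(res)
  expect_identical(out$label, c("positive", "positive"))
  expect_equal(out$probability_positive, c(0.8, 0.5))
  out2 <- predict_gcn(res, "a")
  expect_identical(out2$subject_id, "a")
})

test_that("checkpoints round-trip through disk", {
  co <- separable_cohort(seed = 9, n_labeled = 12, n_unlabeled = 4, n_rois = 6)
  g <- build_graph(co$connectomes, co$manifest, sigma = 1)
  res <- train_gcn(g, gcn_config(max_epochs = 10, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_gcn(res, path)
  back <- load_gcn(path)
  expect_identical(back$probabilities, res$probabilities)
  expect_identical(back$model$W, res$model$W)

  saveRDS(list(format = "other"), path)
  expect_error(load_gcn(path), "not a recognized checkpoint")
})
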