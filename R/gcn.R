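#' GCN configuration
#'
#' Hyperparameters of the semi-supervised graph convolutional classifier.
#' Defaults reproduce the configuration that performed best in the motivating
#' study: 3 graph learning blocks of 128 graph convolutional filters, weighted
#' cross-entropy, Adam at learning rate 0.01 with decay rates (0.9, 0.999),
#' and a maximal epoch of 2000. The number of layers is searched over
#' 1-4 and the filter count over {512, 256, 128, 64, 32, 16} in the
#' hyperparameter sweep.
#'
#' @param n_layers Number of graph learning blocks (1-4).
#' @param n_filters Width of the hidden graph convolutional layers.
#' @param dropout_rate Dropout probability inside hidden blocks, in \[0, 1).
#' @param learning_rate Adam step size.
#' @param adam_beta1,adam_beta2 Adam first/second moment decay rates.
#' @param max_epochs Number of full-graph training epochs.
#' @param loss `"weighted"` (inverse-frequency class weights) or
#'   `"unweighted"`.
#' @param seed Integer seed controlling weight initialization and dropout.
#' @param bn_momentum Running-moment update rate of the batch-norm layers.
#' @param bn_eps Batch-norm variance floor.
#' @return An object of class `gcn_config`.
#' @export
gcn_config <- function(n_layers = 3, n_filters = 128, dropout_rate = 0.5,
                       learning_rate = 0.01, adam_beta1 = 0.9,
                       adam_beta2 = 0.999, max_epochs = 2000,
                       loss = c("weighted", "unweighted"), seed = 1L,
                       bn_momentum = 0.1, bn_eps = 1e-5) {
  loss <- match.arg(loss)
  n_layers <- as.integer(n_layers)
  if (!n_layers %in% 1:4) stop_user("n_layers must be in 1..4")
  if (n_filters < 1) stop_user("n_filters must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_user("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop_user("learning_rate must be positive")
  if (max_epochs < 1) stop_user("max_epochs must be positive")
  structure(list(n_layers = n_layers, n_filters = as.integer(n_filters),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 max_epochs = as.integer(max_epochs), loss = loss,
                 seed = as.integer(seed), bn_momentum = bn_momentum,
                 bn_eps = bn_eps),
            class = "gcn_config")
}

glorot_uniform <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# Layer widths: M -> k -> ... -> k -> 2 (2 output channels feed the softmax).
gcn_dims <- function(config, n_features) {
  L <- config$n_layers
  ins <- c(n_features, rep(config$n_filters, L - 1L))
  outs <- c(rep(config$n_filters, L - 1L), 2L)
  list(ins = ins[seq_len(L)], outs = outs)
}

# Initialize weights and identity batch-norm state. Consumes RNG.
init_gcn <- function(config, n_features) {
  d <- gcn_dims(config, n_features)
  L <- config$n_layers
  W <- vector("list", L)
  bn <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- glorot_uniform(d$ins[l], d$outs[l])
    bn[[l]] <- list(gamma = rep(1, d$outs[l]), beta = rep(0, d$outs[l]),
                    running_mean = rep(0, d$outs[l]),
                    running_var = rep(1, d$outs[l]))
  }
  structure(list(config = config, W = W, bn = bn, n_features = n_features),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  d <- gcn_dims(x$config, x$n_features)
  cat(sprintf("<gcn_model> %d graph learning blocks: %s\n", x$config$n_layers,
              paste(sprintf("%d->%d", d$ins, d$outs), collapse = ", ")))
  invisible(x)
}

bn_forward <- function(Z, st, eps, training, momentum) {
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(sweep(Z, 2, mu)^2)   # population variance over the node batch
    if (momentum >= 1) {                # calibration pass: store stats exactly
      st$running_mean <- mu
      st$running_var <- va
    } else {
      st$running_mean <- (1 - momentum) * st$running_mean + momentum * mu
      st$running_var <- (1 - momentum) * st$running_var + momentum * va
    }
  } else {
    mu <- st$running_mean
    va <- st$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(Z, 2, mu), 2, invstd, `*`)
  out <- sweep(sweep(xhat, 2, st$gamma, `*`), 2, st$beta, `+`)
  list(out = out, xhat = xhat, invstd = invstd, state = st)
}

# Batch-norm backward over the full node batch (training-mode statistics).
bn_backward <- function(dY, xhat, invstd, gamma) {
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  n <- nrow(dY)
  t1 <- sweep(dY, 2, dbeta / n)
  t2 <- sweep(xhat, 2, dgamma / n, `*`)
  dZ <- sweep(t1 - t2, 2, gamma * invstd, `*`)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' GCN forward pass
#'
#' Applies the stacked graph learning blocks to the whole cohort graph. Each
#' of the first L-1 blocks computes S H W (the renormalized propagation rule)
#' followed by batch normalization, ReLU, and (in training mode) dropout; the
#' final block computes S H W to 2 output channels, batch normalization, and
#' a row-wise softmax, so each node receives class probabilities summing
#' to 1. In evaluation mode batch norm uses its running moments and dropout
#' is disabled. Training mode consumes RNG draws for the dropout masks.
#'
#' @param model A `gcn_model`.
#' @param graph A `population_graph` (its `S` and `X` are used).
#' @param training Logical; training mode as described above.
#' @param calibrate Internal: dropout-free pass that normalizes with the
#'   current full-batch statistics and stores them as the running moments
#'   (batch-norm recalibration after training).
#' @param keep_cache Internal: retain intermediates for backpropagation.
#' @return N x 2 matrix of class probabilities (columns: negative, positive);
#'   with `keep_cache = TRUE`, a list `(probs, cache, model)`.
#' @export
gcn_forward <- function(model, graph, training = FALSE, calibrate = FALSE,
                        keep_cache = FALSE) {
  cfg <- model$config
  L <- cfg$n_layers
  S <- graph$S
  H <- graph$X
  cache <- if (keep_cache) vector("list", L) else NULL
  momentum <- if (calibrate) 1 else cfg$bn_momentum
  for (l in seq_len(L)) {
    SH <- S %*% H
    Z <- SH %*% model$W[[l]]
    bnf <- bn_forward(Z, model$bn[[l]], cfg$bn_eps, training || calibrate,
                      momentum)
    if (training || calibrate) model$bn[[l]] <- bnf$state
    if (l < L) {
      act <- pmax(bnf$out, 0)
      if (training && cfg$dropout_rate > 0) {
        mask <- matrix(stats::runif(length(act)) >= cfg$dropout_rate,
                       nrow(act), ncol(act))
        Hnext <- act * mask / (1 - cfg$dropout_rate)
      } else {
        mask <- NULL
        Hnext <- act
      }
    } else {
      mask <- NULL
      Hnext <- row_softmax(bnf$out)
    }
    if (keep_cache) {
      cache[[l]] <- list(SH = SH, xhat = bnf$xhat, invstd = bnf$invstd,
                         bn_out = bnf$out, drop_mask = mask)
    }
    H <- Hnext
  }
  probs <- H
  colnames(probs) <- c("negative", "positive")
  if (keep_cache || calibrate) list(probs = probs, cache = cache, model = model) else probs
}

# Inverse-frequency class weights on the training mask: beta_c = N_mask / C_c.
class_weights <- function(labels, mask, mode) {
  y <- labels[mask]
  if (any(is.na(y))) stop_user("training mask selects a node with a missing label")
  n <- length(y)
  if (mode == "unweighted") return(c(neg = 1, pos = 1))
  c_pos <- sum(y == 1L)
  c_neg <- n - c_pos
  if (c_pos == 0L || c_neg == 0L) {
    stop_user("cannot fit inverse-frequency weights: training mask holds a single class")
  }
  c(neg = n / c_neg, pos = n / c_pos)
}

#' Masked (weighted) binary cross-entropy
#'
#' Mean over the masked nodes of the class-weighted binary cross-entropy
#' -beta_i \[y_i log p_i + (1 - y_i) log(1 - p_i)\], where p_i is the
#' positive-class probability. In `"weighted"` mode beta_i = N/C_class(i) by
#' the inverse frequency method, with N and the class counts C computed on
#' the training mask only; in `"unweighted"` mode beta_i = 1. Probabilities
#' are clamped to \[1e-12, 1 - 1e-12\] inside the logarithm.
#'
#' @param probabilities N x 2 matrix (columns negative, positive).
#' @param labels Integer vector (1 positive, 0 negative, NA unlabeled).
#' @param train_mask Logical vector selecting the labeled training nodes.
#' @param mode `"weighted"` or `"unweighted"`.
#' @return Scalar loss.
#' @export
weighted_loss <- function(probabilities, labels, train_mask,
                          mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (!any(train_mask)) stop_user("empty training mask")
  beta <- class_weights(labels, train_mask, mode)
  y <- labels[train_mask]
  p <- pmin(pmax(probabilities[train_mask, 2L], 1e-12), 1 - 1e-12)
  b <- ifelse(y == 1L, beta[["pos"]], beta[["neg"]])
  mean(-b * (y * log(p) + (1 - y) * log(1 - p)))
}

adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

adam_step <- function(param, grad, st, lr, b1, b2, t, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Train the semi-supervised GCN
#'
#' Masked transductive training: every epoch the whole cohort graph (all
#' labeled, unlabeled, and test nodes) is passed through the network, but the
#' loss — weighted or plain binary cross-entropy — is computed on the
#' `train_labeled` mask only. Unlabeled and test nodes therefore shape the
#' graph convolutions through their features while contributing no label
#' information. Optimization is full-batch Adam; gradients are obtained by
#' exact backpropagation through the graph convolutions, batch-norm layers,
#' ReLU, and dropout. After the last epoch the batch-norm statistics are
#' recalibrated exactly under the final weights with a dropout-free pass
#' (full-batch training leaves the running moments one EMA window behind the
#' still-moving batch statistics, and that small lag is amplified across
#' wide layers into the logits). Deterministic given `config$seed` (which
#' drives the Glorot initialization and the dropout masks).
#'
#' @param graph A `population_graph` whose `train_labeled` mask contains both
#'   classes.
#' @param config A `gcn_config`.
#' @return An object of class `gcn_training_result`: `model` (weights plus
#'   batch-norm running moments), `loss_trajectory` (one value per epoch),
#'   `probabilities` (N x 2 evaluation-mode class probabilities on the full
#'   graph) and `node_ids`.
#' @export
train_gcn <- function(graph, config = gcn_config()) {
  stopifnot(inherits(graph, "population_graph"), inherits(config, "gcn_config"))
  mask <- graph$masks$train_labeled
  beta <- class_weights(graph$labels, mask, config$loss)   # validates mask
  with_seed(config$seed, {
    model <- init_gcn(config, ncol(graph$X))
    L <- config$n_layers
    d <- gcn_dims(config, ncol(graph$X))
    opt_W <- adam_state(lapply(seq_len(L), function(l) c(d$ins[l], d$outs[l])))
    opt_g <- adam_state(lapply(d$outs, function(o) o))
    opt_b <- adam_state(lapply(d$outs, function(o) o))
    nm <- sum(mask)
    y <- graph$labels
    Y <- cbind(ifelse(mask & y == 1L & !is.na(y), 0, 1),
               ifelse(mask & y == 1L & !is.na(y), 1, 0))
    bvec <- numeric(length(mask))
    bvec[mask] <- ifelse(y[mask] == 1L, beta[["pos"]], beta[["neg"]])
    S <- graph$S
    trajectory <- numeric(config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      fw <- gcn_forward(model, graph, training = TRUE, keep_cache = TRUE)
      model <- fw$model                       # batch-norm running moments
      trajectory[epoch] <- weighted_loss(fw$probs, y, mask, config$loss)
      # softmax + cross-entropy gradient w.r.t. the final batch-norm output
      dU <- (fw$probs - Y) * (bvec / nm)
      dU[!mask, ] <- 0
      for (l in rev(seq_len(L))) {
        cc <- fw$cache[[l]]
        if (l < L) {
          dU <- dU * (cc$bn_out > 0)          # ReLU
        }
        bb <- bn_backward(dU, cc$xhat, cc$invstd, model$bn[[l]]$gamma)
        dW <- crossprod(cc$SH, bb$dZ)
        if (l > 1L) {
          dH <- S %*% tcrossprod(bb$dZ, model$W[[l]])
          pc <- fw$cache[[l - 1L]]
          if (!is.null(pc$drop_mask)) {
            dH <- dH * pc$drop_mask / (1 - config$dropout_rate)
          }
          dU <- dH
        }
        st <- adam_step(model$W[[l]], dW, opt_W[[l]], config$learning_rate,
                        config$adam_beta1, config$adam_beta2, epoch)
        model$W[[l]] <- st$param; opt_W[[l]] <- st$state
        st <- adam_step(model$bn[[l]]$gamma, bb$dgamma, opt_g[[l]],
                        config$learning_rate, config$adam_beta1,
                        config$adam_beta2, epoch)
        model$bn[[l]]$gamma <- as.numeric(st$param); opt_g[[l]] <- st$state
        st <- adam_step(model$bn[[l]]$beta, bb$dbeta, opt_b[[l]],
                        config$learning_rate, config$adam_beta1,
                        config$adam_beta2, epoch)
        model$bn[[l]]$beta <- as.numeric(st$param); opt_b[[l]] <- st$state
      }
    }
    # recalibrate batch-norm statistics exactly under the final weights
    # (dropout-free pass), then evaluate
    cal <- gcn_forward(model, graph, calibrate = TRUE)
    model <- cal$model
    probs <- gcn_forward(model, graph, training = FALSE)
    structure(list(model = model, loss_trajectory = trajectory,
                   probabilities = probs, node_ids = graph$node_ids),
              class = "gcn_training_result")
  })
}

#' @export
print.gcn_training_result <- function(x, ...) {
  cat(sprintf("<gcn_training_result> %d nodes, %d epochs, final loss %.4f\n",
              nrow(x$probabilities), length(x$loss_trajectory),
              x$loss_trajectory[length(x$loss_trajectory)]))
  invisible(x)
}

#' Predict node labels from a training result
#'
#' Returns, for the selected nodes, the argmax class label (a tie at
#' probability 0.5 is resolved as positive, the high-risk class) and the
#' positive-class probability used for ROC analysis.
#'
#' @param result A `gcn_training_result`.
#' @param node_mask Logical vector over graph nodes, node indices, or subject
#'   ids; default all nodes.
#' @return `data.frame` with `subject_id`, `probability_positive`, `label`.
#' @export
predict_gcn <- function(result, node_mask = NULL) {
  n <- nrow(result$probabilities)
  idx <- if (is.null(node_mask)) {
    seq_len(n)
  } else if (is.logical(node_mask)) {
    if (length(node_mask) != n) stop_user("mask length %d != %d nodes", length(node_mask), n)
    which(node_mask)
  } else if (is.character(node_mask)) {
    i <- match(node_mask, result$node_ids)
    if (any(is.na(i))) stop_user("unknown subject ids in node_mask")
    i
  } else {
    as.integer(node_mask)
  }
  p <- result$probabilities[idx, 2L]
  data.frame(subject_id = result$node_ids[idx],
             probability_positive = as.numeric(p),
             label = ifelse(p >= 0.5, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Save / load a GCN checkpoint
#'
#' A checkpoint is a single serialized file holding the format version, the
#' configuration, and all trained parameters (filter weights and batch-norm
#' state); `load_gcn` refuses versions it does not know.
#'
#' @param result A `gcn_training_result` (or bare `gcn_model`).
#' @param path Checkpoint file path.
#' @return `save_gcn` invisibly returns `path`; `load_gcn` the restored object.
#' @export
save_gcn <- function(result, path) {
  obj <- list(format = "cohortgcn-checkpoint", version = 1L, payload = result)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_gcn
#' @export
load_gcn <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cohortgcn-checkpoint") || !identical(obj$version, 1L)) {
    stop_user("not a recognized checkpoint: %s", path)
  }
  obj$payload
}

#' Write a per-epoch training log
#'
#' @param result A `gcn_training_result`.
#' @param path CSV output path (`epoch,loss`).
#' @return Invisibly, `path`.
#' @export
write_training_log <- function(result, path) {
  utils::write.csv(data.frame(epoch = seq_along(result$loss_trajectory),
                              loss = result$loss_trajectory),
                   path, row.names = FALSE)
  invisible(path)
}
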