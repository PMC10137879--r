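# Shared fixtures and independent oracles, built in code at test time.

# Random symmetric connectivity matrix with zero diagonal, entries in [0, 1].
random_symmetric <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Brute-force strict-upper-triangle vectorization: double loop, row-major.
brute_vectorize <- function(m) {
  n <- nrow(m)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) out <- c(out, m[i, j])
  }
  out
}

# Brute-force pairwise kernel adjacency via edge_weight on every pair.
brute_adjacency <- function(X, sigma) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) A[i, j] <- edge_weight(X[i, ], X[j, ], sigma)
  }
  A
}

# Per-node brute-force GCN forward in evaluation mode: explicit neighbor sums,
# no matrix products. Mirrors the layer definition from first principles.
brute_forward_eval <- function(model, S, X) {
  cfg <- model$config
  L <- cfg$n_layers
  N <- nrow(X)
  H <- X
  for (l in seq_len(L)) {
    W <- model$W[[l]]
    Fk <- ncol(W)
    Z <- matrix(0, N, Fk)
    for (i in seq_len(N)) {
      agg <- numeric(ncol(H))
      for (j in seq_len(N)) agg <- agg + S[i, j] * H[j, ]
      for (f in seq_len(Fk)) Z[i, f] <- sum(agg * W[, f])
    }
    bn <- model$bn[[l]]
    out <- matrix(0, N, Fk)
    for (f in seq_len(Fk)) {
      out[, f] <- bn$gamma[f] * (Z[, f] - bn$running_mean[f]) /
        sqrt(bn$running_var[f] + cfg$bn_eps) + bn$beta[f]
    }
    if (l < L) {
      H <- pmax(out, 0)
    } else {
      H <- t(apply(out, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    }
  }
  H
}

# All-pairs AUC oracle: fraction of (positive, negative) pairs ranked
# correctly, ties counted half.
brute_auc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Tiny labeled cohort with a strong class signal, for fast end-to-end runs.
separable_cohort <- function(seed = 1, n_labeled = 40, n_unlabeled = 10,
                             n_rois = 10) {
  generate_cohort(synthetic_spec(
    n_labeled = n_labeled, n_unlabeled = n_unlabeled, n_rois = n_rois,
    prevalence = 0.4, effect_size = 0.5, affected_fraction = 0.3,
    noise_sd = 0.05, seed = seed))
}

# Stratified single train/test split of a cohort's labeled subjects.
split_labeled <- function(manifest, frac = 0.5, seed = 1) {
  ids <- manifest$subject_id[manifest$label != "unlabeled"]
  cls <- manifest$label[manifest$label != "unlabeled"]
  set.seed(seed)
  test <- unlist(lapply(unique(cls), function(k) {
    pool <- ids[cls == k]
    sample(pool, floor(length(pool) * frac))
  }))
  list(test = test, train = setdiff(ids, test))
}
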