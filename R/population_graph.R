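#' Gaussian similarity between two feature vectors
#'
#' The cohort-graph edge weight between subjects i and j is a decreasing
#' kernel of the Euclidean distance d between their vectorized connectomes:
#' `gaussian` (default) gives W = exp(-d^2 / (2 sigma^2)); the
#' `exp_distance` variant gives W = exp(-d / (2 sigma^2)). Both are 1 when
#' the features coincide and decay to 0 as d grows; `sigma` controls the
#' decay scale (for the gaussian kernel, W = 0.5 at d = sigma * sqrt(2 ln 2)).
#'
#' @param f_i,f_j Numeric feature vectors of equal length (or
#'   `feature_vector` objects).
#' @param sigma Positive kernel coefficient.
#' @param kernel `"gaussian"` or `"exp_distance"`.
#' @return Edge weight in (0, 1\].
#' @export
edge_weight <- function(f_i, f_j, sigma, kernel = c("gaussian", "exp_distance")) {
  kernel <- match.arg(kernel)
  if (inherits(f_i, "feature_vector")) f_i <- f_i$values
  if (inherits(f_j, "feature_vector")) f_j <- f_j$values
  if (length(f_i) != length(f_j)) {
    stop_user("feature vectors differ in length: %d vs %d",
              length(f_i), length(f_j))
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop_user("sigma must be a single positive number")
  }
  d <- sqrt(sum((f_i - f_j)^2))
  if (kernel == "gaussian") exp(-d^2 / (2 * sigma^2)) else exp(-d / (2 * sigma^2))
}

# Dense kernel adjacency from a feature matrix; zero diagonal.
kernel_adjacency <- function(X, sigma, kernel = "gaussian") {
  D <- as.matrix(stats::dist(X))
  A <- if (kernel == "gaussian") exp(-D^2 / (2 * sigma^2)) else exp(-D / (2 * sigma^2))
  diag(A) <- 0
  dimnames(A) <- NULL
  A
}

#' Renormalized propagation operator
#'
#' Computes S = D~^(-1/2) (A + I) D~^(-1/2), where D~ is the diagonal degree
#' matrix of A~ = A + I. This is the first-order renormalized approximation
#' to spectral graph convolution; every eigenvalue of S lies in \[-1, 1\],
#' and with A = 0 (isolated nodes, self-loops only) S is the identity.
#'
#' @param A Symmetric non-negative adjacency matrix with zero diagonal.
#' @return Symmetric matrix S of the same dimension.
#' @export
propagation_operator <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop_user("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-10) stop_user("adjacency must be symmetric")
  if (any(A < 0)) stop_user("adjacency must be non-negative")
  At <- A
  diag(At) <- diag(At) + 1       # self-connections contribute exactly 1
  dinv <- 1 / sqrt(rowSums(At))
  S <- At * tcrossprod(dinv)
  (S + t(S)) / 2
}

#' Build the weighted cohort graph
#'
#' Assembles the population graph for transductive learning: one node per
#' subject carrying its vectorized connectome as features, fully connected
#' with Gaussian-kernel edge weights on the pairwise Euclidean distances (no
#' sparsification), plus the renormalized propagation operator and the
#' train/test/unlabeled node masks derived from the manifest.
#'
#' @param connectomes List of `connectome` objects (or an N x M numeric
#'   feature matrix whose rownames are subject ids).
#' @param manifest `cohort_manifest` aligned with `connectomes` by subject id.
#' @param sigma Positive kernel coefficient (1.6 by default, the value at
#'   which the cohort graph performed best in the motivating study).
#' @param kernel Kernel form, see [edge_weight()].
#' @param standardize If TRUE, z-score each feature column before computing
#'   distances (default FALSE: mean-FA weights are already on a common
#'   \[0, 1\] scale).
#' @param test_ids Subject ids forming the held-out labeled test set; the
#'   remaining labeled subjects become the training mask.
#' @return An object of class `population_graph` with fields `X`, `A`, `S`,
#'   `sigma`, `node_ids`, `labels` (1 positive / 0 negative / NA unlabeled)
#'   and logical `masks` (`train_labeled`, `test_labeled`, `unlabeled`).
#' @export
build_graph <- function(connectomes, manifest, sigma = 1.6,
                        kernel = c("gaussian", "exp_distance"),
                        standardize = FALSE, test_ids = character(0)) {
  kernel <- match.arg(kernel)
  if (is.matrix(connectomes)) {
    X <- connectomes
  } else {
    X <- feature_matrix(connectomes)
  }
  if (nrow(X) < 2L) stop_user("need at least 2 subjects to build a graph")
  ids <- rownames(X)
  if (is.null(ids)) stop_user("feature matrix must carry subject ids as rownames")
  if (!setequal(ids, manifest$subject_id) || !identical(ids, manifest$subject_id)) {
    extra <- setdiff(ids, manifest$subject_id)
    miss <- setdiff(manifest$subject_id, ids)
    stop_user("connectomes and manifest ids disagree (only in connectomes: %s; only in manifest: %s)",
              paste(utils::head(extra, 3), collapse = ",") %||% "",
              paste(utils::head(miss, 3), collapse = ","))
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_user("sigma must be a single positive number")
  }
  Xd <- if (standardize) {
    sds <- apply(X, 2, stats::sd)
    scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  } else X
  A <- kernel_adjacency(Xd, sigma, kernel)
  S <- propagation_operator(A)
  labels <- ifelse(manifest$label == "positive", 1L,
                   ifelse(manifest$label == "negative", 0L, NA_integer_))
  unlabeled <- manifest$label == "unlabeled"
  test_labeled <- ids %in% test_ids & !unlabeled
  if (length(test_ids) && !all(test_ids %in% ids[!unlabeled])) {
    stop_user("test_ids contain ids that are not labeled graph nodes: %s",
              paste(setdiff(test_ids, ids[!unlabeled]), collapse = ", "))
  }
  train_labeled <- !unlabeled & !test_labeled
  structure(list(X = unname(X), A = A, S = S, sigma = sigma, kernel = kernel,
                 node_ids = ids, labels = labels,
                 masks = list(train_labeled = train_labeled,
                              test_labeled = test_labeled,
                              unlabeled = unlabeled)),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("<population_graph> %d nodes x %d features, sigma = %g (%s kernel)\n",
              nrow(x$X), ncol(x$X), x$sigma, x$kernel))
  cat(sprintf("  masks: %d train-labeled, %d test-labeled, %d unlabeled\n",
              sum(x$masks$train_labeled), sum(x$masks$test_labeled),
              sum(x$masks$unlabeled)))
  invisible(x)
}

# Replace the test/train partition of labeled nodes without rebuilding A/S.
set_graph_masks <- function(graph, test_ids) {
  unl <- graph$masks$unlabeled
  test <- graph$node_ids %in% test_ids & !unl
  if (length(test_ids) && sum(test) != length(test_ids)) {
    stop_user("test_ids contain ids that are not labeled graph nodes")
  }
  graph$masks$test_labeled <- test
  graph$masks$train_labeled <- !unl & !test
  graph
}

#' Export a population graph for inspection
#'
#' Writes the adjacency matrix as CSV, the edge list as TSV
#' (`node_i<TAB>node_j<TAB>weight`, upper-triangle pairs), and the node table
#' (id, label, one column per mask) as CSV.
#'
#' @param graph A `population_graph`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
export_graph <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(graph$A, file.path(dir, "adjacency.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  ut <- which(upper.tri(graph$A), arr.ind = TRUE)
  edges <- data.frame(node_i = graph$node_ids[ut[, 1]],
                      node_j = graph$node_ids[ut[, 2]],
                      weight = graph$A[ut])
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  nodes <- data.frame(subject_id = graph$node_ids, label = graph$labels,
                      train_labeled = graph$masks$train_labeled,
                      test_labeled = graph$masks$test_labeled,
                      unlabeled = graph$masks$unlabeled)
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  invisible(dir)
}
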