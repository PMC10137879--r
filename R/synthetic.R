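#' Specification of a synthetic connectome cohort
#'
#' Describes a cohort with the statistical structure the pipeline assumes: a
#' partially labeled set of subjects (defaults: 119 labeled, 105 unlabeled,
#' matching the motivating cohort), 90-ROI symmetric connectomes with
#' mean-FA-scale weights in \[0, 1\], a ~1:2 positive:negative class ratio
#' (prevalence 37/119), class-dependent mean shifts on a fixed subset of
#' edges, and standardized motor scores (mean 100, SD 15, clipped to
#' \[40, 160\]) whose class-conditional means differ by `score_class_gap`.
#'
#' `effect_size`, `affected_fraction` and `noise_sd` have no real-cohort
#' analogue; the defaults are calibrated once so that labeled-only
#' cross-validated AUC lands in the 0.6-0.8 range typical of connectome-based
#' outcome prediction, and are not tuned per experiment.
#'
#' @param n_labeled,n_unlabeled Cohort composition.
#' @param n_rois Parcellation size (matrix dimension).
#' @param prevalence Positive-class probability among labeled (and latent
#'   among unlabeled) subjects.
#' @param effect_size Class mean shift on affected edges, FA units.
#' @param affected_fraction Fraction of edges carrying class signal, in (0,1\].
#' @param noise_sd Per-edge Gaussian noise SD, FA units (for the manifold
#'   generator, the 2-D cluster noise SD).
#' @param score_mean,score_sd Normative motor-score distribution.
#' @param score_class_gap Reduction of the positive class's mean score.
#' @param manifold_scale Feature-space size of the manifold generator's
#'   clusters (see [generate_manifold_cohort()]).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_labeled = 119, n_unlabeled = 105, n_rois = 90,
                           prevalence = 37 / 119, effect_size = 0.007,
                           affected_fraction = 0.1, noise_sd = 0.04,
                           score_mean = 100, score_sd = 15,
                           score_class_gap = 30, manifold_scale = 1,
                           seed = 1L) {
  if (n_labeled < 2) stop_user("need at least 2 labeled subjects")
  if (n_unlabeled < 0) stop_user("n_unlabeled must be non-negative")
  if (n_rois < 3) stop_user("n_rois must be at least 3")
  if (prevalence <= 0 || prevalence >= 1) stop_user("prevalence must be in (0,1)")
  if (effect_size < 0) stop_user("effect_size must be non-negative")
  if (affected_fraction <= 0 || affected_fraction > 1) {
    stop_user("affected_fraction must be in (0,1]")
  }
  if (noise_sd <= 0) stop_user("noise_sd must be positive")
  structure(list(n_labeled = as.integer(n_labeled),
                 n_unlabeled = as.integer(n_unlabeled),
                 n_rois = as.integer(n_rois), prevalence = prevalence,
                 effect_size = effect_size,
                 affected_fraction = affected_fraction, noise_sd = noise_sd,
                 score_mean = score_mean, score_sd = score_sd,
                 score_class_gap = score_class_gap,
                 manifold_scale = manifold_scale, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate standardized motor scores
#'
#' Draws scores from Normal(`score_mean` - `score_class_gap` * class,
#' `score_sd`) and clips them to the 40-160 scale of standardized motor
#' composites. At the normative defaults (mean 100, SD 15) the clip bounds
#' sit 4 SD from the mean, so clipping is negligible.
#'
#' @param n Number of scores (ignored when `class` has length > 1).
#' @param class 0/1 vector (or scalar) of class indicators.
#' @param score_mean,score_sd,score_class_gap See [synthetic_spec()].
#' @param seed Optional seed; when NULL, draws from the current RNG stream.
#' @return Numeric vector of scores in \[40, 160\].
#' @export
simulate_motor_scores <- function(n, class = 0, score_mean = 100,
                                  score_sd = 15, score_class_gap = 0,
                                  seed = NULL) {
  if (length(class) > 1L) n <- length(class)
  draw <- function() {
    s <- stats::rnorm(n, score_mean - score_class_gap * class, score_sd)
    pmin(pmax(s, 40), 160)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Shared plumbing: subject ids, latent classes, scores, manifest assembly.
cohort_skeleton <- function(spec) {
  n <- spec$n_labeled + spec$n_unlabeled
  ids <- sprintf("sub%04d", seq_len(n))
  labeled <- c(rep(TRUE, spec$n_labeled), rep(FALSE, spec$n_unlabeled))
  class <- stats::rbinom(n, 1L, spec$prevalence)
  scores <- simulate_motor_scores(n, class, spec$score_mean, spec$score_sd,
                                  spec$score_class_gap)
  manifest <- cohort_manifest(
    subject_id = ids,
    motor_score = ifelse(labeled, scores, NA_real_),
    label = ifelse(labeled, ifelse(class == 1L, "positive", "negative"),
                   "unlabeled"))
  list(ids = ids, labeled = labeled, class = class, manifest = manifest, n = n)
}

#' Generate a synthetic partially labeled connectome cohort
#'
#' Emulates the data structure the method consumes, with no real data
#' involved. A base symmetric mean connectome is drawn once per cohort (edge
#' means 0.1 + 0.7 Beta(3, 3), a beta-like distribution kept away from the
#' \[0, 1\] bounds so clipping is rare); each subject's connectome is the
#' base plus a class-specific shift of `effect_size` on a fixed random
#' `affected_fraction` of edges plus symmetric Gaussian edge noise, clipped
#' to \[0, 1\]. Classes are drawn with probability `prevalence` (unlabeled
#' subjects carry a latent class that shapes their features only); motor
#' scores are drawn conditional on class and withheld for the unlabeled
#' subjects. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `connectomes` (list of `connectome`), `manifest`
#'   (`cohort_manifest`) and `truth` (per-subject generating class, for
#'   recovery checks).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    sk <- cohort_skeleton(spec)
    M <- spec$n_rois * (spec$n_rois - 1L) / 2L
    base <- 0.1 + 0.7 * stats::rbeta(M, 3, 3)
    n_aff <- max(1L, round(spec$affected_fraction * M))
    affected <- sample.int(M, n_aff)
    connectomes <- vector("list", sk$n)
    for (i in seq_len(sk$n)) {
      v <- base + stats::rnorm(M, 0, spec$noise_sd)
      if (sk$class[i] == 1L) v[affected] <- v[affected] + spec$effect_size
      v <- pmin(pmax(v, 0), 1)
      connectomes[[i]] <- matricize(v, spec$n_rois, sk$ids[i])
    }
    list(connectomes = connectomes, manifest = sk$manifest, truth = sk$class)
  })
}

#' Generate a two-manifold cohort where unlabeled data helps
#'
#' Construction for studying the semi-supervised gain: subjects lie on two
#' elongated parallel clusters embedded in connectome feature space, long
#' (3 `manifold_scale` feature-space units along a fixed direction u1) and
#' thin (Gaussian thickness `noise_sd`), separated by 0.5 `manifold_scale`
#' along an orthogonal direction u2. A handful of labeled subjects scattered
#' along the clusters under-determine the boundary — their chance positions
#' along the elongation axis tilt any boundary fitted from labels alone —
#' while the many unlabeled subjects trace the cluster shape densely, so a
#' transductive model that sees unlabeled features can smooth predictions
#' along each cluster. Each subject's 2-D coordinate is mapped into the
#' upper-triangle feature space along u1/u2, added to a base connectome near
#' 0.5, and clipped to \[0, 1\]. With `n_unlabeled = 0` this reduces to a
#' plain supervised two-cluster problem.
#'
#' @param spec A [synthetic_spec()]; `prevalence` sets the probability of the
#'   second cluster (the positive class), `noise_sd` the cluster thickness.
#' @return As [generate_cohort()].
#' @export
generate_manifold_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    sk <- cohort_skeleton(spec)
    M <- spec$n_rois * (spec$n_rois - 1L) / 2L
    if (M < 3L) stop_user("n_rois too small for the manifold embedding")
    base <- 0.3 + 0.4 * stats::rbeta(M, 4, 4)
    # fixed orthonormal embedding directions
    u1 <- stats::rnorm(M); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- stats::rnorm(M); u2 <- u2 - sum(u2 * u1) * u1
    u2 <- u2 / sqrt(sum(u2^2))
    t <- stats::runif(sk$n)
    ms <- spec$manifold_scale
    x <- ms * 1.5 * (2 * t - 1)
    ycoord <- ms * 0.25 * ifelse(sk$class == 1L, 1, -1) +
      stats::rnorm(sk$n, 0, spec$noise_sd)
    connectomes <- vector("list", sk$n)
    for (i in seq_len(sk$n)) {
      v <- base + x[i] * u1 + ycoord[i] * u2
      v <- pmin(pmax(v, 0), 1)
      connectomes[[i]] <- matricize(v, spec$n_rois, sk$ids[i])
    }
    list(connectomes = connectomes, manifest = sk$manifest, truth = sk$class)
  })
}
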