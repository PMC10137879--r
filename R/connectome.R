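#' Construct a connectome object
#'
#' A connectome is one subject's square symmetric matrix of structural
#' connectivity weights (for diffusion-derived connectomes, mean fractional
#' anisotropy along the tracts joining each pair of regions, each weight in
#' \[0, 1\]) with a zero diagonal. Text round-trips can break exact symmetry,
#' so matrices symmetric to a relative tolerance of `tol` are symmetrized by
#' averaging with their transpose; larger asymmetries are an error naming the
#' first offending entry pair.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param matrix Square numeric matrix, symmetric within `tol`, finite,
#'   non-negative.
#' @param tol Relative symmetry tolerance (default `1e-8`).
#' @return An object of class `connectome` with elements `subject_id`,
#'   `matrix` (symmetrized, zero diagonal) and `n_rois`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.4
#' conn <- connectome("sub01", m)
#' conn$n_rois
#' @export
connectome <- function(subject_id, matrix, tol = 1e-8) {
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id)) {
    stop_user("subject_id must be a single non-missing string")
  }
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) {
    stop_user("connectome matrix for '%s' is not square: %d x %d",
              subject_id, nrow(m), ncol(m))
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop_user("connectome matrix for '%s' has a non-finite entry at [%d, %d]",
              subject_id, bad[1L], bad[2L])
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop_user("connectome matrix for '%s' has a negative entry at [%d, %d]",
              subject_id, bad[1L], bad[2L])
  }
  asym <- abs(m - t(m))
  scale <- pmax(abs(m), abs(t(m)), 1)
  if (any(asym > tol * scale)) {
    bad <- which(asym > tol * scale, arr.ind = TRUE)
    bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE][1L, ]
    stop_user(paste0("connectome matrix for '%s' is not symmetric: ",
                     "entry [%d, %d] = %g but [%d, %d] = %g"),
              subject_id, bad[1L], bad[2L], m[bad[1L], bad[2L]],
              bad[2L], bad[1L], m[bad[2L], bad[1L]])
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- NULL
  structure(list(subject_id = subject_id, matrix = m, n_rois = nrow(m)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject '%s', %d x %d ROIs, edge weights in [%.3g, %.3g]\n",
              x$subject_id, x$n_rois, x$n_rois,
              min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Vectorize a connectome into its unique connectivity weights
#'
#' Extracts the strict upper triangle of the symmetric connectivity matrix in
#' canonical row-major order (pairs (1,2), (1,3), ..., (1,n), (2,3), ...),
#' giving the n(n-1)/2 unique edge weights that serve as a subject's node
#' feature vector: 4005 features for a 90-ROI parcellation. Zero-valued
#' connections (absent tracts) are retained; they are part of the vector by
#' construction.
#'
#' @param conn A `connectome` object.
#' @return Named list of class `feature_vector` with `subject_id`, `values`
#'   (numeric, length n(n-1)/2) and `n_rois`.
#' @seealso [matricize()] for the inverse.
#' @export
vectorize <- function(conn) {
  if (!inherits(conn, "connectome")) conn <- connectome(conn$subject_id, conn$matrix)
  m <- conn$matrix
  # t(m)[lower.tri(m)] walks the strict upper triangle in row-major order
  values <- t(m)[lower.tri(m)]
  structure(list(subject_id = conn$subject_id, values = values,
                 n_rois = conn$n_rois),
            class = "feature_vector")
}

#' Rebuild a connectome from its feature vector
#'
#' Inverse of [vectorize()]: places the vector back into the strict upper
#' triangle (row-major), mirrors it, and zeroes the diagonal, so
#' `matricize(vectorize(x))` reproduces `x` exactly.
#'
#' @param vec Numeric vector of upper-triangular weights, or a
#'   `feature_vector` object.
#' @param n_rois Number of regions; `length(vec)` must equal
#'   `n_rois * (n_rois - 1) / 2`.
#' @param subject_id Subject identifier (taken from `vec` when it is a
#'   `feature_vector`).
#' @return A `connectome`.
#' @export
matricize <- function(vec, n_rois, subject_id = NULL) {
  if (inherits(vec, "feature_vector")) {
    if (missing(n_rois)) n_rois <- vec$n_rois
    subject_id <- subject_id %||% vec$subject_id
    vec <- vec$values
  }
  subject_id <- subject_id %||% "unnamed"
  n_rois <- as.integer(n_rois)
  expected <- n_rois * (n_rois - 1L) / 2L
  if (length(vec) != expected) {
    stop_user("feature vector length mismatch: expected %d for %d ROIs, got %d",
              expected, n_rois, length(vec))
  }
  m <- matrix(0, n_rois, n_rois)
  tm <- t(m)
  tm[lower.tri(tm)] <- vec
  m <- t(tm)
  m <- m + t(m)
  connectome(subject_id, m)
}

#' Dichotomize a motor score into a risk label
#'
#' Standardized neurodevelopmental motor composites (Bayley-III scale) are
#' normalized to mean 100, SD 15, range 40-160; one standard deviation below
#' the mean (85) is the conventional cutoff for moderate/severe motor
#' abnormality risk. Scores at or below the cutoff are labelled `"positive"`
#' (high risk; the boundary value is positive), scores above it `"negative"`
#' (low risk). Missing scores return `"unlabeled"`, never an error.
#'
#' @param score Numeric vector of motor scores in \[40, 160\] (NA allowed).
#' @param cutoff Dichotomization cutoff (default 85 = 100 - 15).
#' @return Character vector in `c("positive", "negative", "unlabeled")`.
#' @examples
#' dichotomize(c(85, 86, 100, NA))
#' @export
dichotomize <- function(score, cutoff = 85) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L) {
    stop_user("cutoff must be a single number")
  }
  score <- as.numeric(score)
  bad <- !is.na(score) & (score < 40 | score > 160)
  if (any(bad)) {
    stop_user("motor score out of the 40-160 range: %g", score[which(bad)[1L]])
  }
  ifelse(is.na(score), "unlabeled", ifelse(score <= cutoff, "positive", "negative"))
}

valid_labels <- c("positive", "negative", "unlabeled")

#' Construct a cohort manifest
#'
#' The manifest records, per subject, the id, the continuous motor score (or
#' NA for subjects without follow-up), and the class label. `label = "auto"`
#' derives the label from the score via [dichotomize()].
#'
#' @param subject_id Character vector of unique subject ids.
#' @param motor_score Numeric scores in \[40, 160\], NA for missing.
#' @param label Character: `"positive"`, `"negative"`, `"unlabeled"` or
#'   `"auto"`. Default `"auto"`.
#' @param cutoff Cutoff passed to [dichotomize()] when deriving labels.
#' @return A `data.frame` of class `cohort_manifest` with columns
#'   `subject_id`, `motor_score`, `label`.
#' @export
cohort_manifest <- function(subject_id, motor_score = NA_real_, label = "auto",
                            cutoff = 85) {
  subject_id <- as.character(subject_id)
  n <- length(subject_id)
  if (n == 0L) stop_user("manifest has no subjects")
  if (anyDuplicated(subject_id)) {
    stop_user("duplicated subject_id in manifest: '%s'",
              subject_id[duplicated(subject_id)][1L])
  }
  motor_score <- rep_len(as.numeric(motor_score), n)
  label <- rep_len(as.character(label), n)
  auto <- !is.na(label) & label == "auto"
  label[auto] <- dichotomize(motor_score[auto], cutoff)
  label[is.na(label)] <- "unlabeled"
  if (!all(label %in% valid_labels)) {
    stop_user("invalid label '%s' (must be positive/negative/unlabeled/auto)",
              setdiff(label, valid_labels)[1L])
  }
  # explicit labels without a score are allowed; score-less rows that were
  # requested as auto have already become unlabeled above
  df <- data.frame(subject_id = subject_id, motor_score = motor_score,
                   label = label, stringsAsFactors = FALSE)
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' @export
print.cohort_manifest <- function(x, ...) {
  tab <- table(factor(x$label, levels = valid_labels))
  cat(sprintf("<cohort_manifest> %d subjects: %d positive, %d negative, %d unlabeled\n",
              nrow(x), tab[["positive"]], tab[["negative"]], tab[["unlabeled"]]))
  invisible(x)
}

#' Read a cohort from disk
#'
#' Reads a manifest CSV (header `subject_id,motor_score,label`; missing scores
#' as empty fields or `NA`) and one connectivity-matrix CSV per subject
#' (`<subject_id>.csv` in `connectome_dir`: full square matrix, no header,
#' one row per line). Subjects whose matrix file is missing are excluded with
#' a warning naming them.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param connectome_dir Directory holding per-subject matrix CSVs.
#' @param cutoff Dichotomization cutoff for `label = "auto"` rows.
#' @return A list with elements `connectomes` (list of `connectome`) and
#'   `manifest` (`cohort_manifest`), aligned and in manifest order.
#' @export
read_cohort <- function(manifest_path, connectome_dir, cutoff = 85) {
  if (!file.exists(manifest_path)) stop_user("manifest not found: %s", manifest_path)
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"),
                        na.strings = c("NA", ""))
  if (nrow(df) == 0L) stop_user("manifest is empty: %s", manifest_path)
  need <- c("subject_id", "motor_score", "label")
  if (!all(need %in% names(df))) {
    stop_user("manifest must have columns %s", paste(need, collapse = ", "))
  }
  manifest <- cohort_manifest(df$subject_id, df$motor_score, df$label, cutoff)
  paths <- file.path(connectome_dir, paste0(manifest$subject_id, ".csv"))
  present <- file.exists(paths)
  if (!any(present)) stop_user("no connectome files found in %s", connectome_dir)
  if (any(!present)) {
    warning(sprintf("excluding %d subject(s) with no connectome file: %s",
                    sum(!present),
                    paste(manifest$subject_id[!present], collapse = ", ")),
            call. = FALSE)
    manifest <- manifest[present, , drop = FALSE]
    paths <- paths[present]
    class(manifest) <- c("cohort_manifest", "data.frame")
  }
  connectomes <- mapply(function(p, id) {
    m <- as.matrix(utils::read.csv(p, header = FALSE))
    connectome(id, m)
  }, paths, manifest$subject_id, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  list(connectomes = connectomes, manifest = manifest)
}

#' Write a cohort to disk
#'
#' Writes the manifest CSV and one full-square-matrix CSV per subject in the
#' exact formats [read_cohort()] reads, so `read_cohort(write_cohort(x))`
#' round-trips.
#'
#' @param connectomes List of `connectome` objects.
#' @param manifest A `cohort_manifest` aligned with `connectomes`.
#' @param dir Output directory (created if needed); matrices go under
#'   `dir/connectomes/`.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(connectomes, manifest, dir) {
  cdir <- file.path(dir, "connectomes")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(connectomes, function(c) c$subject_id, character(1))
  if (!identical(ids, manifest$subject_id)) {
    stop_user("connectomes and manifest are not aligned by subject_id")
  }
  for (conn in connectomes) {
    utils::write.table(conn$matrix,
                       file.path(cdir, paste0(conn$subject_id, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(as.data.frame(manifest), mpath, row.names = FALSE, na = "")
  invisible(mpath)
}

# Feature matrix (N x M) from a list of connectomes, rows in cohort order.
feature_matrix <- function(connectomes) {
  vecs <- lapply(connectomes, vectorize)
  X <- do.call(rbind, lapply(vecs, function(v) v$values))
  rownames(X) <- vapply(vecs, function(v) v$subject_id, character(1))
  X
}
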