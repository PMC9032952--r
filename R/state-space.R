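#' Build the SVD state-space
#'
#' Thin singular value decomposition `X = U S V'` of the centered
#' normalized matrix (samples x features).  Principal components are
#' `PC = U S` (the sample scores); the rows of `V'` are the feature
#' loadings.  The component that defines the disease axis is chosen later
#' with [select_state_pc()] and oriented with [orient_state_axis()]; until
#' then `state_pc_index = 1` and `orientation_sign = +1`.
#'
#' @param matrix a `normalized_matrix` from [normalize_counts()].
#' @return An object of class `state_space`: `scores` (samples x
#'   components), `singular_values`, `loadings` (components x features),
#'   `feature_means`, `state_pc_index`, `orientation_sign`, `metadata`.
#' @export
fit_state_space <- function(matrix) {
  stopifnot(inherits(matrix, "normalized_matrix"))
  X <- matrix$values
  if (nrow(X) < 2L || ncol(X) < 2L)
    stopf("need at least 2 samples and 2 features")
  sv <- svd(X)
  if (max(sv$d) <= 1e-12 * length(X)) stopf("matrix has rank 0")
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- rownames(X)
  loadings <- t(sv$v)
  colnames(loadings) <- colnames(X)
  structure(list(scores = scores,
                 singular_values = sv$d,
                 loadings = loadings,
                 feature_means = matrix$feature_means,
                 pseudocount = matrix$pseudocount,
                 scale = matrix$scale,
                 state_pc_index = 1L,
                 orientation_sign = 1,
                 metadata = matrix$metadata),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  ve <- x$singular_values^2 / sum(x$singular_values^2)
  cat(sprintf("State-space: %d samples, %d components; state axis = PC%d (%.1f%% variance), sign %+d\n",
              nrow(x$scores), length(x$singular_values), x$state_pc_index,
              100 * ve[x$state_pc_index], x$orientation_sign))
  invisible(x)
}

#' Per-sample state-axis coordinate
#'
#' The chosen-and-oriented disease-axis score of each sample ("PC1" of the
#' state-space, whatever its rank in the SVD).
#'
#' @param space a `state_space`.
#' @return named numeric vector of coordinates.
#' @export
state_coordinate <- function(space) {
  stopifnot(inherits(space, "state_space"))
  stats::setNames(space$orientation_sign * space$scores[, space$state_pc_index],
                  rownames(space$scores))
}

#' Select the disease-axis component by marker correlation
#'
#' Each component's sample scores are regressed against the
#' immunophenotypic marker (Kit-like expression); R-squared is the squared
#' Pearson correlation, computed pairwise-complete.  The chosen component
#' maximizes R-squared; when no component shows any marker association
#' (all R-squared below 0.1) selection falls back to the genotype
#' separation statistic (absolute standardized mean difference) with a
#' warning.
#'
#' @param space a `state_space`.
#' @param marker per-sample marker values (NA allowed for up to 20% of
#'   samples).
#' @param genotype per-sample labels with exactly two levels (e.g. "CM" /
#'   "control"); used for the separation tie-break.
#' @return An object of class `marker_selection`: `r_squared` per
#'   component, `separation` per component, `chosen`.  Apply with
#'   `space$state_pc_index <- sel$chosen` or via [orient_state_axis()].
#' @export
select_state_pc <- function(space, marker, genotype) {
  stopifnot(inherits(space, "state_space"))
  ok <- is.finite(marker)
  if (mean(ok) < 0.8)
    stopf("marker available for %.0f%% of samples; need >= 80%%", 100 * mean(ok))
  if (stats::sd(marker[ok]) == 0) stopf("marker is constant")
  n_comp <- ncol(space$scores)
  r2 <- vapply(seq_len(n_comp), function(k)
    suppressWarnings(stats::cor(marker[ok], space$scores[ok, k]))^2, numeric(1))
  r2[!is.finite(r2)] <- 0
  g <- as.factor(genotype)
  if (nlevels(g) != 2L) stopf("genotype must have exactly two levels")
  sep <- vapply(seq_len(n_comp), function(k) {
    s <- split(space$scores[, k], g)
    sp <- sqrt((stats::var(s[[1]]) + stats::var(s[[2]])) / 2)
    if (sp == 0) 0 else abs(mean(s[[1]]) - mean(s[[2]])) / sp
  }, numeric(1))
  if (max(r2) < 0.1) {
    warnf("no component correlates with the marker (max R^2 = %.3f); falling back to genotype separation", max(r2))
    chosen <- which.max(sep)
  } else {
    top <- which(r2 > max(r2) - 1e-12)
    chosen <- if (length(top) > 1L) top[which.max(sep[top])] else top
  }
  structure(list(r_squared = r2, separation = sep, chosen = as.integer(chosen)),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("Marker selection: chose PC%d (R^2 = %.3f, separation = %.2f)\n",
              x$chosen, x$r_squared[x$chosen], x$separation[x$chosen]))
  invisible(x)
}

#' Orient the disease axis so leukemia is negative
#'
#' Chooses `orientation_sign` so that the mean state-axis score of late CM
#' samples (the final third of each CM mouse's series) is negative
#' relative to the control mean, matching the convention that CM
#' trajectories move toward negative values as mice develop leukemia.  The
#' sign is applied consistently to the score column and the matching
#' loadings row, so the operation is idempotent and involutive.
#'
#' @param space a `state_space`.
#' @param selection optional `marker_selection`; when given,
#'   `state_pc_index` is set to its `chosen` component first.
#' @param genotype,time optional per-sample vectors; defaults are taken
#'   from the space's stored metadata (`genotype`, `time_months`).
#' @return The oriented `state_space` (scores and loadings of the state
#'   component multiplied into the canonical sign; `orientation_sign`
#'   reset to +1 so the stored factors are themselves oriented).
#' @export
orient_state_axis <- function(space, selection = NULL, genotype = NULL,
                              time = NULL) {
  stopifnot(inherits(space, "state_space"))
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "marker_selection"))
    space$state_pc_index <- selection$chosen
  }
  md <- space$metadata
  if (is.null(genotype)) genotype <- md$genotype
  if (is.null(time)) time <- md$time_months
  if (length(unique(genotype)) < 2L) stopf("both genotypes must be present")
  k <- space$state_pc_index
  sc <- space$scores[, k]
  is_cm <- genotype == "CM"
  late <- rep(FALSE, length(sc))
  for (id in unique(md$mouse_id[is_cm])) {
    i <- which(md$mouse_id == id)
    i <- i[order(time[i])]
    start <- ceiling(2 * length(i) / 3) + 1L
    if (start > length(i)) start <- length(i)
    late[i[start:length(i)]] <- TRUE
  }
  if (!any(late)) late <- is_cm # degenerate: single-sample mice
  s <- if (mean(sc[late]) - mean(sc[!is_cm]) > 0) -1 else 1
  space$scores[, k] <- s * space$scores[, k]
  space$loadings[k, ] <- s * space$loadings[k, ]
  space$orientation_sign <- 1
  space
}

#' Project new samples into an existing state-space
#'
#' `scores = X V'` with the training loadings; no refit.  The new matrix
#' must have been transformed with [apply_normalization()] against the
#' training reference, so it is expressed in training feature means.
#'
#' @param space a `state_space`.
#' @param new_matrix a `normalized_matrix` aligned to the training
#'   features.
#' @param min_feature_overlap smallest tolerated fraction of training
#'   features present in the new matrix (default 0.9).
#' @return numeric matrix of projected scores (samples x components).
#' @export
project_samples <- function(space, new_matrix, min_feature_overlap = 0.9) {
  stopifnot(inherits(space, "state_space"),
            inherits(new_matrix, "normalized_matrix"))
  train_feats <- colnames(space$loadings)
  shared <- intersect(train_feats, colnames(new_matrix$values))
  if (length(shared) < min_feature_overlap * length(train_feats))
    stopf("only %d/%d training features present (< %.0f%%)",
          length(shared), length(train_feats), 100 * min_feature_overlap)
  X <- new_matrix$values[, shared, drop = FALSE]
  L <- space$loadings[, shared, drop = FALSE]
  sc <- X %*% t(L)
  rownames(sc) <- rownames(new_matrix$values)
  sc
}

#' Disease-axis coordinates of projected samples
#'
#' Convenience wrapper: project and return the oriented state-axis
#' coordinate only.
#'
#' @inheritParams project_samples
#' @return named numeric vector.
#' @export
project_state_coordinate <- function(space, new_matrix,
                                     min_feature_overlap = 0.9) {
  sc <- project_samples(space, new_matrix, min_feature_overlap)
  stats::setNames(space$orientation_sign * sc[, space$state_pc_index],
                  rownames(sc))
}
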