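#' Expression dataset: counts plus sample metadata
#'
#' The raw material of every stage: a non-negative integer count matrix
#' (samples in rows, features in columns) and a per-sample metadata table
#' with at least `mouse_id`, `genotype`, `time_months` and `status`.
#'
#' @param counts integer matrix, samples x features, with feature column
#'   names; row names are sample ids (taken from `metadata$sample_id` when
#'   absent).
#' @param metadata data.frame with one row per sample.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stopf("counts must have feature column names")
  if (anyDuplicated(colnames(counts))) stopf("feature ids must be unique")
  if (nrow(counts) != nrow(metadata))
    stopf("metadata rows (%d) must match count rows (%d)",
          nrow(metadata), nrow(counts))
  need <- c("sample_id", "mouse_id", "genotype", "time_months", "status")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stopf("metadata lacks columns: %s", paste(miss, collapse = ", "))
  if (any(metadata$time_months < 0)) stopf("time_months must be >= 0")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (is.null(rownames(counts))) rownames(counts) <- metadata$sample_id
  structure(list(counts = counts, metadata = metadata,
                 feature_ids = colnames(counts)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$metadata$genotype)
  cat(sprintf("Expression dataset: %d samples x %d features (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Filter low-count features
#'
#' Keeps features observed with at least `min_count` counts in at least
#' `min_samples` samples, preserving feature order.  Low-abundance
#' features carry little information about the disease axis but
#' destabilize log-space variance.
#'
#' @param dataset an [expression_dataset()].
#' @param min_count,min_samples non-negative thresholds.
#' @return A filtered [expression_dataset()].
#' @export
filter_features <- function(dataset, min_count = 5, min_samples = 3) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (min_count < 0 || min_samples < 0) stopf("thresholds must be >= 0")
  keep <- colSums(dataset$counts >= min_count) >= min_samples
  if (!any(keep))
    stopf("no feature passes the filter (min_count=%g in min_samples=%g)",
          min_count, min_samples)
  expression_dataset(dataset$counts[, keep, drop = FALSE], dataset$metadata)
}

#' Normalize counts to centered log2 counts-per-million
#'
#' Counts are scaled to counts-per-million per sample, transformed with
#' `log2(x + pseudocount)`, and mean-centered per feature.  The training
#' feature means and normalization parameters are stored so that new
#' cohorts can be transformed identically and projected into the same
#' state-space.
#'
#' @param dataset an [expression_dataset()].
#' @param pseudocount positive value added before the log (default 1).
#' @return An object of class `normalized_matrix` with elements `values`
#'   (samples x features, centered), `feature_means`, `pseudocount`,
#'   `scale` (1e6) and `metadata`.
#' @export
normalize_counts <- function(dataset, pseudocount = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  check_number(pseudocount, "pseudocount", lower = .Machine$double.xmin)
  tot <- rowSums(dataset$counts)
  if (any(tot == 0))
    stopf("sample(s) with zero total counts: %s",
          paste(rownames(dataset$counts)[tot == 0], collapse = ", "))
  cpm <- dataset$counts / tot * 1e6
  lg <- log2(cpm + pseudocount)
  mu <- colMeans(lg)
  structure(list(values = sweep(lg, 2, mu),
                 feature_means = mu,
                 pseudocount = pseudocount,
                 scale = 1e6,
                 metadata = dataset$metadata),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("Normalized matrix: %d samples x %d features (log2 CPM + %g, centered)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Apply a reference normalization to new samples
#'
#' Transforms a new cohort with the reference's pseudocount, scale and
#' feature means (no re-centering on the new data), restricting to the
#' intersection of features in the reference's order -- the transformation
#' required before projecting validation samples into a training
#' state-space.
#'
#' @param dataset an [expression_dataset()] of new samples.
#' @param reference a `normalized_matrix` from [normalize_counts()].
#' @return A `normalized_matrix` whose `feature_means` are the reference's
#'   (restricted to shared features).
#' @export
apply_normalization <- function(dataset, reference) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(reference, "normalized_matrix"))
  ref_feats <- names(reference$feature_means)
  shared <- ref_feats[ref_feats %in% colnames(dataset$counts)]
  if (length(shared) == 0L) stopf("no features shared with the reference")
  dropped <- setdiff(colnames(dataset$counts), ref_feats)
  if (length(dropped))
    message(sprintf("apply_normalization: dropping %d feature(s) absent from the reference",
                    length(dropped)))
  tot <- rowSums(dataset$counts) # library size over ALL features, as in training
  if (any(tot == 0)) stopf("sample(s) with zero total counts")
  cpm <- dataset$counts[, shared, drop = FALSE] / tot * reference$scale
  lg <- log2(cpm + reference$pseudocount)
  mu <- reference$feature_means[shared]
  structure(list(values = sweep(lg, 2, mu),
                 feature_means = mu,
                 pseudocount = reference$pseudocount,
                 scale = reference$scale,
                 metadata = dataset$metadata),
            class = "normalized_matrix")
}
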