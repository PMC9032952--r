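#' Angles between components of two state-spaces
#'
#' Two state-spaces built from different feature sets (e.g. miRNA and
#' mRNA) over the same samples are compared in sample space: each
#' component's score vector, restricted to the shared samples and
#' normalized to unit length, is dotted against each component of the
#' other space; the angle is `arccos(|u . v|)` in degrees (the absolute
#' value folds the sign ambiguity of the SVD), so angles lie in
#' `[0, 90]` and small angles mean the components encode the same source
#' of variance.
#'
#' @param space_a,space_b `state_space` objects.
#' @param shared_samples sample ids present in both spaces (default: the
#'   intersection of their score row names).
#' @return A matrix of angles (rows = components of `space_a`).
#' @export
pc_angles <- function(space_a, space_b, shared_samples = NULL) {
  stopifnot(inherits(space_a, "state_space"), inherits(space_b, "state_space"))
  if (is.null(shared_samples))
    shared_samples <- intersect(rownames(space_a$scores), rownames(space_b$scores))
  if (length(shared_samples) < 3L) stopf("need >= 3 shared samples")
  # drop numerically-null components (beyond the centered-data rank):
  # their score vectors are noise and would produce spurious alignments
  keep_a <- space_a$singular_values > 1e-8 * max(space_a$singular_values)
  keep_b <- space_b$singular_values > 1e-8 * max(space_b$singular_values)
  A <- space_a$scores[shared_samples, keep_a, drop = FALSE]
  B <- space_b$scores[shared_samples, keep_b, drop = FALSE]
  norm_cols <- function(M) {
    nz <- sqrt(colSums(M^2))
    if (any(nz == 0)) stopf("zero-norm score vector over the shared samples")
    sweep(M, 2, nz, "/")
  }
  A <- norm_cols(A); B <- norm_cols(B)
  m <- abs(crossprod(A, B))
  m[m > 1] <- 1
  ang <- acos(m) * 180 / pi
  dimnames(ang) <- list(paste0("a_PC", seq_len(ncol(A))),
                        paste0("b_PC", seq_len(ncol(B))))
  ang
}

#' Agreement of critical-point state assignments between two spaces
#'
#' Compares per-sample K1/K2/K3 membership under two critical-point fits
#' of the same samples (e.g. from miRNA- and mRNA-derived axes).
#'
#' @param assign_a,assign_b `state_assignment` objects named by sample id.
#' @param shared_samples ids to compare (default: intersection of names).
#' @return A list: `n`, `n_disagree`, `fraction`, `disagreeing` ids, and
#'   the label `table`.
#' @export
state_agreement <- function(assign_a, assign_b, shared_samples = NULL) {
  stopifnot(inherits(assign_a, "state_assignment"),
            inherits(assign_b, "state_assignment"))
  if (is.null(shared_samples))
    shared_samples <- intersect(names(assign_a$state), names(assign_b$state))
  if (!length(shared_samples)) stopf("no shared samples")
  la <- assign_a$state[shared_samples]
  lb <- assign_b$state[shared_samples]
  dis <- shared_samples[as.character(la) != as.character(lb)]
  list(n = length(shared_samples), n_disagree = length(dis),
       fraction = length(dis) / length(shared_samples),
       disagreeing = dis, table = table(a = la, b = lb))
}

#' Feature--gene correlation matrix with clustering order
#'
#' Pearson correlations between selected features of one normalized
#' matrix and genes of another over their shared samples, with
#' average-linkage hierarchical clustering on `1 - r` for display
#' ordering.  Constant series are excluded with a warning.
#'
#' @param features a `normalized_matrix` (e.g. persistent DE miRNAs),
#'   optionally subset via `feature_ids`.
#' @param genes a `normalized_matrix` of the other modality.
#' @param feature_ids,gene_ids optional column subsets.
#' @return A list: `r` (features x genes), `feature_order`, `gene_order`
#'   (clustering orders), `excluded`.
#' @export
feature_gene_correlation <- function(features, genes, feature_ids = NULL,
                                     gene_ids = NULL) {
  stopifnot(inherits(features, "normalized_matrix"),
            inherits(genes, "normalized_matrix"))
  shared <- intersect(rownames(features$values), rownames(genes$values))
  if (length(shared) < 3L) stopf("need >= 3 shared samples")
  Fm <- features$values[shared, , drop = FALSE]
  Gm <- genes$values[shared, , drop = FALSE]
  if (!is.null(feature_ids)) Fm <- Fm[, feature_ids, drop = FALSE]
  if (!is.null(gene_ids)) Gm <- Gm[, gene_ids, drop = FALSE]
  const_f <- colnames(Fm)[apply(Fm, 2, stats::sd) == 0]
  const_g <- colnames(Gm)[apply(Gm, 2, stats::sd) == 0]
  excluded <- c(const_f, const_g)
  if (length(excluded))
    warnf("excluding %d constant series from the correlation", length(excluded))
  Fm <- Fm[, !colnames(Fm) %in% const_f, drop = FALSE]
  Gm <- Gm[, !colnames(Gm) %in% const_g, drop = FALSE]
  if (!ncol(Fm) || !ncol(Gm)) stopf("no non-constant series left")
  r <- stats::cor(Fm, Gm)
  order_of <- function(M) {
    if (nrow(M) < 3L) return(seq_len(nrow(M)))
    stats::hclust(stats::dist(M), method = "average")$order
  }
  list(r = r, feature_order = order_of(r), gene_order = order_of(t(r)),
       excluded = excluded)
}
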