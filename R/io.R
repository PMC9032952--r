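#' Read and write cohort data
#'
#' Counts travel as TSV (features x samples, integer counts, feature ids
#' in the first column), metadata as CSV with columns sample_id,
#' mouse_id, genotype, time_months, status and optionally marker.
#'
#' @param dataset an [expression_dataset()].
#' @param counts_file,metadata_file file paths.
#' @return `write_dataset` invisibly returns the paths; `read_dataset`
#'   returns an [expression_dataset()].
#' @export
write_dataset <- function(dataset, counts_file, metadata_file) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- data.frame(feature_id = colnames(dataset$counts),
                    t(dataset$counts), check.names = FALSE)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(dataset$metadata, metadata_file, row.names = FALSE,
                   quote = FALSE)
  invisible(c(counts_file, metadata_file))
}

#' @rdname write_dataset
#' @param orientation `"features_x_samples"` (default, as written) or
#'   `"samples_x_features"`.
#' @export
read_dataset <- function(counts_file, metadata_file,
                         orientation = c("features_x_samples",
                                         "samples_x_features")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(counts_file, check.names = FALSE)
  metadata <- utils::read.csv(metadata_file, stringsAsFactors = FALSE)
  if (orientation == "features_x_samples") {
    feats <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    counts <- t(m)
    colnames(counts) <- feats
  } else {
    ids <- tab[[1]]
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- ids
  }
  counts <- counts[match(metadata$sample_id, rownames(counts)), , drop = FALSE]
  expression_dataset(counts, metadata)
}

#' Serialize a normalized matrix to TSV + JSON sidecar
#'
#' @param matrix a `normalized_matrix`.
#' @param values_file TSV of centered values (samples x features).
#' @param sidecar_file JSON with feature means, pseudocount and scale.
#' @export
write_normalized <- function(matrix, values_file, sidecar_file) {
  stopifnot(inherits(matrix, "normalized_matrix"))
  tab <- data.frame(sample_id = rownames(matrix$values), matrix$values,
                    check.names = FALSE)
  utils::write.table(tab, values_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(feature_means = as.list(matrix$feature_means),
         pseudocount = matrix$pseudocount, scale = matrix$scale),
    sidecar_file, auto_unbox = TRUE, digits = NA)
  invisible(c(values_file, sidecar_file))
}

#' Serialize a state-space to a JSON + TSV bundle
#'
#' Singular values, the chosen component and orientation go to JSON;
#' scores and loadings to TSV files alongside.
#'
#' @param space a `state_space`.
#' @param prefix path prefix; writes `<prefix>.json`,
#'   `<prefix>_scores.tsv`, `<prefix>_loadings.tsv`.
#' @export
write_state_space <- function(space, prefix) {
  stopifnot(inherits(space, "state_space"))
  jsonlite::write_json(
    list(singular_values = space$singular_values,
         state_pc_index = space$state_pc_index,
         orientation_sign = space$orientation_sign,
         pseudocount = space$pseudocount, scale = space$scale,
         feature_means = as.list(space$feature_means)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  sc <- data.frame(sample_id = rownames(space$scores), space$scores,
                   check.names = FALSE)
  utils::write.table(sc, paste0(prefix, "_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ld <- data.frame(component = seq_len(nrow(space$loadings)), space$loadings,
                   check.names = FALSE)
  utils::write.table(ld, paste0(prefix, "_loadings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Export a transition curve as CSV
#'
#' @param curve a `transition_curve`.
#' @param file output CSV path (columns time, probability).
#' @export
write_transition_curve <- function(curve, file) {
  stopifnot(inherits(curve, "transition_curve"))
  utils::write.csv(data.frame(time = curve$times,
                              probability = curve$probability),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
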