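#' Assign CM samples to critical-point states
#'
#' State labels are the K-means cluster memberships of the critical-point
#' fit: K1 samples are "at c1" (perturbed hematopoiesis), K2 "at c2"
#' (transition), K3 "at c3" (leukemia).  The labels serve as pseudo-time
#' points aligning mice that progress at different rates.
#'
#' @param fit a `critical_point_fit` computed on the CM samples' state
#'   coordinates.
#' @param sample_ids optional ids for the CM samples, in the order the
#'   coordinates were given to [estimate_critical_points()].
#' @return An object of class `state_assignment`: factor `state` with
#'   levels `c1`, `c2`, `c3`, plus the coordinates.
#' @export
assign_states <- function(fit, sample_ids = NULL) {
  stopifnot(inherits(fit, "critical_point_fit"))
  state <- factor(c("c1", "c2", "c3")[fit$cluster], levels = c("c1", "c2", "c3"))
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != length(state))
      stopf("sample_ids length (%d) must match the fit (%d)",
            length(sample_ids), length(state))
    names(state) <- sample_ids
  }
  structure(list(state = state, coords = fit$coords), class = "state_assignment")
}

#' Critical-point-aligned differential expression
#'
#' Per-feature two-group comparison of normalized (log2 CPM) expression
#' between the CM samples assigned to one critical-point state and ALL
#' control samples (controls remain in their basin throughout, so every
#' control sample is a valid comparator).  The default engine is the
#' empirical-Bayes moderated t-statistic of limma, which retains power at
#' the small per-state group sizes typical of the transition cluster;
#' Welch's t-test and the Wilcoxon rank-sum test are available behind the
#' `test` flag.  Benjamini--Hochberg correction across features.
#'
#' @param matrix a `normalized_matrix` covering CM and control samples
#'   (its `metadata` supplies genotype).
#' @param assignment a `state_assignment` named by CM sample id.
#' @param state one of `"c1"`, `"c2"`, `"c3"`.
#' @param fdr BH threshold declaring a feature differentially expressed.
#' @param test `"moderated"` (default), `"welch"` or `"wilcoxon"`.
#' @param min_samples smallest allowed group size (default 2; the
#'   moderated test borrows variance strength across features, which keeps
#'   two-sample state groups usable).
#' @return An object of class `de_table` (a data.frame): feature, mean
#'   log2 fold change (CM-at-state minus control), raw and BH-adjusted p,
#'   direction (`up`/`down`), `de` flag, `degenerate` flag for
#'   zero-variance features (reported non-DE with p = 1).
#' @export
differential_expression <- function(matrix, assignment, state,
                                    fdr = 0.05,
                                    test = c("moderated", "welch", "wilcoxon"),
                                    min_samples = 2L) {
  stopifnot(inherits(matrix, "normalized_matrix"),
            inherits(assignment, "state_assignment"))
  test <- match.arg(test)
  state <- match.arg(state, c("c1", "c2", "c3"))
  md <- matrix$metadata
  ctrl_rows <- which(md$genotype != "CM")
  cm_ids <- names(assignment$state)[assignment$state == state]
  cm_rows <- match(cm_ids, rownames(matrix$values))
  cm_rows <- cm_rows[!is.na(cm_rows)]
  if (length(cm_rows) < min_samples || length(ctrl_rows) < min_samples)
    stopf("too few samples at state %s (%d CM, %d control; need >= %d each)",
          state, length(cm_rows), length(ctrl_rows), min_samples)
  A <- matrix$values[cm_rows, , drop = FALSE]
  B <- matrix$values[ctrl_rows, , drop = FALSE]
  nf <- ncol(A)
  p <- lfc <- numeric(nf)
  degen <- logical(nf)
  for (j in seq_len(nf)) {
    lfc[j] <- mean(A[, j]) - mean(B[, j])
    degen[j] <- stats::sd(A[, j]) == 0 && stats::sd(B[, j]) == 0
  }
  if (test == "moderated") {
    expr <- t(rbind(A, B)) # features x samples, as limma expects
    design <- cbind(Intercept = 1,
                    cm = rep(c(1, 0), c(nrow(A), nrow(B))))
    p <- tryCatch({
      fit <- limma::eBayes(limma::lmFit(expr, design))
      fit$p.value[, "cm"]
    }, error = function(e) {
      warnf("moderated test failed (%s); falling back to Welch", conditionMessage(e))
      rep(NA_real_, nf)
    })
    if (anyNA(p)) test <- "welch"
  }
  if (test != "moderated") for (j in seq_len(nf)) {
    aj <- A[, j]; bj <- B[, j]
    if (degen[j]) {
      p[j] <- 1
    } else if (test == "welch") {
      p[j] <- tryCatch(stats::t.test(aj, bj)$p.value, error = function(e) 1)
    } else {
      p[j] <- suppressWarnings(stats::wilcox.test(aj, bj)$p.value)
    }
  }
  p[degen] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature = colnames(A), log2fc = lfc,
                    p_value = p, p_adjusted = padj,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    de = padj < fdr & !degen,
                    degenerate = degen,
                    stringsAsFactors = FALSE)
  attr(out, "state") <- state
  attr(out, "fdr") <- fdr
  attr(out, "test") <- test
  class(out) <- c("de_table", "data.frame")
  out
}

#' Classify DE events by critical point
#'
#' Early events are features differentially expressed uniquely at `c1`,
#' transition events uniquely at `c2`, late events uniquely at `c3`, and
#' persistent events at all three critical points.  Features DE at exactly
#' two states are reported as `unassigned` rather than forced into a
#' class.
#'
#' @param de_c1,de_c2,de_c3 `de_table`s over one feature universe.
#' @return An object of class `event_classification` with disjoint
#'   character vectors `early`, `transition`, `late`, `persistent`,
#'   `unassigned`, and `universe`.
#' @export
classify_events <- function(de_c1, de_c2, de_c3) {
  u <- de_c1$feature
  if (!identical(u, de_c2$feature) || !identical(u, de_c3$feature))
    stopf("the three DE tables must share one feature universe (same order)")
  s1 <- de_c1$feature[de_c1$de]
  s2 <- de_c2$feature[de_c2$de]
  s3 <- de_c3$feature[de_c3$de]
  n_states <- (u %in% s1) + (u %in% s2) + (u %in% s3)
  structure(list(
    early = u[u %in% s1 & n_states == 1L],
    transition = u[u %in% s2 & n_states == 1L],
    late = u[u %in% s3 & n_states == 1L],
    persistent = u[n_states == 3L],
    unassigned = u[n_states == 2L],
    universe = u
  ), class = "event_classification")
}

#' @export
print.event_classification <- function(x, ...) {
  cat(sprintf("DE events: %d early, %d transition, %d late, %d persistent, %d two-state (unassigned) of %d features\n",
              length(x$early), length(x$transition), length(x$late),
              length(x$persistent), length(x$unassigned), length(x$universe)))
  invisible(x)
}

#' Loading-based contribution vectors of DE events
#'
#' For each event class and regulation direction, the mean of the
#' (V1*, V2*) feature loadings summarizes where the class points in the
#' state-space.  A feature's contribution toward leukemia combines its
#' state-axis loading with its regulation direction: because disease lies
#' at the negative pole, an up-regulated feature contributes `-V1*` and a
#' down-regulated feature `+V1*` (so e.g. a feature with the largest
#' positive loading whose expression decreases still drives the state
#' toward leukemia).  Positive scores mean movement toward the leukemic
#' state.
#'
#' @param events an `event_classification`.
#' @param tables named list of the three `de_table`s (`c1`, `c2`, `c3`)
#'   used for the classification; supplies per-feature direction (a
#'   feature's direction is taken from the state(s) where it was DE,
#'   majority vote).
#' @param space a `state_space` (oriented); `V1*` is the state-axis
#'   loadings row, `V2*` the display component (highest-variance
#'   remaining).
#' @return A data.frame with one row per event class x direction:
#'   mean_v1, mean_v2, n, and the mean leukemia-contribution `score`.
#'   Empty combinations are omitted.
#' @export
contribution_vectors <- function(events, tables, space) {
  stopifnot(inherits(events, "event_classification"),
            inherits(space, "state_space"))
  k <- space$state_pc_index
  other <- setdiff(order(space$singular_values, decreasing = TRUE), k)[1]
  v1 <- space$orientation_sign * space$loadings[k, ]
  v2 <- space$loadings[other, ]
  # per-feature direction: majority over the states where it was called DE
  dirs <- lapply(tables, function(tb) stats::setNames(tb$direction, tb$feature))
  de_flags <- lapply(tables, function(tb) stats::setNames(tb$de, tb$feature))
  feature_dir <- function(f) {
    d <- unlist(lapply(names(dirs), function(s)
      if (isTRUE(de_flags[[s]][f])) dirs[[s]][f] else NULL))
    if (!length(d)) d <- unlist(lapply(dirs, `[`, f))
    names(which.max(table(d)))
  }
  rows <- list()
  for (cls in c("early", "transition", "late", "persistent")) {
    feats <- events[[cls]]
    if (!length(feats)) next
    dvec <- vapply(feats, feature_dir, character(1))
    for (dr in unique(dvec)) {
      f <- feats[dvec == dr]
      miss <- setdiff(f, names(v1))
      if (length(miss))
        stopf("loadings unavailable for feature(s): %s", paste(miss, collapse = ", "))
      score <- ifelse(dr == "up", -v1[f], v1[f])
      rows[[paste(cls, dr)]] <- data.frame(
        class = cls, direction = dr, n = length(f),
        mean_v1 = mean(v1[f]), mean_v2 = mean(v2[f]),
        score = mean(score), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    message("contribution_vectors: all event classes empty")
    return(data.frame(class = character(), direction = character(),
                      n = integer(), mean_v1 = numeric(), mean_v2 = numeric(),
                      score = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
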