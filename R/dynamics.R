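#' Cluster features by expression-dynamics correlation
#'
#' Feature--feature Pearson correlations are computed over the CM samples
#' (patterns are defined along the disease trajectory), converted to the
#' distance `1 - r`, and clustered by average-linkage hierarchical
#' clustering; the tree is cut into `n_groups` groups (default 4).
#' Constant features are excluded with a warning before the correlation.
#'
#' @param matrix a `normalized_matrix`.
#' @param n_groups number of groups to cut (default 4).
#' @param cm_only restrict to CM samples (default TRUE).
#' @return An object of class `dynamics_groups`: named integer `group`
#'   per clustered feature, `hclust` tree, `excluded` features, and a
#'   silhouette-style suggestion `suggested_k` (printed, never
#'   auto-applied).
#' @export
cluster_dynamics <- function(matrix, n_groups = 4L, cm_only = TRUE) {
  stopifnot(inherits(matrix, "normalized_matrix"))
  X <- matrix$values
  if (cm_only) {
    cm <- matrix$metadata$genotype == "CM"
    if (sum(cm) >= 3) X <- X[cm, , drop = FALSE]
  }
  if (nrow(X) < 3L) stopf("need at least 3 samples for correlations")
  sds <- apply(X, 2, stats::sd)
  excluded <- colnames(X)[sds == 0]
  if (length(excluded))
    warnf("excluding %d constant feature(s) before correlation", length(excluded))
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) < n_groups)
    stopf("fewer usable features (%d) than groups (%d)", ncol(X), n_groups)
  r <- stats::cor(X)
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, k = n_groups)
  # lightweight k suggestion: largest mean silhouette over k = 2..6
  ks <- 2:min(6L, ncol(X) - 1L)
  dm <- as.matrix(d)
  sil <- vapply(ks, function(k) {
    g <- stats::cutree(hc, k = k)
    mean(vapply(seq_along(g), function(i) {
      own <- mean(dm[i, g == g[i] & seq_along(g) != i])
      if (!is.finite(own)) return(0)
      oth <- min(vapply(setdiff(unique(g), g[i]), function(o)
        mean(dm[i, g == o]), numeric(1)))
      (oth - own) / max(own, oth)
    }, numeric(1)))
  }, numeric(1))
  structure(list(group = grp, hclust = hc, n_groups = as.integer(n_groups),
                 excluded = excluded, suggested_k = ks[which.max(sil)]),
            class = "dynamics_groups")
}

#' @export
print.dynamics_groups <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("Dynamics groups: %s (silhouette suggests k = %d)\n",
              paste(sprintf("G%s: %d", names(tab), tab), collapse = ", "),
              x$suggested_k))
  invisible(x)
}

#' Fit an expression pattern along the state coordinate
#'
#' The mean expression of a feature group per sample is regressed on the
#' sample's state coordinate with a cubic polynomial (the lowest degree
#' admitting one interior extremum plus asymmetry).  Classification uses
#' the sign changes of the fitted derivative within the observed
#' coordinate range: none gives a monotonic pattern, one gives a local
#' maximum or minimum with the extremum at the derivative root.  With two
#' interior sign changes the more prominent extremum (larger fitted
#' deviation) is reported and the fit flagged.
#'
#' @param matrix a `normalized_matrix`.
#' @param features character vector of features forming the group.
#' @param state_coords named per-sample state coordinates (names matching
#'   the matrix rows); samples missing a coordinate are dropped.
#' @return An object of class `pattern_fit`: `classification` (one of
#'   `monotonic_increasing`, `monotonic_decreasing`, `local_max`,
#'   `local_min`), `extremum` (state units, `NA` for monotonic fits),
#'   `coefficients`, `range`, `ambiguous` flag.
#' @export
fit_pattern <- function(matrix, features, state_coords) {
  stopifnot(inherits(matrix, "normalized_matrix"))
  miss <- setdiff(features, colnames(matrix$values))
  if (length(miss)) stopf("unknown feature(s): %s", paste(miss, collapse = ", "))
  ids <- intersect(rownames(matrix$values), names(state_coords))
  if (length(ids) < 5L) stopf("need >= 5 samples with state coordinates")
  y <- rowMeans(matrix$values[ids, features, drop = FALSE])
  x <- state_coords[ids]
  if (diff(range(x)) < .Machine$double.eps^0.5)
    stopf("degenerate design: all state coordinates equal")
  fit <- stats::lm(y ~ x + I(x^2) + I(x^3))
  b <- stats::coef(fit)
  b[is.na(b)] <- 0
  # derivative b1 + 2 b2 x + 3 b3 x^2
  d1 <- c(b[2], 2 * b[3], 3 * b[4])
  lo <- min(x); hi <- max(x)
  roots <- numeric(0)
  if (abs(d1[3]) > 1e-12) {
    disc <- d1[2]^2 - 4 * d1[3] * d1[1]
    if (disc >= 0) roots <- (-d1[2] + c(-1, 1) * sqrt(disc)) / (2 * d1[3])
  } else if (abs(d1[2]) > 1e-12) {
    roots <- -d1[1] / d1[2]
  }
  roots <- sort(roots[roots > lo & roots < hi])
  deriv <- function(z) d1[1] + d1[2] * z + d1[3] * z^2
  curve_val <- function(z) b[1] + b[2] * z + b[3] * z^2 + b[4] * z^3
  # drop tangential roots (no sign change)
  if (length(roots)) {
    eps <- (hi - lo) * 1e-6
    keep <- vapply(roots, function(r0)
      sign(deriv(r0 - eps)) * sign(deriv(r0 + eps)) < 0, logical(1))
    roots <- roots[keep]
  }
  ambiguous <- FALSE
  if (length(roots) == 0L) {
    cls <- if (deriv((lo + hi) / 2) >= 0) "monotonic_increasing" else "monotonic_decreasing"
    ext <- NA_real_
  } else {
    if (length(roots) > 1L) {
      ambiguous <- TRUE
      dev <- abs(curve_val(roots) - mean(curve_val(c(lo, hi))))
      roots <- roots[which.max(dev)]
    }
    ext <- unname(roots[1])
    eps <- (hi - lo) * 1e-6
    cls <- if (deriv(ext - eps) > 0) "local_max" else "local_min"
  }
  structure(list(classification = cls, extremum = ext,
                 coefficients = b, range = c(lo, hi),
                 ambiguous = ambiguous, n_samples = length(ids)),
            class = "pattern_fit")
}

#' @export
print.pattern_fit <- function(x, ...) {
  cat(sprintf("Pattern fit: %s%s (n = %d, range [%.3g, %.3g])\n",
              x$classification,
              if (is.finite(x$extremum)) sprintf(" at %.3g", x$extremum) else "",
              x$n_samples, x$range[1], x$range[2]))
  invisible(x)
}

#' Over-representation of event classes in dynamics groups
#'
#' One-sided hypergeometric test per (group, event class) cell: is the
#' class over-represented inside the group relative to the shared feature
#' universe?  BH correction across all cells.  Empty classes give p = 1.
#'
#' @param groups a `dynamics_groups`, or a named vector/factor of group
#'   labels per feature (e.g. planted pattern labels).
#' @param events an `event_classification`.
#' @return A data.frame with one row per group x class: `overlap`,
#'   `group_size`, `class_size`, `p_value`, `p_adjusted`.
#' @export
enrichment_test <- function(groups, events) {
  if (!inherits(groups, "dynamics_groups")) {
    if (is.null(names(groups))) stopf("group labels must be named by feature")
    g <- stats::setNames(as.character(groups), names(groups))
    groups <- structure(list(group = g), class = "dynamics_groups")
  }
  stopifnot(inherits(events, "event_classification"))
  universe <- intersect(names(groups$group), events$universe)
  N <- length(universe)
  if (!N) stopf("no shared feature universe")
  rows <- list()
  for (g in sort(unique(groups$group))) {
    gf <- intersect(names(groups$group)[groups$group == g], universe)
    for (cls in c("early", "transition", "late", "persistent")) {
      cf <- intersect(events[[cls]], universe)
      k <- length(intersect(gf, cf))
      p <- if (!length(cf)) 1 else
        stats::phyper(k - 1, length(cf), N - length(cf), length(gf),
                      lower.tail = FALSE)
      rows[[paste(g, cls)]] <- data.frame(
        group = g, class = cls, overlap = k,
        group_size = length(gf), class_size = length(cf),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
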