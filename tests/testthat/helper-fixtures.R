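# Shared fixtures.  Cohort simulation is cheap (< 1 s) but reused across
# files, so the default cohort and its fitted model are cached per session.

fixture_env <- new.env(parent = emptyenv())

with_seed_local <- function(seed, expr) statetrans:::with_seed(seed, expr)

default_cohort <- function(seed = 42L, ...) {
  key <- paste0("cohort_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- simulate_cohort(cohort_config(seed = seed, ...))
  fixture_env[[key]]
}

default_model <- function(seed = 42L) {
  key <- paste0("model_", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- fit_state_transition(default_cohort(seed)$dataset)
  fixture_env[[key]]
}

# tiny hand-built state space for unit tests of loading-based operations
toy_state_space <- function(loadings, state_pc_index = 1L) {
  structure(list(
    scores = matrix(0, 3, nrow(loadings),
                    dimnames = list(paste0("s", 1:3), NULL)),
    singular_values = rev(seq_len(nrow(loadings))),
    loadings = loadings,
    feature_means = stats::setNames(rep(0, ncol(loadings)), colnames(loadings)),
    pseudocount = 1, scale = 1e6,
    state_pc_index = state_pc_index,
    orientation_sign = 1,
    metadata = data.frame()
  ), class = "state_space")
}

# minimal de_table for classification tests
toy_de_table <- function(universe, de_features, lfc = NULL) {
  if (is.null(lfc)) lfc <- ifelse(universe %in% de_features, 1, 0)
  out <- data.frame(feature = universe, log2fc = lfc,
                    p_value = ifelse(universe %in% de_features, 1e-6, 0.9),
                    p_adjusted = ifelse(universe %in% de_features, 1e-5, 0.95),
                    direction = ifelse(lfc >= 0, "up", "down"),
                    de = universe %in% de_features,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

# independent brute-force log-rank tabulation (oracle)
brute_force_logrank <- function(time1, event1, time2, event2) {
  tm <- c(time1, time2); ev <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  ts <- sort(unique(tm[ev == 1]))
  OmE <- 0; V <- 0
  for (t in ts) {
    at1 <- sum(tm >= t & grp == 1); at2 <- sum(tm >= t & grp == 2)
    d1 <- sum(tm == t & ev == 1 & grp == 1)
    d2 <- sum(tm == t & ev == 1 & grp == 2)
    n <- at1 + at2; d <- d1 + d2
    if (n < 2 || d == 0) next
    OmE <- OmE + d1 - d * at1 / n
    V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}
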