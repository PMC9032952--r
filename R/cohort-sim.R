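#' Configuration for a synthetic AML cohort
#'
#' Defines the study conditions emulated by the generator: serial
#' peripheral-blood samples from conditionally induced (CM) and control
#' mice, drawn monthly, whose expression is a noisy low-rank readout of a
#' one-dimensional latent disease coordinate evolving by Langevin dynamics
#' in a double-well quasi-potential.  The defaults reproduce a training
#' cohort of 7 CM + 7 control mice followed for 10 months in which roughly
#' 80--90% of CM mice transition to leukemia with a median onset near 4
#' months; validation-style cohorts are obtained by changing `n_cm`,
#' `n_control` and `t_max`.
#'
#' The latent geometry places the unstable transition point `c2` close to
#' the perturbed-hematopoiesis well `c1` and the leukemic well `c3` far
#' below: a mouse fluctuates tightly around `c1` for months, and once past
#' `c2` descends rapidly and irreversibly -- long clinical quiescence
#' followed by fast overt progression.  Control mice evolve in the same
#' cubic-gradient family with a much larger scale (`alpha_control`) and
#' with their stable state offset by `control_offset` above `c1`: normal
#' and perturbed hematopoiesis are distinct states, so CM and control
#' samples separate on the disease axis from the first post-induction
#' month even though no CM mouse has yet progressed.
#'
#' @param n_cm,n_control numbers of CM and control mice.
#' @param t_max last observation month (samples at t = 0, 1, ..., t_max).
#' @param true_critical_points `(c1, c2, c3)` of the CM potential,
#'   `c3 < c2 < c1`, in state-space units.
#' @param alpha_cm,alpha_control potential scales for CM and control mice.
#' @param control_offset position of the control (normal hematopoiesis)
#'   stable state above `c1`, in state units.
#' @param diffusion diffusion coefficient D (state-units^2/month) of the
#'   latent Langevin dynamics, common to both genotypes.
#' @param n_features number of features (miRNAs) in the count readout.
#' @param pattern_fractions named fractions of features following each
#'   expression pattern along the latent axis; must sum to 1.
#' @param monotonic_effect |d log2 expression / d latent| of monotonic
#'   features (log2 units per state unit).
#' @param bump_height,bump_width amplitude (log2 units) and width (state
#'   units) of the Gaussian expression bump of `peak_at_c2` /
#'   `trough_at_c2` features, centered at `c2`.
#' @param nb_dispersion negative-binomial dispersion of counts
#'   (`variance = mu + dispersion * mu^2`).
#' @param library_size_mean mean per-sample library size (counts).
#' @param marker_slope slope of the Kit-like marker on the latent
#'   coordinate; negative so the marker rises toward leukemia.
#' @param marker_noise_sd standard deviation of marker noise, state units.
#' @param seed integer seed making the whole cohort reproducible.
#' @return An object of class `cohort_config` (a validated list).  The
#'   element `loading_vector` holds the unit-normalized vector of latent
#'   slopes of the features (the planted disease axis in feature space).
#' @export
cohort_config <- function(n_cm = 7L, n_control = 7L, t_max = 10,
                          true_critical_points = c(2, 1, -4),
                          alpha_cm = 0.55, alpha_control = 8,
                          control_offset = 0.75,
                          diffusion = 0.5,
                          n_features = 300L,
                          pattern_fractions = c(monotonic_up = 50 / 300,
                                                monotonic_down = 50 / 300,
                                                peak_at_c2 = 30 / 300,
                                                trough_at_c2 = 30 / 300,
                                                null = 140 / 300),
                          monotonic_effect = 0.5,
                          bump_height = 1.0, bump_width = 1.3,
                          nb_dispersion = 0.1,
                          library_size_mean = 1e6,
                          marker_slope = -1, marker_noise_sd = 1.0,
                          seed = 1L) {
  cp <- as.numeric(true_critical_points)
  if (length(cp) != 3L || !(cp[3] < cp[2] && cp[2] < cp[1]))
    stopf("true_critical_points must be (c1, c2, c3) with c3 < c2 < c1")
  check_number(diffusion, "diffusion", lower = .Machine$double.xmin)
  check_number(alpha_cm, "alpha_cm", lower = 0)
  check_number(alpha_control, "alpha_control", lower = 0)
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(library_size_mean, "library_size_mean", lower = 1)
  check_number(marker_noise_sd, "marker_noise_sd", lower = 0)
  lbl <- c("monotonic_up", "monotonic_down", "peak_at_c2", "trough_at_c2", "null")
  if (!setequal(names(pattern_fractions), lbl))
    stopf("pattern_fractions must be named: %s", paste(lbl, collapse = ", "))
  pattern_fractions <- pattern_fractions[lbl]
  if (abs(sum(pattern_fractions) - 1) > 1e-8)
    stopf("pattern_fractions must sum to 1")
  n_features <- as.integer(n_features)
  counts <- floor(pattern_fractions * n_features)
  rem <- n_features - sum(counts)
  if (rem > 0) { # distribute remainder by largest fractional part
    fr <- pattern_fractions * n_features - counts
    add <- order(fr, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  pattern_labels <- rep(lbl, counts)
  slopes <- numeric(n_features) # d f / d latent for monotonic features
  slopes[pattern_labels == "monotonic_up"] <- -monotonic_effect
  slopes[pattern_labels == "monotonic_down"] <- monotonic_effect
  nv <- sqrt(sum(slopes^2))
  cfg <- structure(list(
    n_cm = as.integer(n_cm), n_control = as.integer(n_control),
    t_max = t_max, true_critical_points = cp,
    alpha_cm = alpha_cm, alpha_control = alpha_control,
    control_offset = control_offset, diffusion = diffusion,
    n_features = n_features, pattern_labels = pattern_labels,
    loading_vector = if (nv > 0) slopes / nv else slopes,
    monotonic_effect = monotonic_effect,
    bump_height = bump_height, bump_width = bump_width,
    nb_dispersion = nb_dispersion, library_size_mean = library_size_mean,
    marker_slope = marker_slope, marker_noise_sd = marker_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort config: %d CM + %d control mice, t = 0..%g months\n",
              x$n_cm, x$n_control, x$t_max))
  cat(sprintf("  critical points (%.3g, %.3g, %.3g), alpha_cm %.3g, D %.3g, %d features\n",
              x$true_critical_points[1], x$true_critical_points[2],
              x$true_critical_points[3], x$alpha_cm, x$diffusion, x$n_features))
  invisible(x)
}

# Deterministic per-feature readout parameters derived from the config
# seed.  Disease-modulated features are drawn from the low/mid-abundance
# range (the most abundant miRNAs are housekeeping-stable), which also
# keeps their share of library mass small so that counts-per-million
# normalization is compositionally stable.
feature_params <- function(config) {
  is_null <- config$pattern_labels == "null"
  with_seed(config$seed * 1000L + 17L, {
    baseline <- ifelse(is_null,
                       stats::runif(config$n_features, 4, 10),
                       stats::runif(config$n_features, 4, 7)) # log2 abundance
  })
  list(baseline = baseline, labels = config$pattern_labels)
}

# latent -> expected log2 expression offset, per feature pattern
pattern_function <- function(config) {
  c2 <- config$true_critical_points[2]
  h <- config$bump_height; w <- config$bump_width
  function(label, slope, x) {
    switch(label,
      monotonic_up = -config$monotonic_effect * x,
      monotonic_down = config$monotonic_effect * x,
      peak_at_c2 = h * exp(-(x - c2)^2 / (2 * w^2)),
      trough_at_c2 = -h * exp(-(x - c2)^2 / (2 * w^2)),
      null = rep(0, length(x)))
  }
}

#' Simulate one latent Langevin trajectory
#'
#' Euler--Maruyama integration of `dX = -U'(X) dt + sqrt(2 D) dB` on a fine
#' internal step with linear interpolation onto the requested observation
#' grid.  Equal seeds on equal inputs give identical output.
#'
#' @param potential a [quasi_potential()].
#' @param diffusion diffusion coefficient D (state-units^2/month).
#' @param t_grid strictly increasing observation times (months).
#' @param x0 initial position at `t_grid[1]`.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param dt internal integration step (months), at most 0.01.
#' @return numeric vector of positions, one per `t_grid` entry.
#' @export
simulate_latent_trajectory <- function(potential, diffusion, t_grid, x0,
                                       seed = NULL, dt = 0.005) {
  stopifnot(inherits(potential, "quasi_potential"))
  if (any(diff(t_grid) <= 0)) stopf("t_grid must be strictly increasing")
  if (dt > 0.01) stopf("internal step dt must be <= 0.01 month")
  check_number(diffusion, "diffusion", lower = 0)
  with_seed(seed, {
    drop(sim_paths(potential, diffusion, t_grid, x0, n_paths = 1L, dt = dt))
  })
}

# vectorized Euler-Maruyama ensemble: returns matrix [length(t_grid) x n_paths]
# uses the active RNG stream; callers wrap in with_seed().
sim_paths <- function(potential, diffusion, t_grid, x0, n_paths, dt = 0.005) {
  t0 <- t_grid[1]
  span <- t_grid[length(t_grid)] - t0
  n_steps <- ceiling(span / dt + 1e-9)
  x <- rep_len(x0, n_paths)
  out <- matrix(NA_real_, length(t_grid), n_paths)
  fine_t <- t0
  gi <- 1L
  if (t_grid[1] <= t0 + 1e-12) { out[1L, ] <- x; gi <- 2L }
  sig <- sqrt(2 * diffusion * dt)
  prev_x <- x; prev_t <- t0
  for (s in seq_len(n_steps)) {
    step <- min(dt, t0 + span - fine_t)
    if (step <= 0) break
    drift <- -potential_gradient(potential, x)
    if (any(!is.finite(drift)))
      stopf("non-finite drift at step %d (t = %.3f): trajectory diverged", s, fine_t)
    x <- x + drift * step +
      (if (step == dt) sig else sqrt(2 * diffusion * step)) * stats::rnorm(n_paths)
    prev_t <- fine_t
    fine_t <- fine_t + step
    while (gi <= length(t_grid) && t_grid[gi] <= fine_t + 1e-12) {
      w <- (t_grid[gi] - prev_t) / (fine_t - prev_t)
      out[gi, ] <- prev_x * (1 - w) + x * w
      gi <- gi + 1L
    }
    prev_x <- x
  }
  if (gi <= length(t_grid)) stopf("internal error: observation grid not covered")
  out
}

#' Negative-binomial count readout of latent positions
#'
#' Expected log2 expression of feature j at latent position x is
#' `baseline_j + f_j(x)` where `f_j` is linear in x for monotonic features
#' (sign per label; expression of `monotonic_up` features rises as x
#' decreases toward leukemia), a Gaussian bump centered at `c2` for
#' `peak_at_c2`/`trough_at_c2` features, and 0 for `null` features.
#' Expected counts are the per-sample compositional fractions scaled by a
#' log-normal library size, with negative-binomial sampling noise.
#'
#' @param latent numeric vector of latent positions (one per sample).
#' @param config a [cohort_config()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return integer count matrix, samples x features.
#' @export
counts_from_latent <- function(latent, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  fp <- feature_params(config)
  f <- pattern_function(config)
  m <- length(latent); n <- config$n_features
  logmu <- matrix(0, m, n)
  for (j in seq_len(n))
    logmu[, j] <- fp$baseline[j] + f(fp$labels[j], 0, latent)
  mu_rel <- 2^logmu
  p <- mu_rel / rowSums(mu_rel)
  with_seed(seed, {
    lib <- stats::rlnorm(m, meanlog = log(config$library_size_mean), sdlog = 0.1)
    mu <- p * lib
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    cnt <- if (is.finite(size)) {
      stats::rnbinom(m * n, mu = as.vector(mu), size = size)
    } else {
      stats::rpois(m * n, lambda = as.vector(mu))
    }
    matrix(as.integer(cnt), m, n,
           dimnames = list(NULL, sprintf("miR-%03d", seq_len(n))))
  })
}

#' Simulate a full synthetic cohort with ground truth
#'
#' CM mice start at the control (normal hematopoiesis) state at t = 0
#' (pre-induction) and then evolve in the CM quasi-potential; control mice
#' evolve in the high-barrier control potential around `c1 +
#' control_offset`.  All mice are sampled monthly; a CM mouse whose
#' position at an observation time has fallen below `c3 + 0.5` (settled in
#' the leukemic basin, i.e. moribund) contributes that terminal
#' `aml_death` sample and exits the study; all other mice are censored at
#' `t_max`.  A Kit-like marker (`marker_slope * latent + noise`) is
#' recorded per sample.
#'
#' @param config a [cohort_config()].
#' @return A list with elements
#'   `dataset` (an [expression_dataset()]: counts, metadata with columns
#'   sample_id, mouse_id, genotype, time_months, status, marker) and
#'   `truth` (class `ground_truth`: per-mouse monthly latent trajectories,
#'   onset times -- first crossing below `c2` on the fine integration grid
#'   -- or `NA` when censored, true critical points, true diffusion,
#'   per-feature pattern labels, expected log2 fold changes at each
#'   critical point, and the observed latent position of every sample).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cp <- config$true_critical_points
  c1 <- cp[1]; c2 <- cp[2]; c3 <- cp[3]
  ctrl_pos <- c1 + config$control_offset
  qp_cm <- quasi_potential(cp, alpha = config$alpha_cm)
  qp_ct <- quasi_potential(c(ctrl_pos, c2, c3), alpha = config$alpha_control)
  months <- seq(0, config$t_max, by = 1)
  dt <- 0.005
  fine_t <- seq(0, config$t_max, by = dt)
  obs_idx <- round(months / dt) + 1L

  with_seed(config$seed, {
    # latent trajectories on the fine grid; the perturbed set point is
    # established within days of induction, well below the sampling
    # interval, so CM mice start at c1
    cm_paths <- if (config$n_cm > 0)
      sim_paths(qp_cm, config$diffusion, fine_t, c1, config$n_cm, dt)
    else matrix(0, length(fine_t), 0)
    ct_paths <- if (config$n_control > 0)
      sim_paths(qp_ct, config$diffusion, fine_t, ctrl_pos, config$n_control, dt)
    else matrix(0, length(fine_t), 0)

    meta <- list(); latent <- c()
    trajectories <- list(); onset <- c()
    for (m in seq_len(config$n_cm)) {
      path <- cm_paths[, m]
      obs <- path[obs_idx]
      id <- sprintf("CM%02d", m)
      cross <- which(path < c2)[1]
      onset[id] <- if (is.na(cross)) NA_real_ else fine_t[cross]
      dead_at <- which(obs < c3 + 0.5)[1]
      keep <- if (is.na(dead_at)) seq_along(months) else seq_len(dead_at)
      status <- rep("alive", length(keep))
      status[length(keep)] <- if (is.na(dead_at)) "censored" else "aml_death"
      meta[[id]] <- data.frame(
        sample_id = sprintf("%s_t%02d", id, months[keep]),
        mouse_id = id, genotype = "CM",
        time_months = months[keep], status = status,
        stringsAsFactors = FALSE)
      latent <- c(latent, obs[keep])
      trajectories[[id]] <- stats::setNames(obs[keep], months[keep])
    }
    for (m in seq_len(config$n_control)) {
      path <- ct_paths[, m]
      obs <- path[obs_idx]
      id <- sprintf("CTRL%02d", m)
      status <- rep("alive", length(months))
      status[length(months)] <- "censored"
      meta[[id]] <- data.frame(
        sample_id = sprintf("%s_t%02d", id, months),
        mouse_id = id, genotype = "control",
        time_months = months, status = status,
        stringsAsFactors = FALSE)
      latent <- c(latent, obs)
      trajectories[[id]] <- stats::setNames(obs, months)
    }
    metadata <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
    metadata$marker <- config$marker_slope * latent +
      stats::rnorm(length(latent), 0, config$marker_noise_sd)
    counts <- counts_from_latent(latent, config, seed = NULL)
    rownames(counts) <- metadata$sample_id

    # analytic per-feature expected log2 fold change at each critical point
    fp <- feature_params(config)
    f <- pattern_function(config)
    lfc <- sapply(c(c1 = c1, c2 = c2, c3 = c3), function(pos) {
      vapply(seq_len(config$n_features), function(j)
        f(fp$labels[j], 0, pos) - f(fp$labels[j], 0, ctrl_pos), numeric(1))
    })
    rownames(lfc) <- colnames(counts)

    dataset <- expression_dataset(counts, metadata)
    truth <- structure(list(
      trajectories = trajectories,
      onset_months = onset,
      sample_latent = stats::setNames(latent, metadata$sample_id),
      true_critical_points = cp,
      control_position = ctrl_pos,
      diffusion = config$diffusion,
      pattern_labels = stats::setNames(config$pattern_labels, colnames(counts)),
      expected_lfc = lfc,
      de_status = abs(lfc) > 0.25,
      config = config
    ), class = "ground_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  n_on <- sum(!is.na(x$onset_months))
  cat(sprintf("Ground truth: %d mice, %d with AML onset; D = %.3g; c = (%.3g, %.3g, %.3g)\n",
              length(x$trajectories), n_on, x$diffusion,
              x$true_critical_points[1], x$true_critical_points[2],
              x$true_critical_points[3]))
  invisible(x)
}
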