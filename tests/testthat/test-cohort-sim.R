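test_that("a noiseless trajectory started at a critical point stays there", {
  qp <- quasi_potential(c(2, 1, -4), alpha = 0.4)
  x <- simulate_latent_trajectory(qp, diffusion = 0, t_grid = 0:10, x0 = 2,
                                  seed = 1)
  expect_equal(x, rep(2, 11), tolerance = 1e-12)
})

test_that("flat-potential endpoints reproduce the Brownian variance 2Dt", {
  flat <- quasi_potential(c(1, 0, -1), alpha = 0)
  ends <- with_seed_local(21,
    statetrans:::sim_paths(flat, 0.5, c(0, 1), 0, 5000L)[2, ])
  expect_equal(stats::var(ends), 2 * 0.5 * 1, tolerance = 0.05)
  expect_equal(mean(ends), 0, tolerance = 0.05)
})

test_that("low-barrier potential crosses c2 more often than the control potential", {
  cm <- quasi_potential(c(2, 1, -4), alpha = 0.4)
  ctrl <- quasi_potential(c(2, 1, -4), alpha = 8)
  cm_paths <- with_seed_local(31, statetrans:::sim_paths(cm, 0.5, 0:10, 2, 300L))
  ct_paths <- with_seed_local(32, statetrans:::sim_paths(ctrl, 0.5, 0:10, 2, 300L))
  f_cm <- mean(apply(cm_paths, 2, function(p) any(p < 1)))
  f_ct <- mean(apply(ct_paths, 2, function(p) any(p < 1)))
  expect_gt(f_cm, f_ct)
  expect_lt(f_ct, 1e-3) # control barrier essentially uncrossable
})

test_that("trajectory simulation is reproducible and validates its inputs", {
  qp <- quasi_potential(c(2, 1, -4), alpha = 0.4)
  a <- simulate_latent_trajectory(qp, 0.5, 0:5, 2, seed = 9)
  b <- simulate_latent_trajectory(qp, 0.5, 0:5, 2, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_latent_trajectory(qp, 0.5, c(0, 0, 1), 2, seed = 1),
               "strictly increasing")
  expect_error(simulate_latent_trajectory(qp, 0.5, 0:5, 2, seed = 1, dt = 0.1),
               "0.01")
  # diverging drift is reported, not silently propagated
  steep <- quasi_potential(c(2, 1, -4), alpha = 1e8)
  expect_error(simulate_latent_trajectory(steep, 1e8, 0:5, 50, seed = 1),
               "diverged")
})

test_that("count readout is deterministic and respects the sign convention", {
  cfg <- cohort_config(seed = 5)
  a <- counts_from_latent(c(2, -4), cfg, seed = 17)
  b <- counts_from_latent(c(2, -4), cfg, seed = 17)
  expect_identical(a, b)
  lbl <- cfg$pattern_labels
  # up-in-AML features have larger expected counts at the AML end (c3)
  up <- lbl == "monotonic_up"
  expect_gt(mean(a[2, up]), 5 * mean(a[1, up]))
  dn <- lbl == "monotonic_down"
  expect_gt(mean(a[1, dn]), 5 * mean(a[2, dn]))
})

test_that("null features have identical distributions at any latent position", {
  cfg <- cohort_config(seed = 5, n_features = 50,
                       pattern_fractions = c(monotonic_up = 0, monotonic_down = 0,
                                             peak_at_c2 = 0, trough_at_c2 = 0,
                                             null = 1))
  a <- counts_from_latent(c(2, -4), cfg, seed = 3)
  # equal seeds on equal inputs give equal outputs
  expect_identical(counts_from_latent(c(2, -4), cfg, seed = 3), a)
  # identical in law: per-feature means over replicates agree across positions
  reps <- with_seed_local(13, {
    t(vapply(1:200, function(i) colMeans(counts_from_latent(c(2, -4), cfg,
                                                            seed = NULL)),
             numeric(50)))
  })
  # compare against a second ensemble at the swapped positions
  reps2 <- with_seed_local(14, {
    t(vapply(1:200, function(i) colMeans(counts_from_latent(c(-4, 2), cfg,
                                                            seed = NULL)),
             numeric(50)))
  })
  expect_equal(colMeans(reps), colMeans(reps2), tolerance = 0.15)
})

test_that("the dispersion-to-zero limit is Poisson (variance equals mean)", {
  cfg <- cohort_config(seed = 5, nb_dispersion = 0, n_features = 100,
                       pattern_fractions = c(monotonic_up = 0, monotonic_down = 0,
                                             peak_at_c2 = 0, trough_at_c2 = 0,
                                             null = 1))
  reps <- with_seed_local(8, {
    t(vapply(1:200, function(i)
      counts_from_latent(2, cfg, seed = NULL)[1, ], numeric(100)))
  })
  # CPM-scale library variation is removed by scaling each draw to its total
  reps <- reps / rowSums(reps) * mean(rowSums(reps))
  ratio <- apply(reps, 2, stats::var) / colMeans(reps)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("cohorts are reproducible byte for byte and respect the study design", {
  sim1 <- simulate_cohort(cohort_config(seed = 77))
  sim2 <- simulate_cohort(cohort_config(seed = 77))
  expect_identical(serialize(sim1, NULL), serialize(sim2, NULL))

  md <- sim1$dataset$metadata
  expect_identical(nrow(md), nrow(sim1$dataset$counts))
  expect_setequal(unique(md$genotype), c("CM", "control"))
  # controls observed at every month, never leukemic
  for (id in unique(md$mouse_id[md$genotype == "control"])) {
    d <- md[md$mouse_id == id, ]
    expect_equal(sort(d$time_months), 0:10)
    expect_false(any(d$status == "aml_death"))
  }
  # CM mice: at most one terminal aml_death sample, which is their last
  for (id in unique(md$mouse_id[md$genotype == "CM"])) {
    d <- md[md$mouse_id == id, ]
    d <- d[order(d$time_months), ]
    expect_lte(sum(d$status == "aml_death"), 1)
    if (any(d$status == "aml_death"))
      expect_identical(d$status[nrow(d)], "aml_death")
  }
  # onset defined iff the latent trajectory crossed c2
  cp <- sim1$truth$true_critical_points
  for (id in names(sim1$truth$onset_months)) {
    has_onset <- !is.na(sim1$truth$onset_months[id])
    died <- any(md$status[md$mouse_id == id] == "aml_death")
    if (died) expect_true(has_onset) # death implies crossing
  }
})

test_that("a cohort with no CM mice contains only controls and no onsets", {
  sim <- simulate_cohort(cohort_config(n_cm = 0, seed = 3))
  expect_true(all(sim$dataset$metadata$genotype == "control"))
  expect_length(sim$truth$onset_months, 0)
})

test_that("most but not all CM mice transition by the end of the study", {
  # study-condition check: the proportion of CM mice developing leukemia
  # within 10 months lies strictly inside (0, 1), near the 80-90% design point
  n_aml <- 0; n_tot <- 0
  for (r in 1:20) {
    sim <- simulate_cohort(cohort_config(seed = 1000 + r))
    md <- sim$dataset$metadata
    for (id in unique(md$mouse_id[md$genotype == "CM"])) {
      n_tot <- n_tot + 1
      n_aml <- n_aml + any(md$status[md$mouse_id == id] == "aml_death")
    }
  }
  frac <- n_aml / n_tot
  expect_gt(frac, 0.6)
  expect_lt(frac, 1)
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(true_critical_points = c(-4, 1, 2)), "c3 < c2 < c1")
  expect_error(cohort_config(diffusion = 0), "diffusion")
  expect_error(cohort_config(pattern_fractions = c(monotonic_up = 1)), "named")
  bad <- c(monotonic_up = 0.5, monotonic_down = 0.2, peak_at_c2 = 0.1,
           trough_at_c2 = 0.1, null = 0.3)
  expect_error(cohort_config(pattern_fractions = bad), "sum to 1")
  cfg <- cohort_config()
  expect_equal(sum(cfg$loading_vector^2), 1, tolerance = 1e-12)
  expect_length(cfg$pattern_labels, cfg$n_features)
})
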