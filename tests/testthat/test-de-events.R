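fit_default_states <- function(seed = 42L) {
  key <- paste0("states_", seed)
  if (is.null(fixture_env[[key]])) {
    sim <- default_cohort(seed)
    nm <- normalize_counts(filter_features(sim$dataset, 5, 3))
    sp <- fit_state_space(nm)
    sel <- select_state_pc(sp, nm$metadata$marker, nm$metadata$genotype)
    sp <- orient_state_axis(sp, sel)
    coord <- state_coordinate(sp)
    md <- sim$dataset$metadata
    cm_ids <- md$sample_id[md$genotype == "CM"]
    fit <- estimate_critical_points(coord[cm_ids])
    fixture_env[[key]] <- list(sim = sim, nm = nm, sp = sp, fit = fit,
                               asn = assign_states(fit, cm_ids))
  }
  fixture_env[[key]]
}

test_that("state labels partition the CM samples by cluster membership", {
  fx <- fit_default_states()
  st <- fx$asn$state
  expect_identical(length(st), length(fx$fit$cluster))
  expect_identical(as.integer(table(st)), as.integer(table(fx$fit$cluster)))
  # samples at the cluster centers get the matching label
  expect_identical(as.character(st[which.max(fx$fit$coords)]), "c1")
  expect_identical(as.character(st[which.min(fx$fit$coords)]), "c3")
  expect_error(assign_states(fx$fit, sample_ids = "only_one"), "match")
})

test_that("terminal samples of transitioned mice are assigned to the AML state", {
  n_ok <- 0; n_tot <- 0
  for (s in c(42L, 43L, 44L)) {
    fx <- fit_default_states(s)
    md <- fx$sim$dataset$metadata
    dead <- md$sample_id[md$status == "aml_death"]
    dead <- intersect(dead, names(fx$asn$state))
    n_tot <- n_tot + length(dead)
    n_ok <- n_ok + sum(fx$asn$state[dead] == "c3")
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("identical group values give p = 1 and no DE calls", {
  fx <- fit_default_states()
  nm <- fx$nm
  nm$values[] <- 0 # every feature identical in both groups
  de <- suppressWarnings(differential_expression(nm, fx$asn, "c1"))
  expect_true(all(de$p_value == 1))
  expect_false(any(de$de))
  expect_true(all(de$degenerate))
})

test_that("too few samples at a state is an explicit failure naming the state", {
  fx <- fit_default_states()
  tiny <- fx$asn
  keep <- names(tiny$state)[tiny$state == "c2"][1]
  tiny$state <- tiny$state[keep]
  expect_error(differential_expression(fx$nm, tiny, "c2"), "state c2")
})

test_that("a planted fold change is detected with high power", {
  # 6 vs 6 samples, 4-fold change, NB-like noise on the log scale
  det <- 0
  for (r in 1:20) {
    vals <- with_seed_local(600 + r, {
      m <- matrix(stats::rnorm(12 * 50, sd = sqrt(0.1) / log(2)), 12, 50)
      m[1:6, 1] <- m[1:6, 1] + 2 # log2(4)
      m
    })
    colnames(vals) <- paste0("f", 1:50)
    rownames(vals) <- paste0("s", 1:12)
    md <- data.frame(sample_id = rownames(vals), mouse_id = rownames(vals),
                     genotype = rep(c("CM", "control"), each = 6),
                     time_months = 1, status = "alive",
                     stringsAsFactors = FALSE)
    nm <- structure(list(values = vals, feature_means = setNames(rep(0, 50), colnames(vals)),
                         pseudocount = 1, scale = 1e6, metadata = md),
                    class = "normalized_matrix")
    asn <- structure(list(state = stats::setNames(
      factor(rep("c1", 6), levels = c("c1", "c2", "c3")), rownames(vals)[1:6])),
      class = "state_assignment")
    de <- differential_expression(nm, asn, "c1")
    if (de$de[de$feature == "f1"]) det <- det + 1
  }
  expect_gte(det, 18)
})

test_that("event classification implements the set logic exactly", {
  u <- c("x", "y", "z", "w", "v", "q")
  ev <- classify_events(toy_de_table(u, c("x", "y", "z")),
                        toy_de_table(u, c("y", "z", "w")),
                        toy_de_table(u, c("z", "w", "v")))
  expect_identical(ev$early, "x")
  expect_identical(ev$transition, character(0))
  expect_identical(ev$late, "v")
  expect_identical(ev$persistent, "z")
  expect_setequal(ev$unassigned, c("y", "w"))
  # all-empty inputs give all-empty outputs
  e0 <- classify_events(toy_de_table(u, character(0)),
                        toy_de_table(u, character(0)),
                        toy_de_table(u, character(0)))
  expect_length(c(e0$early, e0$transition, e0$late, e0$persistent, e0$unassigned), 0)
  expect_error(classify_events(toy_de_table(u, "x"), toy_de_table(rev(u), "x"),
                               toy_de_table(u, "x")), "universe")
})

test_that("random DE sets classify identically to per-feature enumeration", {
  set.seed(14)
  u <- paste0("f", 1:40)
  for (rep in 1:10) {
    s1 <- sample(u, 12); s2 <- sample(u, 12); s3 <- sample(u, 12)
    ev <- classify_events(toy_de_table(u, s1), toy_de_table(u, s2),
                          toy_de_table(u, s3))
    for (f in u) {
      k <- (f %in% s1) + (f %in% s2) + (f %in% s3)
      expected <- if (k == 3) "persistent"
      else if (k == 2) "unassigned"
      else if (k == 1 && f %in% s1) "early"
      else if (k == 1 && f %in% s2) "transition"
      else if (k == 1) "late"
      else "none"
      member <- c(early = f %in% ev$early, transition = f %in% ev$transition,
                  late = f %in% ev$late, persistent = f %in% ev$persistent,
                  unassigned = f %in% ev$unassigned)
      if (expected == "none") expect_false(any(member))
      else expect_identical(names(which(member)), expected)
    }
  }
})

test_that("contribution vectors apply the leukemia-direction rule", {
  loadings <- rbind(c(-0.5, 0.3, 0.5), c(0.1, 0.2, -0.1))
  colnames(loadings) <- c("up_neg", "down_pos", "up_pos")
  sp <- toy_state_space(loadings)
  u <- colnames(loadings)
  # up-regulated feature with negative V1*: contributes toward AML (+0.5)
  t1 <- toy_de_table(u, "up_neg", lfc = c(2, 0, 0))
  t0 <- toy_de_table(u, character(0))
  ev <- classify_events(t1, t0, t0)
  cv <- contribution_vectors(ev, list(c1 = t1, c2 = t0, c3 = t0), sp)
  row <- cv[cv$class == "early", ]
  expect_equal(row$mean_v1, -0.5)
  expect_equal(row$mean_v2, 0.1)
  expect_equal(row$score, 0.5)
  # down-regulated feature with positive V1*: also toward AML (+0.3)
  t2 <- toy_de_table(u, "down_pos", lfc = c(0, -1, 0))
  ev2 <- classify_events(t2, t0, t0)
  cv2 <- contribution_vectors(ev2, list(c1 = t2, c2 = t0, c3 = t0), sp)
  expect_equal(cv2$score[1], 0.3)
  expect_identical(cv2$direction[1], "down")
  # mirrored up/down loadings give equal-magnitude opposite vectors
  t3 <- toy_de_table(u, c("up_neg", "up_pos"), lfc = c(2, 0, -2))
  ev3 <- classify_events(t3, t0, t0)
  cv3 <- contribution_vectors(ev3, list(c1 = t3, c2 = t0, c3 = t0), sp)
  expect_equal(cv3$mean_v1[cv3$direction == "up"],
               -cv3$mean_v1[cv3$direction == "down"])
})

test_that("BH discoveries shrink monotonically as the threshold tightens", {
  fx <- fit_default_states()
  n_prev <- Inf
  for (fdr in c(0.1, 0.05, 0.01, 0.001)) {
    de <- differential_expression(fx$nm, fx$asn, "c3", fdr = fdr)
    expect_lte(sum(de$de), n_prev)
    n_prev <- sum(de$de)
  }
})
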