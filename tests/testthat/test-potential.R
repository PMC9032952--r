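test_that("potential_value matches the closed form and scales linearly in alpha", {
  qp <- quasi_potential(c(1, 0, -1), alpha = 1)
  expect_equal(potential_value(qp, 0), 0)
  expect_equal(potential_value(qp, c(-1, 1)), c(-0.25, -0.25))
  x <- seq(-2, 2, length.out = 21)
  expect_equal(potential_value(qp, x), x^4 / 4 - x^2 / 2)
  qp2 <- quasi_potential(c(1, 0, -1), alpha = 2)
  expect_equal(potential_value(qp2, x), 2 * potential_value(qp, x))
})

test_that("gradient vanishes at the critical points for random valid potentials", {
  set.seed(7)
  for (i in 1:20) {
    cp <- sort(stats::rnorm(3, sd = 3), decreasing = TRUE)
    if (min(diff(rev(cp))) < 1e-3) next
    qp <- quasi_potential(cp, alpha = stats::runif(1, 0.1, 5))
    expect_equal(potential_gradient(qp, cp), rep(0, 3), tolerance = 1e-12)
    # U'' signs: minima at c1, c3; maximum at c2
    h <- 1e-5
    curv <- (potential_gradient(qp, cp + h) - potential_gradient(qp, cp - h)) / (2 * h)
    expect_true(curv[1] > 0 && curv[3] > 0 && curv[2] < 0)
  }
})

test_that("potential_value agrees with numeric quadrature of the gradient", {
  qp <- quasi_potential(c(2, 1, -4), alpha = 0.4)
  for (x in c(-5, -1.3, 0.4, 2.7)) {
    q <- stats::integrate(function(s) potential_gradient(qp, s), 0, x,
                          rel.tol = 1e-10)$value
    expect_equal(potential_value(qp, x), q, tolerance = 1e-8)
  }
})

test_that("potential constructor validates ordering and alpha", {
  expect_error(quasi_potential(c(-1, 0, 1)), "c3 < c2 < c1")
  expect_error(quasi_potential(c(1, 0, -1), alpha = -1), "alpha")
  expect_silent(quasi_potential(c(1, 0, -1), alpha = 0)) # flat allowed
})

test_that("exact 1-D K-means matches exhaustive partition search", {
  # brute force over all ordered 3-partitions of the sorted data
  brute <- function(x, k = 3) {
    o <- order(x); xs <- x[o]; n <- length(xs)
    best <- Inf; best_cut <- NULL
    for (i in 1:(n - k + 1)) for (j in (i + 1):(n - k + 2)) {
      g <- list(xs[1:i], xs[(i + 1):j], xs[(j + 1):n])
      ss <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
      if (ss < best) { best <- ss; best_cut <- c(i, j) }
    }
    best
  }
  set.seed(11)
  for (rep in 1:10) {
    x <- c(stats::rnorm(8, 0), stats::rnorm(6, 4), stats::rnorm(5, 9))
    lab <- statetrans:::kmeans_1d_exact(x, 3)
    ss <- sum(vapply(1:3, function(g) sum((x[lab == g] - mean(x[lab == g]))^2),
                     numeric(1)))
    expect_equal(ss, brute(x), tolerance = 1e-10)
    # label 1 is the most positive cluster
    m <- vapply(1:3, function(g) mean(x[lab == g]), numeric(1))
    expect_true(m[1] > m[2] && m[2] > m[3])
  }
})

test_that("boltzmann_c2 equals the exhaustive-grid oracle and ignores kB scale", {
  set.seed(3)
  for (rep in 1:10) {
    c1 <- stats::runif(1, 1, 3); c3 <- stats::runif(1, -5, -2)
    alpha <- stats::runif(1, 0.1, 2)
    cand <- seq(c3 + 0.05, c1 - 0.05, length.out = 500)
    # oracle: direct evaluation of the Boltzmann ratio on the same grid
    obj <- vapply(cand, function(x) {
      qp <- quasi_potential(c(c1, x, c3), alpha = alpha)
      -(potential_value(qp, c3) - potential_value(qp, c1))
    }, numeric(1))
    oracle <- cand[which.max(obj)]
    expect_equal(boltzmann_c2(cand, c1, c3, alpha = alpha, kB = 1), oracle)
    expect_equal(boltzmann_c2(cand, c1, c3, alpha = alpha, kB = 37.5), oracle)
    expect_equal(boltzmann_c2(cand, c1, c3, alpha = 5 * alpha, kB = 1), oracle)
  }
  expect_error(boltzmann_c2(numeric(0), 1, -1), "empty")
  expect_error(boltzmann_c2(c(0, 2), 1, -1), "inside")
})

test_that("critical points of three point masses are recovered exactly", {
  x <- c(rep(3, 10), rep(0, 10), rep(-4, 10))
  fit <- estimate_critical_points(x)
  expect_equal(fit$potential$c1, 3)
  expect_equal(fit$potential$c3, -4)
  k2 <- x[fit$cluster == 2]
  expect_true(fit$potential$c2 >= min(k2) - 1e-9 &&
              fit$potential$c2 <= max(k2) + 1e-9)
})

test_that("critical point estimation is deterministic and permutation invariant", {
  set.seed(5)
  x <- c(stats::rnorm(20, 2, 0.3), stats::rnorm(6, 0.3, 0.3), stats::rnorm(7, -4, 0.3))
  f1 <- estimate_critical_points(x)
  f2 <- estimate_critical_points(x) # no RNG involved
  expect_identical(f1$potential, f2$potential)
  p <- sample(length(x))
  f3 <- estimate_critical_points(x[p])
  expect_equal(f3$potential$c1, f1$potential$c1)
  expect_equal(f3$potential$c2, f1$potential$c2)
  expect_equal(f3$potential$c3, f1$potential$c3)
  expect_identical(f3$cluster, f1$cluster[p])
})

test_that("degenerate coordinate sets are rejected", {
  expect_error(estimate_critical_points(rep(1, 20)), "identical")
  expect_error(estimate_critical_points(c(1, 2)), "at least 9")
})

test_that("diffusion is recovered from Brownian trajectories", {
  flat <- quasi_potential(c(1, 0, -1), alpha = 0)
  ok <- 0
  for (r in 1:10) {
    trajs <- with_seed_local(800 + r, lapply(1:50, function(i)
      drop(statetrans:::sim_paths(flat, 0.5, 0:10, 0, 1L))))
    d <- estimate_diffusion(trajs)
    if (d$D / 0.5 >= 0.8 && d$D / 0.5 <= 1.2) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("diffusion estimate flags degenerate input and rescales with time units", {
  expect_warning(d0 <- estimate_diffusion(list(rep(1, 5), rep(2, 5))), "degenerate")
  expect_equal(d0$D, 0)
  expect_error(estimate_diffusion(list(1, 2)), "fewer than 2")
  flat <- quasi_potential(c(1, 0, -1), alpha = 0)
  tr <- with_seed_local(99, lapply(1:20, function(i)
    drop(statetrans:::sim_paths(flat, 0.5, 0:10, 0, 1L))))
  d_month <- estimate_diffusion(tr, max_lag = 3, dt = 1)
  d_week <- estimate_diffusion(tr, max_lag = 3, dt = 4.345)
  expect_equal(d_week$D, d_month$D / 4.345, tolerance = 1e-10)
})
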