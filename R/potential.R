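#' Double-well quasi-potential
#'
#' Constructs the quartic quasi-potential whose gradient is
#' `alpha * (x - c1) * (x - c2) * (x - c3)`.  The three critical points are
#' the stable perturbed-hematopoiesis state `c1`, the unstable transition
#' point `c2` ("point of no return") and the stable leukemic state `c3`,
#' ordered `c3 < c2 < c1` on the disease axis (disease lies at the negative
#' end).  `alpha` scales the depth of the landscape; `alpha = 0` is allowed
#' and gives a flat potential (useful for diffusion-only checks).
#'
#' @param critical_points numeric length-3 vector `(c1, c2, c3)` in
#'   state-space units with `c3 < c2 < c1`.
#' @param alpha non-negative scale of the landscape (energy per
#'   state-unit^4).
#' @return An object of class `quasi_potential` with elements `c1`, `c2`,
#'   `c3` and `alpha`.
#' @examples
#' qp <- quasi_potential(c(1, 0, -1), alpha = 1)
#' potential_value(qp, 0)      # barrier top, U = 0
#' potential_value(qp, c(-1, 1))  # the two wells, U = -0.25
#' @export
quasi_potential <- function(critical_points, alpha = 1) {
  if (length(critical_points) != 3L || !all(is.finite(critical_points)))
    stopf("'critical_points' must be three finite numbers (c1, c2, c3)")
  c1 <- critical_points[[1]]; c2 <- critical_points[[2]]; c3 <- critical_points[[3]]
  if (!(c3 < c2 && c2 < c1))
    stopf("critical points must satisfy c3 < c2 < c1 (got c1=%g, c2=%g, c3=%g)",
          c1, c2, c3)
  check_number(alpha, "alpha", lower = 0)
  structure(list(c1 = c1, c2 = c2, c3 = c3, alpha = alpha),
            class = "quasi_potential")
}

#' @export
print.quasi_potential <- function(x, ...) {
  cat(sprintf(
    "Double-well quasi-potential: c1 = %.4g, c2 = %.4g, c3 = %.4g, alpha = %.4g\n",
    x$c1, x$c2, x$c3, x$alpha))
  cat(sprintf("  barrier U(c2) - U(c1) = %.4g, well gap U(c3) - U(c1) = %.4g\n",
              potential_value(x, x$c2) - potential_value(x, x$c1),
              potential_value(x, x$c3) - potential_value(x, x$c1)))
  invisible(x)
}

#' Evaluate the quasi-potential
#'
#' Closed-form antiderivative of `alpha*(x-c1)(x-c2)(x-c3)` with integration
#' constant 0:
#' `U(x) = alpha*(x^4/4 - (c1+c2+c3) x^3/3 + (c1c2+c1c3+c2c3) x^2/2 - c1c2c3 x)`.
#'
#' @param potential a [quasi_potential()].
#' @param x numeric vector of state coordinates.
#' @return numeric vector of energies.
#' @export
potential_value <- function(potential, x) {
  stopifnot(inherits(potential, "quasi_potential"))
  c1 <- potential$c1; c2 <- potential$c2; c3 <- potential$c3
  e1 <- c1 + c2 + c3
  e2 <- c1 * c2 + c1 * c3 + c2 * c3
  e3 <- c1 * c2 * c3
  potential$alpha * (x^4 / 4 - e1 * x^3 / 3 + e2 * x^2 / 2 - e3 * x)
}

#' Gradient of the quasi-potential
#'
#' `U'(x) = alpha*(x - c1)(x - c2)(x - c3)`; the Langevin drift is `-U'(x)`.
#'
#' @inheritParams potential_value
#' @return numeric vector of gradient values.
#' @export
potential_gradient <- function(potential, x) {
  stopifnot(inherits(potential, "quasi_potential"))
  potential$alpha * (x - potential$c1) * (x - potential$c2) * (x - potential$c3)
}

# Exact 1-D K-means by dynamic programming on the sorted coordinates.
# Deterministic (no random initialisation) and permutation invariant;
# O(k n^2) which is ample for cohort-scale inputs.  Returns cluster labels
# 1..k ordered so that label 1 has the LARGEST mean (K1 = control side).
kmeans_1d_exact <- function(x, k = 3L) {
  n <- length(x)
  if (n < k) stopf("need at least %d points for %d clusters", k, k)
  o <- order(x)
  xs <- x[o]
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  ssq <- function(i, j) { # within-SS of xs[i..j]
    s <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    max(0, s2 - s^2 / (j - i + 1))
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) { cost[1, j] <- ssq(1, j); back[1, j] <- 1L }
  if (k > 1) for (q in 2:k) for (j in q:n) {
    for (i in q:j) {
      v <- cost[q - 1, i - 1] + ssq(i, j)
      if (v < cost[q, j]) { cost[q, j] <- v; back[q, j] <- i }
    }
  }
  lab_sorted <- integer(n)
  j <- n
  for (q in k:1) { i <- back[q, j]; lab_sorted[i:j] <- q; j <- i - 1 }
  # q runs 1..k from most negative; relabel so 1 = most positive cluster
  lab <- integer(n)
  lab[o] <- (k + 1L) - lab_sorted
  lab
}

#' Estimate the transition critical point by the Boltzmann ratio
#'
#' For each candidate position `x`, the quasi-potential is rebuilt with
#' critical points `(c1, x, c3)` and the Boltzmann ratio between the
#' leukemic and non-leukemic wells,
#' `exp(-(U(c3) - U(c1)) / kB)`, is evaluated; the candidate maximizing the
#' ratio is returned (exact ties broken toward the midpoint of `(c3, c1)`).
#' The objective is monotone in the candidate, so on cluster-restricted
#' candidates the estimate lands at the K1-side edge of the middle cluster
#' -- the transition point is best identified near the K1/K2 boundary.
#' The argmax is invariant to `alpha` and to rescaling `kB` (both apply a
#' monotone transform to the objective).
#'
#' @param candidates numeric vector of candidate positions, all inside
#'   `(c3, c1)`.
#' @param c1,c3 the outer critical points.
#' @param alpha potential scale used to build candidate potentials.
#' @param kB Boltzmann-like fluctuation scale (> 0).
#' @return the selected candidate position (length-1 numeric).
#' @export
boltzmann_c2 <- function(candidates, c1, c3, alpha = 1, kB = 1) {
  if (length(candidates) == 0L) stopf("empty candidate set for c2")
  check_number(kB, "kB", lower = .Machine$double.xmin)
  if (any(candidates <= c3 | candidates >= c1))
    stopf("all c2 candidates must lie strictly inside (c3, c1)")
  delta <- vapply(candidates, function(x) {
    qp <- quasi_potential(c(c1, x, c3), alpha = alpha)
    potential_value(qp, c3) - potential_value(qp, c1)
  }, numeric(1))
  obj <- -delta / kB # log of the Boltzmann ratio; monotone, overflow-safe
  best <- which(obj == max(obj))
  if (length(best) > 1L) {
    mid <- (c1 + c3) / 2
    best <- best[which.min(abs(candidates[best] - mid))]
  }
  candidates[[best]]
}

#' Estimate the critical points from CM state coordinates
#'
#' Exact 1-D K-means with K = 3 partitions the disease-axis coordinates of
#' the CM samples into clusters K1 (control side, most positive), K2
#' (transition) and K3 (leukemic, most negative).  `c1` and `c3` are the
#' means of K1 and K3; `c2` is the Boltzmann-ratio estimate over candidates
#' drawn from K2 (the observed K2 coordinates plus a 200-point uniform grid
#' over the K2 range, clipped inside `(c3, c1)`).
#'
#' @param cm_state_coords numeric vector of CM sample coordinates on the
#'   disease axis (at least 9 values).
#' @param alpha potential scale forwarded to [boltzmann_c2()]; the c2
#'   argmax does not depend on it.
#' @param kB fluctuation scale forwarded to [boltzmann_c2()].
#' @return An object of class `critical_point_fit`: `potential` (a
#'   [quasi_potential()] with the estimated points), `cluster` (per-sample
#'   labels 1, 2, 3 for K1, K2, K3), `c2_candidates`, `kB`, `alpha`.
#' @export
estimate_critical_points <- function(cm_state_coords, alpha = 1, kB = 1) {
  x <- as.numeric(cm_state_coords)
  if (any(!is.finite(x))) stopf("non-finite state coordinates")
  if (length(x) < 9L)
    stopf("need at least 9 CM samples (3 per cluster), got %d", length(x))
  if (diff(range(x)) < .Machine$double.eps^0.5)
    stopf("all CM coordinates are identical; no 3-cluster structure")
  lab <- kmeans_1d_exact(x, 3L)
  k2 <- x[lab == 2L]
  if (length(k2) == 0L)
    stopf("middle cluster K2 is empty after K-means; cannot place c2")
  c1 <- mean(x[lab == 1L])
  c3 <- mean(x[lab == 3L])
  lo <- max(min(k2), c3 + 1e-9 * (c1 - c3))
  hi <- min(max(k2), c1 - 1e-9 * (c1 - c3))
  grid <- if (hi > lo) seq(lo, hi, length.out = 200L) else numeric(0)
  cand <- sort(unique(c(k2[k2 > c3 & k2 < c1], grid)))
  if (length(cand) == 0L)
    stopf("no c2 candidates inside (c3, c1); K2 spans [%g, %g]", min(k2), max(k2))
  c2 <- boltzmann_c2(cand, c1 = c1, c3 = c3, alpha = alpha, kB = kB)
  structure(list(
    potential = quasi_potential(c(c1, c2, c3), alpha = alpha),
    cluster = lab,
    coords = x,
    c2_candidates = cand,
    alpha = alpha,
    kB = kB
  ), class = "critical_point_fit")
}

#' @export
print.critical_point_fit <- function(x, ...) {
  p <- x$potential
  cat(sprintf("Critical-point fit (exact 1-D K-means, K = 3, n = %d)\n",
              length(x$coords)))
  cat(sprintf("  c1 = %.4g (K1 n = %d), c2 = %.4g (K2 n = %d), c3 = %.4g (K3 n = %d)\n",
              p$c1, sum(x$cluster == 1), p$c2, sum(x$cluster == 2),
              p$c3, sum(x$cluster == 3)))
  invisible(x)
}

#' Estimate the diffusion coefficient from state-space trajectories
#'
#' The mean squared displacement (MSD) is averaged over mice and over all
#' (overlapping) time origins for integer lags up to `max_lag` months;
#' the diffusion coefficient is half the slope of the least-squares fit of
#' MSD against lag through the origin, as for Brownian motion where
#' `MSD(tau) = 2 D tau`.
#'
#' @param trajectories a list of numeric vectors (one per mouse) of
#'   time-ordered state coordinates at unit (monthly) spacing, or a single
#'   numeric vector.
#' @param max_lag largest lag (months) entering the fit; default 3.
#' @param dt spacing of observations in months (default 1).
#' @return An object of class `diffusion_estimate` with `D`, `msd` (per-lag
#'   values), `lags`, `slope` and `n_pairs`.
#' @export
estimate_diffusion <- function(trajectories, max_lag = 3L, dt = 1) {
  if (is.numeric(trajectories)) trajectories <- list(trajectories)
  if (!length(trajectories)) stopf("no trajectories supplied")
  check_number(dt, "dt", lower = .Machine$double.xmin)
  lens <- vapply(trajectories, length, integer(1))
  if (all(lens < 2L)) stopf("all trajectories have fewer than 2 observations")
  max_lag <- min(as.integer(max_lag), max(lens) - 1L)
  if (max_lag < 1L) stopf("max_lag must allow at least lag 1")
  msd <- numeric(max_lag)
  npr <- integer(max_lag)
  for (l in seq_len(max_lag)) {
    sq <- 0; np <- 0L
    for (tr in trajectories) {
      n <- length(tr)
      if (n > l) {
        d <- tr[(l + 1):n] - tr[1:(n - l)]
        sq <- sq + sum(d^2)
        np <- np + (n - l)
      }
    }
    msd[l] <- if (np > 0) sq / np else NA_real_
    npr[l] <- np
  }
  lags <- seq_len(max_lag) * dt
  use <- !is.na(msd)
  if (!any(use)) stopf("no lag had any displacement pairs")
  slope <- sum(lags[use] * msd[use]) / sum(lags[use]^2)
  D <- slope / 2
  degenerate <- D <= 0 || all(msd[use] == 0)
  if (degenerate)
    warnf("degenerate MSD (all displacements zero); diffusion estimate is 0")
  structure(list(D = D, msd = msd, lags = lags, slope = slope,
                 n_pairs = npr, degenerate = degenerate),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Diffusion estimate: D = %.4g state-units^2/month (MSD slope %.4g over %d lags)\n",
              x$D, x$slope, length(x$lags)))
  invisible(x)
}
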