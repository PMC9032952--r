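#' Spatial/temporal grid for the Fokker--Planck solver
#'
#' @param x_min,x_max domain limits (state units); the domain must pad the
#'   outer critical points by at least 2 state units so that the no-flux
#'   boundaries do not influence the density near the wells.
#' @param n_x number of spatial nodes (>= 200).
#' @param t_max horizon in months.
#' @param n_t number of saved output times (evenly spaced on `[0, t_max]`,
#'   including both ends).
#' @return An object of class `fp_grid`.
#' @export
fp_grid <- function(x_min, x_max, n_x = 800L, t_max, n_t = NULL) {
  if (x_min >= x_max) stopf("x_min must be < x_max")
  n_x <- as.integer(n_x)
  if (n_x < 200L) stopf("n_x must be >= 200")
  check_number(t_max, "t_max", lower = .Machine$double.xmin)
  if (is.null(n_t)) n_t <- max(2L, round(t_max * 10) + 1L)
  structure(list(x_min = x_min, x_max = x_max, n_x = n_x,
                 t_max = t_max, n_t = as.integer(n_t)),
            class = "fp_grid")
}

# default grid padding the critical points
default_fp_grid <- function(potential, t_max, n_x = 800L, n_t = NULL) {
  pad <- max(2.1, 0.35 * (potential$c1 - potential$c3))
  fp_grid(potential$c3 - pad, potential$c1 + pad, n_x = n_x,
          t_max = t_max, n_t = n_t)
}

#' Solve the Fokker--Planck equation of the state-transition model
#'
#' Solves the drift--diffusion equation
#' `dP/dt = d/dx(U'(x) P) + D d^2P/dx^2`
#' (the transport equation of the Langevin dynamics `dX = -U' dt +
#' sqrt(2D) dB`) with a conservative exponential-fitting
#' (Scharfetter--Gummel) finite-volume discretization, no-flux boundaries
#' and Crank--Nicolson time stepping (a few backward-Euler start steps
#' damp initial-layer oscillations).  The discrete stationary solution is
#' exactly the Boltzmann density `exp(-U/D)` on the grid, and total mass
#' is conserved to solver precision.
#'
#' The initial condition is a Gaussian with the given mean and standard
#' deviation, normalized on the grid.
#'
#' @param potential a [quasi_potential()].
#' @param D diffusion coefficient (> 0), same units as the Langevin noise.
#' @param init_mean,init_sd Gaussian initial condition; `init_sd` is
#'   floored at 0.1 state units.
#' @param grid an [fp_grid()]; default pads the critical points.
#' @param dt internal time step in months (default 0.01).
#' @param convention `"langevin"` (default) solves the equation whose
#'   solutions match the Langevin ensemble; `"printed"` flips the drift
#'   sign to the literal transport form `-d/dx(U' P)` for archaeology.
#' @return An object of class `fp_solution`: `x` (nodes), `times`,
#'   `density` (n_x x n_t matrix, each column integrating to 1), `dx`,
#'   `potential`, `D`, `init`.
#' @export
solve_fp <- function(potential, D, init_mean, init_sd, grid = NULL,
                     dt = 0.01, convention = c("langevin", "printed")) {
  stopifnot(inherits(potential, "quasi_potential"))
  convention <- match.arg(convention)
  check_number(D, "D", lower = .Machine$double.xmin)
  if (is.null(grid)) stopf("an fp_grid must be supplied (see fp_grid())")
  stopifnot(inherits(grid, "fp_grid"))
  init_sd <- max(init_sd, 0.1)
  x <- seq(grid$x_min, grid$x_max, length.out = grid$n_x)
  dx <- x[2] - x[1]
  U <- potential_value(potential, x)
  p0 <- stats::dnorm(x, init_mean, init_sd)
  s0 <- sum(p0) * dx
  if (s0 <= 0) stopf("initial Gaussian has no mass on the grid")
  p0 <- p0 / s0
  times <- seq(0, grid$t_max, length.out = grid$n_t)
  n_steps <- ceiling(grid$t_max / dt - 1e-9)
  dt_eff <- grid$t_max / n_steps
  save_steps <- round(times / dt_eff)
  dens <- fp_solve_cpp(U, D, dx, p0, dt_eff, n_steps,
                       as.integer(save_steps),
                       flip_drift = (convention == "printed"),
                       n_rannacher = 4L)
  # report densities at the exact saved steps; re-normalize display copy
  structure(list(x = x, times = times, density = dens, dx = dx,
                 potential = potential, D = D,
                 init = c(mean = init_mean, sd = init_sd),
                 convention = convention),
            class = "fp_solution")
}

#' @export
print.fp_solution <- function(x, ...) {
  cat(sprintf("Fokker-Planck solution: %d nodes on [%.3g, %.3g], %d times to %.3g months (D = %.3g)\n",
              length(x$x), min(x$x), max(x$x), length(x$times),
              max(x$times), x$D))
  invisible(x)
}

#' Probability of having transitioned past the critical point
#'
#' `F(t)` integrates the density from the lower domain edge to `c2`
#' (leukemia occupies the negative end of the axis).  Because mass can
#' re-cross the unstable point, an optional running-maximum envelope
#' (default on) reports the non-decreasing transition-probability curve
#' used for survival prediction; the raw integral is kept alongside.
#'
#' @param solution an `fp_solution`.
#' @param c2 the transition critical point (must lie inside the grid);
#'   default is the solution potential's `c2`.
#' @param envelope logical; apply the running maximum (default TRUE).
#' @return An object of class `transition_curve`: `times`, `probability`
#'   (envelope if requested), `raw_probability`, `c2`, `envelope`.
#' @export
transition_probability <- function(solution, c2 = NULL, envelope = TRUE) {
  stopifnot(inherits(solution, "fp_solution"))
  if (is.null(c2)) c2 <- solution$potential$c2
  x <- solution$x
  if (c2 <= min(x) || c2 >= max(x)) stopf("c2 must lie inside the grid")
  dx <- solution$dx
  # cell mass below c2, fractional cell at the boundary
  w <- pmin(pmax((c2 - (x - dx / 2)) / dx, 0), 1)
  raw <- as.numeric(w %*% solution$density) * dx
  mass <- colSums(solution$density) * dx
  raw <- raw / mass
  prob <- if (envelope) cummax(raw) else raw
  structure(list(times = solution$times, probability = prob,
                 raw_probability = raw, c2 = c2, envelope = envelope),
            class = "transition_curve")
}

#' @export
print.transition_curve <- function(x, ...) {
  cat(sprintf("Transition curve: F(%.3g) = %.3f over %d times (c2 = %.3g%s)\n",
              max(x$times), x$probability[length(x$probability)],
              length(x$times), x$c2,
              if (x$envelope) ", envelope" else ""))
  invisible(x)
}

#' Consistency check between the Fokker--Planck and Langevin faces
#'
#' Simulates an Euler--Maruyama ensemble under the same potential,
#' diffusion and Gaussian initial condition, and compares the empirical
#' fraction of paths below `c2` at each requested time against the raw
#' Fokker--Planck transition probability.  The tolerance at each time is
#' `3 * binomial SE + 0.02`.
#'
#' @param potential a [quasi_potential()].
#' @param D diffusion coefficient.
#' @param init `c(mean, sd)` of the Gaussian initial condition.
#' @param n_paths ensemble size (>= 1000).
#' @param t_grid times at which to compare (months, starting at 0).
#' @param seed integer seed for the ensemble.
#' @param convention forwarded to [solve_fp()]; `"printed"` deliberately
#'   breaks the drift sign and should fail the check.
#' @return A list: `times`, `fp` (F(t)), `empirical`, `tolerance`,
#'   `max_discrepancy`, `pass`.
#' @export
fp_vs_langevin_check <- function(potential, D, init, n_paths = 5000L,
                                 t_grid = 0:10, seed = 1L,
                                 convention = c("langevin", "printed")) {
  convention <- match.arg(convention)
  if (n_paths < 1000L) stopf("n_paths must be >= 1000")
  grid <- default_fp_grid(potential, t_max = max(t_grid))
  sol <- solve_fp(potential, D, init[1], init[2], grid,
                  convention = convention)
  tc <- transition_probability(sol, envelope = FALSE)
  fp_at <- stats::approx(tc$times, tc$raw_probability, xout = t_grid)$y
  paths <- with_seed(seed, {
    x0 <- stats::rnorm(n_paths, init[1], max(init[2], 0.1))
    sim_paths(potential, D, t_grid, x0, n_paths)
  })
  emp <- rowMeans(paths < potential$c2)
  tol <- 3 * sqrt(pmax(fp_at * (1 - fp_at), 1e-12) / n_paths) + 0.02
  disc <- abs(emp - fp_at)
  list(times = t_grid, fp = fp_at, empirical = emp, tolerance = tol,
       max_discrepancy = max(disc), pass = all(disc <= tol))
}
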