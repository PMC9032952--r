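#' Fit the full state-transition model on a training cohort
#'
#' Runs the training pipeline: feature filtering, CPM/log2/centering,
#' SVD state-space, marker-based selection and phenotype-anchored
#' orientation of the disease axis, critical-point estimation on the CM
#' state coordinates, diffusion estimation from per-mouse state
#' trajectories, and calibration of the potential scale `alpha` so that
#' the Fokker--Planck median transition time matches the training
#' cohort's observed median time-to-leukemia.
#'
#' @param dataset training [expression_dataset()] whose metadata carries a
#'   `marker` column.
#' @param min_count,min_samples feature filter thresholds.
#' @param fdr not used here (reserved for DE stages).
#' @param max_lag MSD lags for diffusion estimation.
#' @param alpha_bounds search interval for the potential-scale
#'   calibration (log-uniform bracket).
#' @return An object of class `state_transition_model`: `space`,
#'   `selection`, `fit` (critical points), `assignment`, `diffusion`,
#'   `alpha`, `potential` (calibrated), `normalized`, `init_train`
#'   (mean/sd of the month-1 CM state coordinates).
#' @export
fit_state_transition <- function(dataset, min_count = 5, min_samples = 3,
                                 fdr = 0.05, max_lag = 3L,
                                 alpha_bounds = c(1e-3, 10)) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$metadata$marker)) stopf("metadata must carry a 'marker' column")
  filtered <- filter_features(dataset, min_count, min_samples)
  norm <- normalize_counts(filtered)
  space <- fit_state_space(norm)
  sel <- select_state_pc(space, dataset$metadata$marker,
                         ifelse(dataset$metadata$genotype == "CM", "CM", "control"))
  space <- orient_state_axis(space, sel)
  coord <- state_coordinate(space)
  md <- dataset$metadata
  is_cm <- md$genotype == "CM"
  cpf <- estimate_critical_points(coord[md$sample_id[is_cm]])
  assignment <- assign_states(cpf, md$sample_id[is_cm])
  # per-mouse CM state trajectories, monthly order
  trajs <- lapply(split(seq_len(nrow(md))[is_cm], md$mouse_id[is_cm]), function(i) {
    i <- i[order(md$time_months[i])]
    unname(coord[md$sample_id[i]])
  })
  diff_est <- estimate_diffusion(trajs, max_lag = max_lag)
  cpf$kB <- diff_est$D
  obs <- observed_survival(dataset)
  init <- init_condition(coord, md, month = 1, c2 = cpf$potential$c2)
  alpha <- calibrate_alpha(cpf$potential, diff_est$D, init,
                           obs, t_max = max(md$time_months),
                           bounds = alpha_bounds)
  potential <- quasi_potential(c(cpf$potential$c1, cpf$potential$c2,
                                 cpf$potential$c3), alpha = alpha)
  structure(list(space = space, selection = sel, fit = cpf,
                 assignment = assignment, diffusion = diff_est,
                 alpha = alpha, potential = potential,
                 normalized = norm, init_train = init),
            class = "state_transition_model")
}

#' @export
print.state_transition_model <- function(x, ...) {
  p <- x$potential
  cat(sprintf("State-transition model: axis PC%d, c = (%.3g, %.3g, %.3g), alpha = %.3g, D = %.3g\n",
              x$space$state_pc_index, p$c1, p$c2, p$c3, p$alpha, x$diffusion$D))
  invisible(x)
}

# Gaussian initial condition from the first post-induction CM samples.
# The time-to-transition question is posed for mice still at risk, so
# samples already past the transition point c2 at the initial month are
# excluded (for cohorts where no mouse has transitioned by month 1 this
# is a no-op).
init_condition <- function(coord, metadata, month = 1, c2 = NULL) {
  i <- metadata$genotype == "CM" & metadata$time_months == month
  if (!any(i)) { # fall back to the earliest CM month available
    mo <- sort(unique(metadata$time_months[metadata$genotype == "CM"]))
    month <- mo[1]
    i <- metadata$genotype == "CM" & metadata$time_months == month
  }
  v <- coord[metadata$sample_id[i]]
  if (!is.null(c2)) {
    at_risk <- v > c2
    if (any(at_risk)) v <- v[at_risk]
    else warnf("all month-%g CM samples lie past c2; using all for the initial condition", month)
  }
  c(mean = mean(v), sd = max(stats::sd(v), 0.1, na.rm = TRUE))
}

# Calibrate the potential scale so the FP median transition time matches
# the observed median time-to-leukemia (1-D root finding on log alpha;
# coarse grid during the search).  Larger alpha deepens the barrier and
# slows transition, so the objective is monotone.
calibrate_alpha <- function(potential, D, init, observed, t_max,
                            bounds = c(1e-3, 10)) {
  subj <- observed$subjects
  if (sum(subj$event) < 1L) stopf("no observed events; cannot calibrate alpha")
  # empirical transition fraction at event times; median = first t with F >= 0.5
  tt <- sort(subj$time[subj$event == 1])
  Fobs <- seq_along(tt) / nrow(subj)
  t_med <- tt[which(Fobs >= 0.5)[1]]
  target <- if (is.na(t_med)) { # fewer than half transition: anchor at the last event
    t_med <- tt[length(tt)]
    Fobs[length(Fobs)]
  } else 0.5
  f_at_tmed <- function(log_a) {
    qp <- quasi_potential(c(potential$c1, potential$c2, potential$c3),
                          alpha = exp(log_a))
    grid <- default_fp_grid(qp, t_max = t_med, n_x = 400L,
                            n_t = max(2L, round(t_med) + 1L))
    sol <- solve_fp(qp, D, init["mean"], init["sd"], grid, dt = 0.02)
    tc <- transition_probability(sol)
    tc$probability[length(tc$probability)] - target
  }
  lo <- log(bounds[1]); hi <- log(bounds[2])
  flo <- f_at_tmed(lo); fhi <- f_at_tmed(hi)
  if (flo <= 0) return(bounds[1]) # even the flattest potential is too slow
  if (fhi >= 0) return(bounds[2]) # even the deepest is too fast (unlikely)
  exp(stats::uniroot(f_at_tmed, c(lo, hi), tol = 0.02)$root)
}

#' Predict time-to-leukemia for a projected cohort
#'
#' Solves the Fokker--Planck equation with the training-derived potential
#' and diffusion, a Gaussian initial condition from the cohort's first
#' post-induction CM state coordinates, and returns the transition curve
#' and predicted survival.
#'
#' @param model a `state_transition_model`.
#' @param dataset validation [expression_dataset()].
#' @param seed seed for the predicted pseudo-cohort draw.
#' @return A list: `coord` (projected state coordinates), `curve`,
#'   `predicted` (`survival_data` with a pseudo-cohort the size of the
#'   validation CM cohort), `observed` (`survival_data`), `init`.
#' @export
predict_time_to_aml <- function(model, dataset, seed = 1L) {
  stopifnot(inherits(model, "state_transition_model"),
            inherits(dataset, "expression_dataset"))
  normv <- apply_normalization(dataset, model$normalized)
  coord <- project_state_coordinate(model$space, normv)
  md <- dataset$metadata
  if (!any(md$genotype == "CM")) stopf("validation cohort has no CM mice")
  init <- init_condition(coord, md, month = 1, c2 = model$potential$c2)
  t_max <- max(md$time_months)
  months <- seq(0, t_max, by = 1)
  grid <- default_fp_grid(model$potential, t_max = t_max)
  sol <- solve_fp(model$potential, model$diffusion$D, init["mean"], init["sd"], grid)
  curve <- transition_probability(sol)
  obs <- observed_survival(dataset)
  pred <- predicted_survival(curve, months, n = nrow(obs$subjects), seed = seed)
  list(coord = coord, curve = curve, predicted = pred, observed = obs,
       init = init, solution = sol)
}

#' End-to-end prediction check on paired synthetic cohorts
#'
#' Full pipeline: fit the state-transition model on the training cohort,
#' project the validation cohort, predict its survival from the
#' Fokker--Planck solution, and compare predicted with observed survival
#' by the log-rank test.  A prediction consistent with observation fails
#' to reject (p > 0.05).
#'
#' @param train,validate [expression_dataset()]s generated from one
#'   [cohort_config()] family.
#' @param seed pseudo-cohort seed.
#' @return A list: `p_value`, `hazard_ratio`, `pass` (p > 0.05), `model`,
#'   `prediction`.
#' @export
end_to_end_prediction_check <- function(train, validate, seed = 1L) {
  model <- fit_state_transition(train)
  pred <- predict_time_to_aml(model, validate, seed = seed)
  lr <- logrank_test(pred$predicted, pred$observed)
  list(p_value = lr$p_value, hazard_ratio = lr$hazard_ratio,
       pass = lr$p_value > 0.05, logrank = lr,
       model = model, prediction = pred)
}
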