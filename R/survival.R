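#' Predicted survival from a transition curve
#'
#' Evaluates `S(t) = 1 - F(t)` at the experimental observation times and
#' instantiates the model curve as a pseudo-cohort for comparison with an
#' observed cohort: event times are assigned by the inverse CDF of `F(t)`
#' restricted to the evaluation grid (a subject with `u > F(t_end)` is
#' censored at `t_end`).  By default the `u` are stratified quantiles
#' `(i - 1/2)/n`, so the pseudo-cohort is the deterministic discrete
#' representation of the curve and the comparison carries no sampling
#' noise; random draws under a fixed seed are available with
#' `stratified = FALSE`.
#'
#' @param curve a `transition_curve` (envelope recommended).
#' @param eval_times observation times (months) within the curve range.
#' @param n pseudo-cohort size (default: 0 = no pseudo-cohort, survival
#'   probabilities only).
#' @param seed seed for the inverse-CDF draw (used when `stratified =
#'   FALSE`).
#' @param stratified use stratified quantiles instead of random draws.
#' @return An object of class `survival_data`: `eval_times`, `surv`
#'   (S(t)), `expected_events` (n * F(t) when n > 0), and `subjects`
#'   (data.frame subject/time/event; event 1 = leukemia, 0 = censored)
#'   with `group = "predicted"`.
#' @export
predicted_survival <- function(curve, eval_times, n = 0L, seed = 1L,
                               stratified = TRUE) {
  stopifnot(inherits(curve, "transition_curve"))
  if (any(eval_times < min(curve$times) - 1e-9) ||
      any(eval_times > max(curve$times) + 1e-9))
    stopf("eval_times must lie within the curve range")
  Fv <- stats::approx(curve$times, curve$probability, xout = eval_times,
                      rule = 2)$y
  Fv <- cummax(pmin(pmax(Fv, 0), 1)) # monotone on the evaluation grid
  subjects <- NULL
  if (n > 0) {
    u <- if (stratified) (seq_len(n) - 0.5) / n
         else with_seed(seed, stats::runif(n))
    t_end <- eval_times[length(eval_times)]
    idx <- vapply(u, function(ui) {
      i <- which(Fv >= ui)[1]
      if (is.na(i)) NA_integer_ else i
    }, integer(1))
    subjects <- data.frame(
      subject = sprintf("pred%02d", seq_len(n)),
      time = ifelse(is.na(idx), t_end, eval_times[idx]),
      event = as.integer(!is.na(idx)),
      group = "predicted", stringsAsFactors = FALSE)
  }
  structure(list(eval_times = eval_times, surv = 1 - Fv,
                 expected_events = if (n > 0) n * Fv else NULL,
                 subjects = subjects, group = "predicted"),
            class = "survival_data")
}

#' Observed survival data from cohort metadata
#'
#' Extracts per-mouse time-to-leukemia from an [expression_dataset()]'s
#' metadata: CM mice with a terminal `aml_death` sample contribute an
#' event at that time; all other CM mice are censored at their last
#' observation.
#'
#' @param dataset an [expression_dataset()] (or its metadata data.frame).
#' @return A `survival_data` with `group = "observed"`.
#' @export
observed_survival <- function(dataset) {
  md <- if (inherits(dataset, "expression_dataset")) dataset$metadata else dataset
  md <- md[md$genotype == "CM", , drop = FALSE]
  if (!nrow(md)) stopf("no CM mice in the cohort")
  subjects <- do.call(rbind, lapply(split(md, md$mouse_id), function(d) {
    d <- d[order(d$time_months), , drop = FALSE]
    last <- d[nrow(d), ]
    data.frame(subject = last$mouse_id, time = last$time_months,
               event = as.integer(last$status == "aml_death"),
               group = "observed", stringsAsFactors = FALSE)
  }))
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, group = "observed"),
            class = "survival_data")
}

#' Log-rank comparison of two survival curves
#'
#' Standard log-rank chi-square (1 df) over the pooled event times with
#' censoring, via [survival::survdiff()]; the hazard ratio is the
#' Mantel--Haenszel observed/expected ratio with a log-scale normal
#' confidence interval.
#'
#' @param a,b `survival_data` objects carrying `subjects` tables.
#' @param conf_level confidence level for the HR interval.
#' @return An object of class `logrank_result`: `chi_square`, `p_value`,
#'   `hazard_ratio` (group a relative to group b), `hr_ci`, `n_events`.
#' @export
logrank_test <- function(a, b, conf_level = 0.95) {
  sa <- a$subjects; sb <- b$subjects
  if (is.null(sa) || is.null(sb) || !nrow(sa) || !nrow(sb))
    stopf("both groups must carry subjects")
  df <- rbind(sa[c("time", "event")], sb[c("time", "event")])
  df$grp <- factor(rep(c("a", "b"), c(nrow(sa), nrow(sb))), c("a", "b"))
  if (sum(df$event) == 0)
    stopf("no events in either group; the log-rank test is undefined")
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  chi <- fit$chisq
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  O <- fit$obs; E <- fit$exp
  hr <- if (E[1] > 0 && E[2] > 0 && O[2] > 0) (O[1] / E[1]) / (O[2] / E[2]) else NA_real_
  se <- if (E[1] > 0 && E[2] > 0) sqrt(1 / E[1] + 1 / E[2]) else NA_real_
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.finite(hr) && hr > 0) exp(log(hr) + c(-1, 1) * z * se) else c(NA, NA)
  structure(list(chi_square = chi, p_value = p, hazard_ratio = hr,
                 hr_ci = ci, n_events = c(a = O[1], b = O[2]),
                 expected = c(a = E[1], b = E[2])),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi^2 = %.3f, p = %.3g; HR = %.3g (%.3g-%.3g)\n",
              x$chi_square, x$p_value, x$hazard_ratio, x$hr_ci[1], x$hr_ci[2]))
  invisible(x)
}
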