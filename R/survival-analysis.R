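#' Kaplan-Meier survival estimate as a tibble
#'
#' Product-limit estimator via [survival::survfit()]; with no censoring
#' this equals the empirical survival function. Tied censored subjects
#' are counted as at risk for a tied event (the standard convention).
#'
#' @param times Follow-up times in years (non-negative).
#' @param events Logical event indicators (`TRUE` = death).
#' @return Tibble with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (non-increasing, starting from 1).
#' @examples
#' km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0 || length(times) != length(events)) {
    abort_domain("need non-empty, equal-length times and events")
  }
  check_nonneg(times, "times")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' Per-arm Kaplan-Meier curves for a trial table
#'
#' @param trial Patient-level tibble with `arm`, `survival_years`, `died`.
#' @return Tibble of per-arm [km_estimate()] rows with an `arm` column.
#' @export
km_by_arm <- function(trial) {
  trial |>
    group_by(.data$arm) |>
    dplyr::reframe(km_estimate(.data$survival_years, .data$died))
}

#' Survival fractions at a fixed horizon
#'
#' With complete follow-up to the horizon (as in a trial where every
#' patient is traced for the full 5 years), the alive fraction at the
#' horizon is a simple count; any patient censored before the horizon is
#' an error rather than silently treated as alive.
#'
#' @param trial Patient-level tibble with `arm`, `survival_years`, `died`.
#' @param horizon_years Horizon (e.g. 1, 2 or 5).
#' @return Tibble per arm: `alive`, `n`, `percent` (whole percent, as
#'   survival tables print it).
#' @examples
#' trial <- generate_trial(trial_config(), seed = 1)
#' survival_at(trial, 2)
#' @export
survival_at <- function(trial, horizon_years) {
  check_nonneg(horizon_years, "horizon_years")
  censored_early <- !trial$died & trial$survival_years < horizon_years
  if (any(censored_early)) {
    abort_domain("follow-up incomplete: censoring before the horizon")
  }
  trial |>
    group_by(.data$arm) |>
    summarise(alive = sum(.data$survival_years >= horizon_years),
              n = n(), .groups = "drop") |>
    mutate(percent = round_pounds(100 * .data$alive / .data$n))
}

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L))) abort_domain("need a 2 x 2 table")
  if (any(m < 0) || any(m != round(m))) {
    abort_domain("cell counts must be non-negative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort_domain("all margins must be positive")
  }
  m
}

#' Fisher exact test on a 2 x 2 table
#'
#' Two-sided exact p-value under the probability-mass criterion: the sum
#' of hypergeometric probabilities of all tables with the observed
#' margins that are no more probable than the observed table.
#'
#' @param table 2 x 2 matrix of counts (rows = arms, columns = outcome).
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(reference_survival_table("all", 2))
#' @export
fisher_exact <- function(table) {
  m <- as_2x2(table)
  fisher.test(m)$p.value
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Continuity correction is off by default (the assignments and p-values
#' of the motivating trial's survival tables reproduce without it); set
#' `correct = TRUE` for Yates' correction.
#'
#' @param table 2 x 2 matrix of counts.
#' @param correct Apply Yates' continuity correction?
#' @return Two-sided p-value on 1 degree of freedom.
#' @examples
#' chisq_2x2(reference_survival_table("all", 5))
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  m <- as_2x2(table)
  suppressWarnings(chisq.test(m, correct = correct)$p.value)
}

#' Choose Fisher exact or chi-square by sample size
#'
#' Concrete small-sample rule: use the Fisher exact test when any
#' observed or expected cell count is below 5, otherwise the chi-square
#' test. (Cochran's classic rule looks only at expected counts; extending
#' it to observed cells reproduces the test assignments of the motivating
#' trial's survival tables at every horizon and subgroup.)
#'
#' @param table 2 x 2 matrix of counts.
#' @return `"fisher"` or `"chisq"`.
#' @examples
#' select_test(reference_survival_table("all", 2)) # small death cells
#' select_test(reference_survival_table("all", 5)) # all cells large
#' @export
select_test <- function(table) {
  m <- as_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(m < 5) || any(expected < 5)) "fisher" else "chisq"
}

#' Compare arm survival at a horizon with the sample-size-chosen test
#'
#' @param table 2 x 2 matrix (rows = arms, columns = alive/dead).
#' @return Tibble: `test` used and `p_value`.
#' @export
compare_survival <- function(table) {
  test <- select_test(table)
  p <- if (test == "fisher") fisher_exact(table) else chisq_2x2(table)
  tibble(test = test, p_value = p)
}
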