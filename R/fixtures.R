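#' Published group-level summaries from the motivating trial
#'
#' Group-level results reported by the randomized trial of an enhanced
#' recovery program (ERP) for open liver resection that this package's
#' analyses are designed around: survival counts at fixed horizons
#' (overall and for the malignant-disease and colorectal-metastasis
#' subgroups), community resource-use totals, and group cost and
#' quality-of-life summaries. Patient-level data were never deposited, so
#' these printed summaries serve as worked-example inputs and as fixtures
#' for the arithmetic the package automates.
#'
#' @return A list with tibbles `survival` (subgroup, horizon_years, arm,
#'   alive, n), `counts` (measure, arm, value) and `summaries`
#'   (measure, arm, value).
#' @examples
#' reference_summaries()$survival
#' @export
reference_summaries <- function() {
  surv <- tibble(
    subgroup = rep(c("all", "malignant", "colorectal"), each = 6),
    horizon_years = rep(rep(c(1, 2, 5), each = 2), times = 3),
    arm = rep(c("ERP", "STANDARD"), times = 9),
    alive = c(45, 41, 42, 33, 24, 23,
              44, 32, 41, 24, 23, 16,
              34, 23, 32, 18, 16, 14),
    n = c(rep(c(46, 45), 3), rep(c(45, 36), 3), rep(c(35, 26), 3))
  )
  counts <- tibble(
    measure = rep(c("gp_total_visits", "practice_nurse_total_visits",
                    "nurse_home_total_visits", "friends_family_events"),
                  each = 2),
    arm = rep(c("ERP", "STANDARD"), 4),
    value = c(15, 38, 33, 48, 42, 49, 132, 188)
  )
  summaries <- tibble(
    measure = rep(c("hospital_cost_total", "hospital_cost_median",
                    "community_cost_total", "outlier_excluded_median",
                    "eq5d_auc_median", "icu_stay_median_days",
                    "hdu_stay_median_days", "ward_stay_median_days"),
                  each = 2),
    arm = rep(c("ERP", "STANDARD"), 8),
    value = c(344147, 457623, 6826, 7690, 6723, 9265,
              7027.07, 7823.88, 37.2, 35.6, 1.5, 2, 1, 2, 2, 3)
  )
  list(survival = surv, counts = counts, summaries = summaries)
}

#' Survival contingency table at a horizon from the reference summaries
#'
#' @param subgroup One of `"all"`, `"malignant"`, `"colorectal"`.
#' @param horizon_years 1, 2 or 5.
#' @return A 2 x 2 integer matrix, rows = arms (ERP, STANDARD),
#'   columns = alive/dead at the horizon.
#' @examples
#' reference_survival_table("all", 2)
#' @export
reference_survival_table <- function(subgroup = "all", horizon_years = 2) {
  s <- reference_summaries()$survival
  s <- s[s$subgroup == subgroup & s$horizon_years == horizon_years, ]
  if (nrow(s) != 2) abort_domain("unknown subgroup or horizon")
  m <- cbind(alive = s$alive, dead = s$n - s$alive)
  rownames(m) <- s$arm
  m
}
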