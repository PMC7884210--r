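#' Unit-cost schedule for fully absorbed NHS costs
#'
#' All monetary rates used by the costing functions, in GBP. Defaults are
#' the fully absorbed local rates of the motivating trial: per-minute
#' anaesthetic and theatre rates, per-day bed rates by care level
#' (intensive care, high dependency, ward), the ERP-only consumables
#' (pre-operative carbohydrate drink per patient, oral nutritional
#' supplements per bottle, cardiac-output monitoring per patient), and
#' per-contact community care rates. Community rates default to
#' round-figure approximations in the spirit of the national community
#' costing compendia; they are configuration, not measured trial values.
#' Informal help from friends and family is recorded but costed at zero
#' under the NHS perspective.
#'
#' @param anesthetic_per_minute,theatre_per_minute Theatre rates, GBP/min.
#' @param icu_per_day,hdu_per_day,ward_per_day Bed-day rates, GBP/day.
#' @param carb_drink_per_patient,supplement_per_bottle,lidco_per_patient
#'   ERP consumable costs, GBP.
#' @param community_unit_costs Named numeric vector with one rate per
#'   community resource category.
#' @param currency Currency label.
#' @return A `unit_cost_schedule` list.
#' @examples
#' sched <- unit_cost_schedule()
#' sched$icu_per_day
#' @export
unit_cost_schedule <- function(anesthetic_per_minute = 9.16,
                               theatre_per_minute = 15.70,
                               icu_per_day = 1652.80,
                               hdu_per_day = 502.08,
                               ward_per_day = 151.68,
                               carb_drink_per_patient = 8.40,
                               supplement_per_bottle = 0.14,
                               lidco_per_patient = 91.20,
                               community_unit_costs = c(
                                 gp_surgery_visits = 36,
                                 gp_home_visits = 120,
                                 practice_nurse_visits = 13.50,
                                 nurse_home_visits = 25,
                                 outpatient_visits = 135,
                                 ed_attendances = 108,
                                 friends_family_events = 0
                               ),
                               currency = "GBP") {
  sched <- list(
    currency = currency,
    anesthetic_per_minute = anesthetic_per_minute,
    theatre_per_minute = theatre_per_minute,
    icu_per_day = icu_per_day, hdu_per_day = hdu_per_day,
    ward_per_day = ward_per_day,
    carb_drink_per_patient = carb_drink_per_patient,
    supplement_per_bottle = supplement_per_bottle,
    lidco_per_patient = lidco_per_patient,
    community_unit_costs = community_unit_costs
  )
  check_nonneg(unlist(sched[sapply(sched, is.numeric)]), "unit costs")
  class(sched) <- "unit_cost_schedule"
  sched
}

#' Read a unit-cost schedule from YAML or JSON
#'
#' Top-level keys are passed to [unit_cost_schedule()];
#' `community_unit_costs` must be a named mapping.
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `unit_cost_schedule`.
#' @export
read_unit_costs <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$community_unit_costs)) {
    x$community_unit_costs <- unlist(x$community_unit_costs)
  }
  do.call(unit_cost_schedule, x)
}

#' Bed-day cost under the linear daily-cost assumption
#'
#' Each day in a given care level is costed at the same fully absorbed
#' daily rate (the first day costs the same as every later day).
#'
#' @param days Days of stay (fractional allowed, e.g. half days in ICU).
#' @param daily_rate Fully absorbed daily rate, GBP/day.
#' @return Cost in GBP.
#' @examples
#' stay_cost(1.5, 1652.80) # median ICU stay at the ICU rate
#' @export
stay_cost <- function(days, daily_rate) {
  check_nonneg(days, "days"); check_nonneg(daily_rate, "daily_rate")
  days * daily_rate
}

#' Theatre cost from recorded anaesthetic and operating minutes
#'
#' @param anesthetic_minutes,surgical_minutes Recorded durations.
#' @param schedule A [unit_cost_schedule()].
#' @return Cost in GBP.
#' @examples
#' theatre_cost(52, 189)
#' @export
theatre_cost <- function(anesthetic_minutes, surgical_minutes,
                         schedule = unit_cost_schedule()) {
  check_nonneg(anesthetic_minutes, "anesthetic_minutes")
  check_nonneg(surgical_minutes, "surgical_minutes")
  anesthetic_minutes * schedule$anesthetic_per_minute +
    surgical_minutes * schedule$theatre_per_minute
}

#' ERP-only consumables cost
#'
#' Zero for standard-care patients. For ERP patients: the pre-operative
#' carbohydrate drink, oral nutritional supplements at the per-bottle
#' contract price, and per-patient cardiac-output monitoring for
#' goal-directed fluid therapy.
#'
#' @param arm `"ERP"` or `"STANDARD"` (vectorised).
#' @param supplement_bottles Bottles consumed (vectorised).
#' @param schedule A [unit_cost_schedule()].
#' @return Cost in GBP.
#' @export
erp_consumables_cost <- function(arm, supplement_bottles,
                                 schedule = unit_cost_schedule()) {
  check_nonneg(supplement_bottles, "supplement_bottles")
  ifelse(arm == "ERP",
         schedule$carb_drink_per_patient +
           supplement_bottles * schedule$supplement_per_bottle +
           schedule$lidco_per_patient,
         0)
}

#' Community care cost from resource-use counts
#'
#' Sums count times unit rate over the community categories present in
#' `usage`. Every used category must have a rate in the schedule;
#' informal friends-and-family help is costed at its configured rate
#' (zero by default, reflecting the NHS perspective).
#'
#' @param usage A data frame (or one-row tibble) of community counts, or a
#'   named numeric vector; names must match `community_unit_costs` names.
#' @param schedule A [unit_cost_schedule()].
#' @return Numeric vector of costs, one per row of `usage`.
#' @export
community_cost <- function(usage, schedule = unit_cost_schedule()) {
  if (is.numeric(usage) && !is.null(names(usage))) {
    usage <- as_tibble(as.list(usage))
  }
  cats <- names(usage)
  rates <- schedule$community_unit_costs
  missing <- setdiff(cats, names(rates))
  if (length(missing)) {
    abort_config(paste0("no community unit cost configured for: ",
                        paste(missing, collapse = ", ")))
  }
  m <- as.matrix(usage)
  check_nonneg(m, "community usage counts")
  as.numeric(m %*% rates[cats])
}

community_categories <- function() {
  c("gp_surgery_visits", "gp_home_visits", "practice_nurse_visits",
    "nurse_home_visits", "outpatient_visits", "ed_attendances",
    "friends_family_events")
}

#' Per-patient fully absorbed cost breakdown
#'
#' Adds component costs to a patient-level trial table: theatre, critical
#' care (ICU + HDU), ward, readmission (at the ward daily rate unless a
#' care level is recorded; the trial costed readmissions at the
#' appropriate fully absorbed daily rate), ERP consumables, and community
#' care. `total_hospital` excludes community care; `total` includes it.
#'
#' @param trial Patient-level tibble with the [generate_trial()] schema.
#' @param schedule A [unit_cost_schedule()].
#' @return The input tibble with cost columns `cost_theatre`,
#'   `cost_critical_care`, `cost_ward`, `cost_readmission`,
#'   `cost_erp_consumables`, `cost_community`, `cost_total_hospital`,
#'   `cost_total` appended.
#' @examples
#' trial <- generate_trial(trial_config(), seed = 1)
#' costed <- cost_patients(trial)
#' dplyr::summarise(dplyr::group_by(costed, arm),
#'                  median = median(cost_total_hospital))
#' @export
cost_patients <- function(trial, schedule = unit_cost_schedule()) {
  usage <- trial[, intersect(community_categories(), names(trial))]
  trial |>
    mutate(
      cost_theatre = theatre_cost(.data$anesthetic_minutes,
                                  .data$surgical_minutes, schedule),
      cost_critical_care = stay_cost(.data$icu_days, schedule$icu_per_day) +
        stay_cost(.data$hdu_days, schedule$hdu_per_day),
      cost_ward = stay_cost(.data$ward_days, schedule$ward_per_day),
      cost_readmission = stay_cost(.data$readmission_days,
                                   schedule$ward_per_day),
      cost_erp_consumables = erp_consumables_cost(.data$arm,
                                                  .data$supplement_bottles,
                                                  schedule),
      cost_community = community_cost(usage, schedule),
      cost_total_hospital = .data$cost_theatre + .data$cost_critical_care +
        .data$cost_ward + .data$cost_readmission + .data$cost_erp_consumables,
      cost_total = .data$cost_total_hospital + .data$cost_community
    )
}

#' Group cost summary (median, IQR, total, mean)
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7, the R default).
#'
#' @param costs Numeric vector of per-patient costs (non-empty).
#' @return One-row tibble: `n`, `median`, `iqr_low`, `iqr_high`, `total`,
#'   `mean`.
#' @examples
#' group_summary(c(1, 2, 3))
#' @export
group_summary <- function(costs) {
  if (length(costs) == 0) abort_domain("cannot summarise an empty group")
  check_nonneg(costs, "costs")
  q <- quantile(costs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(n = length(costs), median = q[2], iqr_low = q[1], iqr_high = q[3],
         total = sum(costs), mean = mean(costs))
}

#' Per-arm cost summaries for a costed trial table
#'
#' @param costed Output of [cost_patients()].
#' @param column Cost column to summarise (default total hospital cost).
#' @return Tibble with one row per arm plus the [group_summary()] columns.
#' @export
arm_cost_summary <- function(costed, column = "cost_total_hospital") {
  costed |>
    group_by(.data$arm) |>
    summarise(group_summary(.data[[column]]), .groups = "drop")
}

#' Between-arm difference of group summaries
#'
#' Computed as standard care minus ERP, so positive values are savings in
#' favour of the enhanced recovery program.
#'
#' @param summary_erp,summary_std One-row [group_summary()] tibbles.
#' @return Tibble with `median_diff` and `total_diff`.
#' @examples
#' arm_difference(group_summary(c(5, 6, 7)), group_summary(c(7, 8, 9)))
#' @export
arm_difference <- function(summary_erp, summary_std) {
  tibble(median_diff = summary_std$median - summary_erp$median,
         total_diff = summary_std$total - summary_erp$total)
}

#' Outlier-exclusion sensitivity analysis on hospital costs
#'
#' Recomputes per-arm medians and their difference after excluding the
#' given patients (e.g. extreme prolonged-stay outliers), mirroring the
#' common sensitivity check that a skewed cost difference is not driven
#' by a handful of extreme stays.
#'
#' @param costed Output of [cost_patients()].
#' @param exclude_ids Character vector of `patient_id`s to drop (must all
#'   be present; may be empty).
#' @param column Cost column (default total hospital cost).
#' @return Tibble with `median_erp`, `median_std`, `median_diff`
#'   (standard minus ERP).
#' @export
outlier_sensitivity <- function(costed, exclude_ids = character(),
                                column = "cost_total_hospital") {
  if (!all(exclude_ids %in% costed$patient_id)) {
    abort_domain("exclude_ids contains unknown patient ids")
  }
  kept <- costed[!costed$patient_id %in% exclude_ids, ]
  meds <- tapply(kept[[column]], kept$arm, median)
  if (any(is.na(meds[c("ERP", "STANDARD")]))) {
    abort_domain("exclusion emptied an arm")
  }
  tibble(median_erp = unname(meds["ERP"]),
         median_std = unname(meds["STANDARD"]),
         median_diff = unname(meds["STANDARD"] - meds["ERP"]))
}
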