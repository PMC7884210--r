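sched <- unit_cost_schedule()

test_that("bed-day and theatre costs reproduce hand arithmetic", {
  expect_equal(stay_cost(1.5, sched$icu_per_day), 2479.20)
  expect_equal(stay_cost(2, sched$ward_per_day), 303.36)
  expect_equal(stay_cost(0, 9999), 0)
  expect_error(stay_cost(-1, 100), class = "erpcea_domain_error")
  expect_equal(theatre_cost(52, 189, sched), 52 * 9.16 + 189 * 15.70)
  expect_equal(theatre_cost(52, 189, sched), 3443.62)
  expect_equal(theatre_cost(55, 207, sched), 3753.70)
  expect_equal(theatre_cost(0, 0, sched), 0)
  expect_error(theatre_cost(-5, 10, sched), class = "erpcea_domain_error")
})

test_that("ERP consumables are gated on the arm", {
  expect_equal(erp_consumables_cost("STANDARD", 50, sched), 0)
  expect_equal(erp_consumables_cost("ERP", 0, sched), 99.60)
  expect_equal(erp_consumables_cost("ERP", 10, sched), 101.00)
})

test_that("community costing sums count x rate and flags missing rates", {
  zero <- stats::setNames(rep(0, 7), erpcea:::community_categories())
  expect_equal(community_cost(zero, sched), 0)
  expect_equal(community_cost(c(gp_surgery_visits = 2), sched), 72)
  # informal care is recorded but not monetized by default
  expect_equal(community_cost(c(friends_family_events = 9), sched), 0)
  expect_error(community_cost(c(helicopter_rides = 1), sched),
               class = "erpcea_config_error")
})

test_that("per-patient breakdown matches the sum of its components", {
  rec <- blank_patient("ERP")
  rec$anesthetic_minutes <- 52; rec$surgical_minutes <- 189
  rec$icu_days <- 1.5; rec$hdu_days <- 1; rec$ward_days <- 2
  costed <- cost_patients(rec, sched)
  expect_equal(costed$cost_total_hospital, 6827.86)
  expect_equal(costed$cost_total, 6827.86)

  ward_only <- blank_patient("STANDARD")
  ward_only$ward_days <- 2
  expect_equal(cost_patients(ward_only, sched)$cost_total, 303.36)
  zero <- cost_patients(blank_patient("STANDARD"), sched)
  expect_equal(zero$cost_total, 0)
})

test_that("cost aggregation is additive and homogeneous in the rates", {
  trial <- generate_trial(trial_config(n_erp = 20, n_std = 20), seed = 5)
  costed <- cost_patients(trial, sched)
  expect_equal(costed$cost_total_hospital,
               costed$cost_theatre + costed$cost_critical_care +
                 costed$cost_ward + costed$cost_readmission +
                 costed$cost_erp_consumables)
  expect_equal(costed$cost_total,
               costed$cost_total_hospital + costed$cost_community)
  # component recomputation agrees with the row-wise operations
  expect_equal(costed$cost_theatre,
               theatre_cost(trial$anesthetic_minutes,
                            trial$surgical_minutes, sched))
  k <- 2.5
  sk <- unit_cost_schedule(
    anesthetic_per_minute = k * 9.16, theatre_per_minute = k * 15.70,
    icu_per_day = k * 1652.80, hdu_per_day = k * 502.08,
    ward_per_day = k * 151.68, carb_drink_per_patient = k * 8.40,
    supplement_per_bottle = k * 0.14, lidco_per_patient = k * 91.20,
    community_unit_costs = k * sched$community_unit_costs)
  scaled <- cost_patients(trial, sk)
  for (cl in grep("^cost_", names(costed), value = TRUE)) {
    expect_equal(scaled[[cl]], k * costed[[cl]], label = cl)
  }
})

test_that("group summaries use type-7 quartiles and additive totals", {
  s <- group_summary(c(1, 2, 3))
  expect_equal(s$median, 2); expect_equal(s$total, 6)
  single <- group_summary(5)
  expect_equal(c(single$iqr_low, single$median, single$iqr_high),
               c(5, 5, 5))
  expect_error(group_summary(numeric()), class = "erpcea_domain_error")
  x <- runif(50, 0, 100)
  expect_equal(group_summary(sample(x))$total, group_summary(x)$total)
  # simulated symmetric costs centre the median near the true centre
  set.seed(8)
  draws <- 5000 + rnorm(1000, sd = 50)
  se_med <- 1.2533 * 50 / sqrt(1000)
  expect_lt(abs(group_summary(draws)$median - 5000), 3 * se_med)
})

test_that("arm differences are antisymmetric and match the worked totals", {
  s <- reference_summaries()$summaries
  pick <- function(measure, arm) s$value[s$measure == measure & s$arm == arm]
  erp_h <- tibble::tibble(median = pick("hospital_cost_median", "ERP"),
                          total = pick("hospital_cost_total", "ERP"))
  std_h <- tibble::tibble(median = pick("hospital_cost_median", "STANDARD"),
                          total = pick("hospital_cost_total", "STANDARD"))
  d <- arm_difference(erp_h, std_h)
  expect_equal(d$total_diff, 113476)
  expect_equal(d$median_diff, 864)
  flipped <- arm_difference(std_h, erp_h)
  expect_equal(flipped$total_diff, -d$total_diff)
  expect_equal(flipped$median_diff, -d$median_diff)
  expect_equal(arm_difference(erp_h, erp_h)$total_diff, 0)
})

test_that("outlier exclusion recomputes medians on the reduced data", {
  trial <- generate_trial(trial_config(n_erp = 15, n_std = 15), seed = 9)
  costed <- cost_patients(trial, sched)
  # empty exclusion is the identity
  base <- outlier_sensitivity(costed, character())
  meds <- tapply(costed$cost_total_hospital, costed$arm, median)
  expect_equal(base$median_erp, unname(meds["ERP"]))
  expect_equal(base$median_diff, unname(meds["STANDARD"] - meds["ERP"]))
  # a 10x cost outlier drags the arm mean; excluding it moves the mean
  # back toward the (robust) median
  out <- costed
  idx <- which(out$arm == "STANDARD")[1]
  out$cost_total_hospital[idx] <- 10 * max(out$cost_total_hospital)
  std <- out$cost_total_hospital[out$arm == "STANDARD"]
  before_gap <- abs(mean(std) - median(std))
  kept <- std[-1]
  expect_lt(abs(mean(kept) - median(kept)), before_gap)
  excl <- outlier_sensitivity(out, out$patient_id[idx])
  expect_equal(excl$median_std,
               median(out$cost_total_hospital[out$arm == "STANDARD"][-1]))
  expect_error(outlier_sensitivity(costed, "NOBODY-9"),
               class = "erpcea_domain_error")
  everyone_std <- costed$patient_id[costed$arm == "STANDARD"]
  expect_error(outlier_sensitivity(costed, everyone_std),
               class = "erpcea_domain_error")
})
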