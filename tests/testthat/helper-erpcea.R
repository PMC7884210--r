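# shared fixtures and independent oracles

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins and sum hypergeometric probabilities no larger than the
# observed table's (probability-mass criterion)
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  a_vals <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_vals, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# patient-level dataset whose alive/dead counts at 1/2/5 years exactly
# match the reference survival tables (deaths placed mid-interval)
reference_shaped_trial <- function(subgroup = "all") {
  s <- reference_summaries()$survival
  s <- s[s$subgroup == subgroup, ]
  rows <- lapply(unique(s$arm), function(a) {
    alive <- s$alive[s$arm == a][order(s$horizon_years[s$arm == a])]
    n <- s$n[s$arm == a][1]
    d1 <- n - alive[1]; d2 <- alive[1] - alive[2]; d5 <- alive[2] - alive[3]
    times <- c(rep(0.5, d1), rep(1.5, d2), rep(3.5, d5), rep(5, alive[3]))
    tibble::tibble(
      patient_id = sprintf("%s-%s-%03d", subgroup, a, seq_len(n)),
      arm = a, survival_years = times,
      died = times < 5
    )
  })
  dplyr::bind_rows(rows)
}

# minimal patient record rows for costing unit tests
blank_patient <- function(arm = "STANDARD", n = 1) {
  usage <- as.list(stats::setNames(rep(0, 7), erpcea:::community_categories()))
  tibble::tibble(
    patient_id = sprintf("P-%03d", seq_len(n)), arm = arm,
    anesthetic_minutes = 0, surgical_minutes = 0, icu_days = 0,
    hdu_days = 0, ward_days = 0, readmission_days = 0,
    supplement_bottles = 0, !!!usage
  )
}

# markov spec with deterministic dynamics for closed-form checks:
# constant annual death probability q, utility 1, free care, no discount
constant_hazard_spec <- function(q, horizon, discount = 0) {
  s5 <- c(1 - q, (1 - q)^2, (1 - q)^5)
  lt <- tidyr::expand_grid(age = 25:120, sex = c("M", "F"))
  lt$qx <- q
  markov_spec(
    horizon = horizon, discount_rate_costs = discount,
    discount_rate_effects = discount, life_table = lt, relative_risk = 1,
    arms = list(
      ERP = list(p_death_inhosp = 0, p_comp_discharge = 0,
                 trial_survival = s5, p_comp_incidence = 0,
                 p_comp_resolution = 0, utility_no_comp = 1,
                 utility_comp = 1, annual_cost_no_comp = 0,
                 annual_cost_comp = 0, inhospital_cost = 0, qaly0 = 0),
      STANDARD = list(p_death_inhosp = 0, p_comp_discharge = 0,
                      trial_survival = s5, p_comp_incidence = 0,
                      p_comp_resolution = 0, utility_no_comp = 1,
                      utility_comp = 1, annual_cost_no_comp = 0,
                      annual_cost_comp = 0, inhospital_cost = 0, qaly0 = 0)
    )
  )
}

# random but always-valid markov spec for property probes
random_markov_spec <- function() {
  rand_arm <- function() {
    s1 <- runif(1, 0.6, 1); s2 <- s1 * runif(1, 0.6, 1)
    s5 <- s2 * runif(1, 0.5, 1)
    list(p_death_inhosp = runif(1, 0, 0.2),
         p_comp_discharge = runif(1), trial_survival = c(s1, s2, s5),
         p_comp_incidence = runif(1), p_comp_resolution = runif(1),
         utility_no_comp = runif(1), utility_comp = runif(1),
         annual_cost_no_comp = runif(1, 0, 5000),
         annual_cost_comp = runif(1, 0, 5000),
         inhospital_cost = runif(1, 0, 20000), qaly0 = 0)
  }
  markov_spec(horizon = sample(1:15, 1),
              discount_rate_costs = runif(1, 0, 0.06),
              discount_rate_effects = runif(1, 0, 0.06),
              cohort = list(age = sample(40:80, 1), p_male = runif(1)),
              relative_risk = runif(1, 0.5, 3),
              arms = list(ERP = rand_arm(), STANDARD = rand_arm()))
}
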