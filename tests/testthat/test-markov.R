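test_that("decision tree composes death and complication risks", {
  expect_equal(unname(decision_tree(0, 0)), c(1, 0, 0))
  d <- decision_tree(1 / 46, 0.3)
  expect_equal(unname(d), c((1 - 1 / 46) * 0.7, (1 - 1 / 46) * 0.3, 1 / 46))
  set.seed(61)
  for (i in 1:25) {
    expect_equal(sum(decision_tree(runif(1), runif(1))), 1)
  }
  expect_error(decision_tree(1.2, 0), class = "erpcea_config_error")
})

test_that("mortality adjustment multiplies and caps the table rate", {
  lt <- tibble::tibble(age = c(70, 70), sex = c("M", "F"),
                       qx = c(0.02, 0.6))
  expect_equal(adjusted_mortality(70, "M", lt, relative_risk = 1), 0.02)
  expect_equal(adjusted_mortality(70, "M", lt, relative_risk = 2.5), 0.05)
  expect_equal(adjusted_mortality(70, "F", lt, relative_risk = 2), 1)
  expect_error(adjusted_mortality(30, "M", lt),
               class = "erpcea_domain_error")
})

test_that("discount factors follow (1+r)^-cycle", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 7), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 10), 1.03^-10)
})

test_that("occupancy is conserved and death is absorbing on random specs", {
  set.seed(71)
  for (i in 1:60) {
    spec <- random_markov_spec()
    for (arm in c("ERP", "STANDARD")) {
      out <- run_markov(spec, arm)
      occ <- as.matrix(out$trace[, c("alive_no_comp", "alive_comp", "dead")])
      expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
      expect_true(all(diff(occ[, "dead"]) >= -1e-12))
      expect_true(all(occ >= -1e-12 & occ <= 1 + 1e-12))
    }
  }
})

test_that("a frozen 10-cycle immortal cohort yields exactly 10 LY and QALYs", {
  spec <- constant_hazard_spec(q = 0, horizon = 10)
  out <- run_markov(spec, "ERP")
  expect_equal(out$totals$life_years, 10)
  expect_equal(out$totals$qalys, 10)
  expect_equal(out$totals$cost, 0)
})

test_that("constant-hazard life expectancy matches the geometric series", {
  spec <- constant_hazard_spec(q = 0.5, horizon = 40)
  out <- run_markov(spec, "ERP")
  # sum_{c>=1} (1-q)^c = (1-q)/q = 1 for q = 1/2; horizon-40 truncation
  # error is 2^-40
  expect_equal(out$totals$life_years, 1, tolerance = 1e-9)
  closed <- sum(0.5^(1:40))
  expect_equal(out$totals$life_years, closed, tolerance = 1e-12)
})

test_that("discounting only shrinks totals, and QALYs never exceed LY", {
  set.seed(81)
  for (i in 1:20) {
    spec <- random_markov_spec()
    disc <- run_markov(spec, "ERP")$totals
    spec0 <- spec
    spec0$discount_rate_costs <- 0
    spec0$discount_rate_effects <- 0
    undisc <- run_markov(spec0, "ERP")$totals
    expect_lte(disc$life_years, undisc$life_years + 1e-12)
    expect_lte(disc$cost, undisc$cost + 1e-12)
    expect_lte(disc$qalys, disc$life_years + 1e-12) # utilities <= 1
  }
  spec <- constant_hazard_spec(0.2, 15, discount = 0)
  expect_equal(run_markov(spec, "ERP")$totals$life_years,
               run_markov({
                 s <- spec; s$discount_rate_effects <- 0; s
               }, "ERP")$totals$life_years)
})

test_that("raising utility raises QALYs; raising mortality lowers LY", {
  set.seed(91)
  for (i in 1:10) {
    spec <- random_markov_spec()
    base <- run_markov(spec, "ERP")$totals
    up <- spec
    up$arms$ERP$utility_no_comp <- min(1, up$arms$ERP$utility_no_comp + 0.1)
    up$arms$ERP$utility_comp <- min(1, up$arms$ERP$utility_comp + 0.1)
    expect_gte(run_markov(up, "ERP")$totals$qalys, base$qalys - 1e-12)
    worse <- spec
    worse$arms$ERP$trial_survival <- spec$arms$ERP$trial_survival * 0.8
    expect_lte(run_markov(worse, "ERP")$totals$life_years,
               base$life_years + 1e-12)
  }
})

test_that("half-cycle correction interpolates between cycle boundaries", {
  spec_end <- constant_hazard_spec(q = 0.3, horizon = 12)
  spec_hc <- spec_end
  spec_hc$half_cycle <- TRUE
  ly_end <- run_markov(spec_end, "ERP")$totals$life_years
  ly_hc <- run_markov(spec_hc, "ERP")$totals$life_years
  # trapezoidal credit adds half of the cycle-0 vs horizon occupancy gap
  expect_equal(ly_hc - ly_end, 0.5 * (1 - 0.7^12))
})

test_that("QALE weights state years by state utilities", {
  expect_equal(quality_adjusted_life_expectancy(10, 1), 10)
  expect_equal(quality_adjusted_life_expectancy(c(6, 2), c(0.8, 0.6)), 6)
  expect_equal(quality_adjusted_life_expectancy(numeric(), numeric()), 0)
  expect_error(quality_adjusted_life_expectancy(c(1, 2), 1),
               class = "erpcea_domain_error")
})

test_that("ICER sign logic and dominance labels", {
  r <- icer(tibble::tibble(cost = 100, qalys = 2.5),
            tibble::tibble(cost = 200, qalys = 2))
  expect_equal(r$icer, -200)
  expect_equal(r$label, "dominant")
  # worked three-column table arithmetic
  r2 <- icer(tibble::tibble(cost = 9538.30, qalys = 6.9),
             tibble::tibble(cost = 14793.10, qalys = 6.1))
  expect_equal(r2$icer, (9538.30 - 14793.10) / 0.8, tolerance = 1e-9)
  expect_equal(round(r2$icer, 2), -6568.50)
  expect_equal(r2$label, "dominant")
  same <- icer(tibble::tibble(cost = 5, qalys = 1),
               tibble::tibble(cost = 5, qalys = 1))
  expect_equal(same$label, "undefined")
  expect_true(is.na(same$icer))
  dom <- icer(tibble::tibble(cost = 300, qalys = 1),
              tibble::tibble(cost = 200, qalys = 2))
  expect_equal(dom$label, "dominated")
})

test_that("tidy and glance expose per-arm and incremental results", {
  res <- run_cea(markov_spec(horizon = 5))
  expect_equal(nrow(tidy(res)), 2)
  expect_named(glance(res), c("delta_cost", "delta_effect", "icer", "label"))
  expect_output(print(res), "ICER")
})
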