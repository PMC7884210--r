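#' Specify the decision-tree plus Markov cost-effectiveness model
#'
#' The model compares two strategies (ERP vs standard care). A decision
#' tree distributes each arm's cohort at discharge over three states —
#' alive without complications, alive with complications, dead — from the
#' arm's in-hospital death and discharge-complication probabilities. A
#' Markov cohort simulation then runs in annual cycles: each year
#' survivors may develop a complication, resolve one, remain in state, or
#' die. Annual death probabilities for the first five cycles are derived
#' from the trial's observed arm-specific survival fractions; beyond the
#' trial window they come from a background life table multiplied by a
#' relative risk for high-risk surgical survivors. State utilities weight
#' life-years into QALYs; per-state annual follow-up costs accrue on top
#' of the one-off in-hospital cost, and costs and effects are discounted
#' (3% per year by default, the NICE reference case).
#'
#' Default arm parameters are calibrated to the motivating trial: mean
#' in-hospital plus community cost per patient, in-hospital death 1/46
#' (ERP) and 1/45 (standard), discharge complication rates favouring the
#' ERP, trial 1/2/5-year survival fractions, and a cycle-0 QALY bonus for
#' the ERP arm equal to the annualized 28-day quality-of-life gain.
#' Literature-style state utilities and follow-up costs are
#' configuration, not trial measurements.
#'
#' @param horizon Cycles (years) to simulate, default 10.
#' @param discount_rate_costs,discount_rate_effects Annual discount rates.
#' @param half_cycle Use a half-cycle correction (trapezoidal cycle
#'   credit)? Default `FALSE` (end-of-cycle credit).
#' @param cohort List with `age` (mean age at surgery) and `p_male`.
#' @param life_table Background mortality table, see [uk_life_table()].
#' @param relative_risk Background-mortality multiplier for surgical
#'   survivors (applies after the trial-informed first five cycles).
#' @param arms Named list (`ERP`, `STANDARD`) of per-arm overrides merged
#'   over the defaults; see Details for the parameter names.
#' @return A `markov_spec` list.
#' @examples
#' spec <- markov_spec(horizon = 10)
#' run_cea(spec)
#' @export
markov_spec <- function(horizon = 10,
                        discount_rate_costs = 0.03,
                        discount_rate_effects = 0.03,
                        half_cycle = FALSE,
                        cohort = list(age = 65, p_male = 54 / 91),
                        life_table = uk_life_table(),
                        relative_risk = 2,
                        arms = list()) {
  default_arm <- function(arm) {
    erp <- arm == "ERP"
    list(
      p_death_inhosp = if (erp) 1 / 46 else 1 / 45,
      p_comp_discharge = if (erp) 0.20 else 0.40,
      trial_survival = if (erp) c(45, 42, 24) / 46 else c(41, 33, 23) / 45,
      p_comp_incidence = if (erp) 0.03 else 0.05,
      p_comp_resolution = 0.40,
      utility_no_comp = 0.80,
      utility_comp = 0.60,
      annual_cost_no_comp = 250,
      annual_cost_comp = 1500,
      inhospital_cost = if (erp) (344147 + 6723) / 46 else
        (457623 + 9265) / 45,
      qaly0 = if (erp) 0.004 else 0
    )
  }
  spec <- structure(list(
    states = c("alive_no_comp", "alive_comp", "dead"),
    horizon = as.integer(horizon),
    discount_rate_costs = discount_rate_costs,
    discount_rate_effects = discount_rate_effects,
    half_cycle = isTRUE(half_cycle),
    cohort = cohort, life_table = life_table,
    relative_risk = relative_risk,
    arms = list(
      ERP = utils::modifyList(default_arm("ERP"), arms$ERP %||% list()),
      STANDARD = utils::modifyList(default_arm("STANDARD"),
                                   arms$STANDARD %||% list())
    )
  ), class = "markov_spec")
  validate_markov_spec(spec)
  spec
}

validate_markov_spec <- function(spec) {
  if (spec$horizon < 1) abort_config("horizon must be at least 1 cycle")
  check_nonneg(c(spec$discount_rate_costs, spec$discount_rate_effects),
               "discount rates")
  check_prob(spec$cohort$p_male, "cohort p_male")
  for (arm in names(spec$arms)) {
    p <- spec$arms[[arm]]
    check_prob(c(p$p_death_inhosp, p$p_comp_discharge, p$trial_survival,
                 p$p_comp_incidence, p$p_comp_resolution),
               paste0(arm, " probabilities"))
    if (any(diff(p$trial_survival) > 0)) {
      abort_config("trial_survival fractions must be non-increasing")
    }
    check_nonneg(c(p$annual_cost_no_comp, p$annual_cost_comp,
                   p$inhospital_cost), paste0(arm, " costs"))
  }
  invisible(spec)
}

#' Decision-tree initial distribution for one arm
#'
#' Splits the cohort at discharge: in-hospital death first, then
#' complications among survivors.
#'
#' @param p_death_inhosp,p_comp_discharge Probabilities in \[0, 1\].
#' @return Named numeric vector over (alive_no_comp, alive_comp, dead),
#'   summing to 1.
#' @examples
#' decision_tree(1 / 46, 0.2)
#' @export
decision_tree <- function(p_death_inhosp, p_comp_discharge) {
  check_prob(c(p_death_inhosp, p_comp_discharge), "decision-tree probabilities")
  c(alive_no_comp = (1 - p_death_inhosp) * (1 - p_comp_discharge),
    alive_comp = (1 - p_death_inhosp) * p_comp_discharge,
    dead = p_death_inhosp)
}

#' Discount factor at an annual rate
#'
#' @param rate Annual rate (e.g. 0.03).
#' @param cycle Cycle index (0 = no discounting).
#' @return `(1 + rate)^-cycle`.
#' @examples
#' discount_factor(0.03, 1)
#' @export
discount_factor <- function(rate, cycle) {
  check_nonneg(rate, "rate"); check_nonneg(cycle, "cycle")
  (1 + rate)^(-cycle)
}

# annual death probability per cycle: trial-informed for cycles 1..5,
# life table x relative risk thereafter
cycle_death_probs <- function(spec, arm) {
  p <- spec$arms[[arm]]
  s <- p$trial_survival
  s_annual <- c(1, s[1], s[2],
                s[2] * (s[3] / s[2])^(1 / 3),
                s[2] * (s[3] / s[2])^(2 / 3), s[3])
  q_trial <- 1 - s_annual[-1] / s_annual[-6]
  H <- spec$horizon
  q <- numeric(H)
  q[seq_len(min(5, H))] <- q_trial[seq_len(min(5, H))]
  if (H > 5) {
    ages <- spec$cohort$age + 5:(H - 1)
    q[6:H] <- cohort_mortality(ages, spec$cohort$p_male, spec$life_table,
                               spec$relative_risk)
  }
  q
}

# one-cycle transition matrix over (alive_no_comp, alive_comp, dead)
build_transition <- function(q_death, p_inc, p_res) {
  m <- rbind(
    c((1 - q_death) * (1 - p_inc), (1 - q_death) * p_inc, q_death),
    c((1 - q_death) * p_res, (1 - q_death) * (1 - p_res), q_death),
    c(0, 0, 1)
  )
  if (any(abs(rowSums(m) - 1) > 1e-12) || any(m < 0) || any(m > 1)) {
    rlang::abort("transition rows must be probabilities summing to 1",
                 class = "erpcea_model_error")
  }
  m
}

#' Run the Markov cohort simulation for one arm
#'
#' Propagates the decision-tree initial distribution through the per-cycle
#' transition matrices and accumulates discounted life-years, QALYs and
#' costs. By default each cycle's reward is credited at its end (the
#' occupancy after the cycle's transitions); with `half_cycle = TRUE` in
#' the spec, rewards use trapezoidal cycle credit (half weight at cycle 0
#' and the horizon). The arm's one-off in-hospital cost and cycle-0 QALY
#' bonus are added undiscounted.
#'
#' @param spec A [markov_spec()].
#' @param arm `"ERP"` or `"STANDARD"`.
#' @return A list with `trace` (tibble: cycle, state occupancies,
#'   discounted increments) and one-row `totals` (arm, cost, life_years,
#'   qalys).
#' @examples
#' run_markov(markov_spec(), "ERP")$totals
#' @export
run_markov <- function(spec, arm = "ERP") {
  validate_markov_spec(spec)
  p <- spec$arms[[arm]]
  H <- spec$horizon
  q <- cycle_death_probs(spec, arm)
  occ <- matrix(0, nrow = H + 1, ncol = 3,
                dimnames = list(NULL, spec$states))
  occ[1, ] <- decision_tree(p$p_death_inhosp, p$p_comp_discharge)
  for (cyc in seq_len(H)) {
    tm <- build_transition(q[cyc], p$p_comp_incidence, p$p_comp_resolution)
    occ[cyc + 1, ] <- occ[cyc, ] %*% tm
    if (abs(sum(occ[cyc + 1, ]) - 1) > 1e-12) {
      rlang::abort("state occupancy not conserved",
                   class = "erpcea_model_error")
    }
  }
  u <- c(p$utility_no_comp, p$utility_comp, 0)
  cost_s <- c(p$annual_cost_no_comp, p$annual_cost_comp, 0)
  cycles <- 0:H
  df_e <- discount_factor(spec$discount_rate_effects, cycles)
  df_c <- discount_factor(spec$discount_rate_costs, cycles)
  w <- if (spec$half_cycle) c(0.5, rep(1, H - 1), 0.5) else
    c(0, rep(1, H))
  alive <- occ[, 1] + occ[, 2]
  ly_inc <- w * df_e * alive
  qaly_inc <- w * df_e * as.numeric(occ %*% u)
  cost_inc <- w * df_c * as.numeric(occ %*% cost_s)
  trace <- tibble(cycle = cycles, as_tibble(occ),
                  ly_disc = ly_inc, qaly_disc = qaly_inc,
                  cost_disc = cost_inc)
  totals <- tibble(arm = arm,
                   cost = p$inhospital_cost + sum(cost_inc),
                   life_years = sum(ly_inc),
                   qalys = p$qaly0 + sum(qaly_inc))
  list(trace = trace, totals = totals)
}

#' Quality-adjusted life expectancy from state life-years
#'
#' Weights expected years spent in each state by that state's utility.
#'
#' @param life_years_by_state Named or positional numeric vector of
#'   expected years per alive state.
#' @param utilities Utility per state, same order.
#' @return QALE (QALYs).
#' @examples
#' quality_adjusted_life_expectancy(c(6, 2), c(0.8, 0.6))
#' @export
quality_adjusted_life_expectancy <- function(life_years_by_state, utilities) {
  if (length(life_years_by_state) != length(utilities)) {
    abort_domain("life_years_by_state and utilities must align")
  }
  check_nonneg(life_years_by_state, "life_years_by_state")
  sum(life_years_by_state * utilities)
}

#' Incremental cost-effectiveness comparison of two arm results
#'
#' Increments are ERP minus standard care. When the increments' signs
#' oppose, the comparison is labelled `dominant` (cheaper and more
#' effective) or `dominated` (dearer and less effective); a zero effect
#' difference leaves the ICER undefined and only the increments are
#' reported.
#'
#' @param totals_erp,totals_std One-row tibbles with `cost` and `qalys`
#'   (and optionally `life_years`), as produced by [run_markov()].
#' @return One-row tibble: `delta_cost`, `delta_effect`, `icer`, `label`.
#' @examples
#' icer(tibble::tibble(cost = 9500, qalys = 6.9),
#'      tibble::tibble(cost = 14800, qalys = 6.1))
#' @export
icer <- function(totals_erp, totals_std) {
  dc <- totals_erp$cost - totals_std$cost
  de <- totals_erp$qalys - totals_std$qalys
  if (de == 0) {
    return(tibble(delta_cost = dc, delta_effect = 0, icer = NA_real_,
                  label = "undefined"))
  }
  label <- if (dc < 0 && de > 0) "dominant" else
    if (dc > 0 && de < 0) "dominated" else "tradeoff"
  tibble(delta_cost = dc, delta_effect = de, icer = dc / de, label = label)
}

#' Run the full cost-effectiveness comparison
#'
#' Runs [run_markov()] for both arms and forms the incremental
#' comparison.
#'
#' @param spec A [markov_spec()].
#' @return A `cea_result`: list with `arms` (per-arm discounted cost,
#'   life-years, QALYs), `incremental` (see [icer()]), and the `spec`.
#' @examples
#' res <- run_cea(markov_spec())
#' glance(res)
#' @export
run_cea <- function(spec = markov_spec()) {
  erp <- run_markov(spec, "ERP")
  std <- run_markov(spec, "STANDARD")
  structure(list(
    arms = bind_rows(erp$totals, std$totals),
    incremental = icer(erp$totals, std$totals),
    traces = list(ERP = erp$trace, STANDARD = std$trace),
    spec = spec
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness comparison (discounted,",
      x$spec$horizon, "year horizon)\n")
  print(x$arms)
  inc <- x$incremental
  cat(sprintf("\ndelta cost %.2f, delta QALYs %.4f, ICER %s (%s)\n",
              inc$delta_cost, inc$delta_effect,
              ifelse(is.na(inc$icer), "undefined",
                     sprintf("%.2f/QALY", inc$icer)),
              inc$label))
  invisible(x)
}

#' @rdname run_cea
#' @param x A `cea_result`.
#' @param ... Unused.
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) x$arms

#' @rdname run_cea
#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) x$incremental
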