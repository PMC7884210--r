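#' Configure the probabilistic sensitivity analysis
#'
#' Builds the sampling plan for [run_psa()]. Every varied parameter gets
#' a distribution centred on its base-case value in the model spec:
#' probabilities and utilities are beta-distributed (parameterized by
#' mean and an effective sample size), costs are gamma-distributed
#' (parameterized by mean and coefficient of variation), and the survivor
#' relative risk is gamma. Each parameter draws from its own RNG stream
#' seeded by the master seed and the parameter's id, so adding or
#' removing one parameter does not perturb the others' draws.
#'
#' @param spec The base-case [markov_spec()].
#' @param n_iterations Monte Carlo iterations (default 10000).
#' @param seed Master seed.
#' @param ess_prob Effective sample size for beta-distributed
#'   probabilities and utilities (larger = tighter).
#' @param cv_cost Coefficient of variation for gamma-distributed costs.
#' @param cv_rr Coefficient of variation for the relative risk.
#' @param parameters Optional explicit named list of distribution specs
#'   (each `list(family, mean, ess|cv)` with family `"beta"`, `"gamma"`
#'   or `"fixed"`), overriding the auto-generated plan entrywise. Ids use
#'   `ARM.field` for arm parameters (e.g. `"ERP.utility_comp"`) or a bare
#'   spec field name (e.g. `"relative_risk"`).
#' @return A `psa_config` list.
#' @examples
#' cfg <- psa_config(markov_spec(), n_iterations = 100, seed = 7)
#' names(cfg$parameters)[1:4]
#' @export
psa_config <- function(spec = markov_spec(), n_iterations = 10000,
                       seed = 42, ess_prob = 100, cv_cost = 0.2,
                       cv_rr = 0.15, parameters = NULL) {
  if (n_iterations < 1) abort_config("n_iterations must be at least 1")
  beta_p <- function(m) list(family = "beta", mean = m, ess = ess_prob)
  gamma_p <- function(m, cv) list(family = "gamma", mean = m, cv = cv)
  plan <- list(relative_risk = gamma_p(spec$relative_risk, cv_rr))
  for (arm in names(spec$arms)) {
    p <- spec$arms[[arm]]
    plan[[paste0(arm, ".p_comp_discharge")]] <- beta_p(p$p_comp_discharge)
    plan[[paste0(arm, ".p_comp_incidence")]] <- beta_p(p$p_comp_incidence)
    plan[[paste0(arm, ".p_comp_resolution")]] <- beta_p(p$p_comp_resolution)
    plan[[paste0(arm, ".utility_no_comp")]] <- beta_p(p$utility_no_comp)
    plan[[paste0(arm, ".utility_comp")]] <- beta_p(p$utility_comp)
    plan[[paste0(arm, ".annual_cost_no_comp")]] <-
      gamma_p(p$annual_cost_no_comp, cv_cost)
    plan[[paste0(arm, ".annual_cost_comp")]] <-
      gamma_p(p$annual_cost_comp, cv_cost)
    plan[[paste0(arm, ".inhospital_cost")]] <-
      gamma_p(p$inhospital_cost, cv_cost / 2)
  }
  if (!is.null(parameters)) plan <- utils::modifyList(plan, parameters)
  for (id in names(plan)) validate_dist(plan[[id]], id)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), parameters = plan, spec = spec),
            class = "psa_config")
}

validate_dist <- function(d, id) {
  if (!d$family %in% c("beta", "gamma", "fixed")) {
    abort_config(paste0(id, ": unknown distribution family"))
  }
  if (d$family == "beta") {
    if (d$mean <= 0 || d$mean >= 1 || (d$ess %||% 0) <= 0) {
      abort_config(paste0(id, ": beta needs mean in (0,1) and ess > 0"))
    }
  }
  if (d$family == "gamma" && (d$mean < 0 || (d$cv %||% -1) < 0)) {
    abort_config(paste0(id, ": gamma needs mean >= 0 and cv >= 0"))
  }
  invisible(d)
}

draw_dist <- function(d, n) {
  switch(d$family,
    fixed = rep(d$mean, n),
    beta = rbeta(n, d$mean * d$ess, (1 - d$mean) * d$ess),
    gamma = {
      if (d$mean == 0 || d$cv == 0) rep(d$mean, n) else {
        shape <- 1 / d$cv^2
        rgamma(n, shape = shape, rate = shape / d$mean)
      }
    })
}

#' Draw the joint parameter sample for a PSA
#'
#' One column per varied parameter, one row per iteration; fully
#' reproducible from the config's seed. `draw_parameters()` returns the
#' single row for one iteration.
#'
#' @param config A [psa_config()].
#' @return Tibble `n_iterations` x parameters.
#' @export
psa_draws <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  cols <- purrr::imap(config$parameters, function(d, id) {
    set.seed(seed_from_id(config$seed, id))
    draw_dist(d, config$n_iterations)
  })
  as_tibble(cols)
}

#' @rdname psa_draws
#' @param iteration Iteration index (1-based).
#' @export
draw_parameters <- function(config, iteration) {
  if (iteration < 1 || iteration > config$n_iterations) {
    abort_domain("iteration out of range")
  }
  psa_draws(config)[iteration, ]
}

# apply one draw (named list/one-row tibble) onto a markov_spec
apply_draw <- function(spec, draw) {
  for (id in names(draw)) {
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      spec$arms[[parts[1]]][[parts[2]]] <- draw[[id]]
    } else {
      spec[[id]] <- draw[[id]]
    }
  }
  spec
}

# lean single-arm run: totals only, no validation or tibbles
markov_totals <- function(spec, arm) {
  p <- spec$arms[[arm]]
  H <- spec$horizon
  q <- cycle_death_probs(spec, arm)
  occ <- decision_tree(p$p_death_inhosp, p$p_comp_discharge)
  u <- c(p$utility_no_comp, p$utility_comp, 0)
  cost_s <- c(p$annual_cost_no_comp, p$annual_cost_comp, 0)
  hc <- spec$half_cycle
  ly <- qaly <- cost <- 0
  if (hc) {
    ly <- 0.5 * (occ[1] + occ[2])
    qaly <- 0.5 * sum(occ * u)
    cost <- 0.5 * sum(occ * cost_s)
  }
  for (cyc in seq_len(H)) {
    tm <- build_transition(q[cyc], p$p_comp_incidence, p$p_comp_resolution)
    occ <- as.numeric(occ %*% tm)
    w <- if (hc && cyc == H) 0.5 else 1
    de <- (1 + spec$discount_rate_effects)^(-cyc)
    dc <- (1 + spec$discount_rate_costs)^(-cyc)
    ly <- ly + w * de * (occ[1] + occ[2])
    qaly <- qaly + w * de * sum(occ * u)
    cost <- cost + w * dc * sum(occ * cost_s)
  }
  c(cost = p$inhospital_cost + cost, life_years = ly,
    qalys = p$qaly0 + qaly)
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' For each joint parameter draw, rebuilds the model spec, reruns both
#' arms of the Markov model, and records the incremental cost and effect
#' (ERP minus standard care). A draw that yields an invalid model (e.g. a
#' transition row leaving \[0, 1\]) is resampled from a dedicated
#' follow-up stream and counted in the `n_resampled` attribute.
#'
#' @param config A [psa_config()].
#' @return A `psa_cloud`: tibble with `iteration`, `delta_cost`,
#'   `delta_effect`, carrying the seed, base-case increments and
#'   resample count as attributes.
#' @examples
#' cloud <- run_psa(psa_config(markov_spec(), n_iterations = 50, seed = 1))
#' summary(cloud$delta_cost)
#' @export
run_psa <- function(config) {
  spec <- config$spec
  draws <- psa_draws(config)
  base <- icer(as_tibble(as.list(markov_totals(spec, "ERP"))),
               as_tibble(as.list(markov_totals(spec, "STANDARD"))))
  n <- config$n_iterations
  dc <- de <- numeric(n)
  n_resampled <- 0L
  for (i in seq_len(n)) {
    draw <- as.list(draws[i, ])
    res <- tryCatch({
      s <- apply_draw(spec, draw)
      markov_totals(s, "ERP") - markov_totals(s, "STANDARD")
    }, error = function(e) NULL)
    tries <- 0
    while (is.null(res) && tries < 100) {
      n_resampled <- n_resampled + 1L
      tries <- tries + 1
      set.seed(seed_from_id(config$seed, paste0("resample-", i, "-", tries)))
      draw <- purrr::map(config$parameters, draw_dist, n = 1)
      res <- tryCatch({
        s <- apply_draw(spec, draw)
        markov_totals(s, "ERP") - markov_totals(s, "STANDARD")
      }, error = function(e) NULL)
    }
    if (is.null(res)) {
      rlang::abort("PSA draw repeatedly produced an invalid model",
                   class = "erpcea_model_error")
    }
    dc[i] <- res[["cost"]]; de[i] <- res[["qalys"]]
  }
  structure(tibble(iteration = seq_len(n), delta_cost = dc,
                   delta_effect = de),
            seed = config$seed, base_case = base,
            n_resampled = n_resampled,
            class = c("psa_cloud", "tbl_df", "tbl", "data.frame"))
}

#' Net monetary benefit
#'
#' @param wtp Willingness-to-pay per QALY (lambda).
#' @param delta_cost,delta_effect Incremental cost and effect.
#' @return `wtp * delta_effect - delta_cost` (vectorised).
#' @export
net_monetary_benefit <- function(wtp, delta_cost, delta_effect) {
  wtp * delta_effect - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the ERP is
#' cost-effective: the fraction of PSA iterations with positive net
#' monetary benefit. At a willingness-to-pay of zero this is the
#' fraction of cost-saving draws.
#'
#' @param cloud A `psa_cloud` (or tibble with `delta_cost`,
#'   `delta_effect`).
#' @param wtp_grid Strictly increasing willingness-to-pay grid, GBP/QALY;
#'   default 0 to 50,000 in 1,000 steps, spanning the usual NICE
#'   threshold range.
#' @return Tibble with `wtp` and `probability`.
#' @examples
#' cloud <- run_psa(psa_config(markov_spec(), n_iterations = 50, seed = 1))
#' ceac(cloud)[1:5, ]
#' @export
ceac <- function(cloud, wtp_grid = seq(0, 50000, by = 1000)) {
  if (nrow(cloud) == 0) abort_domain("empty PSA cloud")
  if (length(wtp_grid) == 0) abort_domain("empty willingness-to-pay grid")
  if (any(diff(wtp_grid) <= 0)) {
    abort_domain("wtp_grid must be strictly increasing")
  }
  prob <- vapply(wtp_grid, function(l) {
    mean(net_monetary_benefit(l, cloud$delta_cost, cloud$delta_effect) > 0)
  }, numeric(1))
  tibble(wtp = wtp_grid, probability = prob)
}

#' Percentile intervals and ICER summary for a PSA cloud
#'
#' 95% percentile intervals (2.5th-97.5th) for the incremental cost and
#' effect, plus a ratio-free ICER summary: the median of per-draw ratios
#' over draws with a nonzero effect difference, and the share of draws in
#' each cost-effectiveness-plane quadrant (ratio confidence intervals are
#' unstable when a cloud straddles quadrants).
#'
#' @param cloud A `psa_cloud` with at least 40 iterations.
#' @return A list with tibbles `intervals` (quantity, lower, upper) and
#'   `quadrants` (quadrant, share), and scalar `icer_median`.
#' @export
interval_95 <- function(cloud) {
  if (nrow(cloud) < 40) abort_domain("need at least 40 iterations")
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  ci_c <- qs(cloud$delta_cost); ci_e <- qs(cloud$delta_effect)
  nz <- cloud$delta_effect != 0
  quad <- dplyr::case_when(
    cloud$delta_effect > 0 & cloud$delta_cost < 0 ~ "dominant",
    cloud$delta_effect >= 0 & cloud$delta_cost >= 0 ~ "more_costly_more_effective",
    cloud$delta_effect < 0 & cloud$delta_cost > 0 ~ "dominated",
    .default = "less_costly_less_effective"
  )
  shares <- tibble(quadrant = c("dominant", "more_costly_more_effective",
                                "dominated", "less_costly_less_effective")) |>
    mutate(share = vapply(.data$quadrant, function(qd) mean(quad == qd),
                          numeric(1)))
  list(
    intervals = tibble(quantity = c("delta_cost", "delta_effect"),
                       lower = c(ci_c[1], ci_e[1]),
                       upper = c(ci_c[2], ci_e[2])),
    icer_median = median(cloud$delta_cost[nz] / cloud$delta_effect[nz]),
    quadrants = shares
  )
}

#' @rdname run_psa
#' @param x A `psa_cloud`.
#' @param ... Unused.
#' @method glance psa_cloud
#' @export
glance.psa_cloud <- function(x, ...) {
  iv <- interval_95(x)
  tibble(
    n = nrow(x),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_effect = mean(x$delta_effect),
    delta_cost_lo = iv$intervals$lower[1],
    delta_cost_hi = iv$intervals$upper[1],
    delta_effect_lo = iv$intervals$lower[2],
    delta_effect_hi = iv$intervals$upper[2],
    icer_median = iv$icer_median,
    prob_ce_30k = mean(net_monetary_benefit(30000, x$delta_cost,
                                            x$delta_effect) > 0),
    n_resampled = attr(x, "n_resampled") %||% 0L
  )
}
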