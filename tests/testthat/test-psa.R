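fixed_plan <- function(spec) {
  cfg <- psa_config(spec, n_iterations = 1, seed = 1)
  lapply(cfg$parameters, function(d) list(family = "fixed", mean = d$mean))
}

test_that("degenerate distributions collapse onto the base case", {
  spec <- markov_spec()
  cfg <- psa_config(spec, n_iterations = 500, seed = 5,
                    parameters = fixed_plan(spec))
  cloud <- run_psa(cfg)
  base <- glance(run_cea(spec))
  # every draw is exactly the same point ...
  expect_true(all(cloud$delta_cost == cloud$delta_cost[1]))
  expect_true(all(cloud$delta_effect == cloud$delta_effect[1]))
  # ... and that point is the base case (to accumulation-order precision)
  expect_equal(cloud$delta_cost[1], base$delta_cost, tolerance = 1e-12)
  expect_equal(cloud$delta_effect[1], base$delta_effect, tolerance = 1e-12)
})

test_that("a fixed seed reproduces the cloud, CEAC and intervals", {
  cfg <- psa_config(markov_spec(), n_iterations = 300, seed = 42)
  a <- run_psa(cfg)
  b <- run_psa(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(ceac(a), ceac(b))
  expect_identical(interval_95(a), interval_95(b))
})

test_that("per-parameter streams are unaffected by adding a parameter", {
  spec <- markov_spec()
  cfg1 <- psa_config(spec, n_iterations = 50, seed = 9)
  cfg2 <- psa_config(spec, n_iterations = 50, seed = 9,
                     parameters = list(extra_thing = list(
                       family = "gamma", mean = 10, cv = 0.1)))
  d1 <- psa_draws(cfg1)
  d2 <- psa_draws(cfg2)
  for (id in names(d1)) expect_identical(d1[[id]], d2[[id]], label = id)
})

test_that("sampling families respect their supports and moments", {
  spec <- markov_spec()
  cfg <- psa_config(spec, n_iterations = 10000, seed = 3,
                    parameters = list(p = list(family = "beta", mean = 0.5,
                                               ess = 4)))
  d <- psa_draws(cfg)
  probs <- d[grep("^(ERP|STANDARD)\\.(p_|utility_)", names(d))]
  expect_true(all(unlist(probs) > 0 & unlist(probs) < 1))
  costs <- d[grep("cost", names(d))]
  expect_true(all(unlist(costs) >= 0))
  # beta(2,2) moment check: mean 0.5, sd sqrt(1/20)
  se <- sqrt(0.05 / 10000)
  expect_lt(abs(mean(d$p) - 0.5), 3 * se)
  expect_error(
    psa_config(spec, parameters = list(bad = list(family = "beta",
                                                  mean = 1.5, ess = 10))),
    class = "erpcea_config_error")
  expect_error(psa_config(spec, n_iterations = 0),
               class = "erpcea_config_error")
})

test_that("draw_parameters indexes the reproducible joint sample", {
  cfg <- psa_config(markov_spec(), n_iterations = 20, seed = 2)
  expect_identical(draw_parameters(cfg, 7), psa_draws(cfg)[7, ])
  expect_error(draw_parameters(cfg, 21), class = "erpcea_domain_error")
})

test_that("CEAC counts net-benefit-positive draws", {
  dominant <- tibble::tibble(delta_cost = -runif(200, 10, 100),
                             delta_effect = runif(200, 0.1, 1))
  expect_true(all(ceac(dominant)$probability == 1))
  dominated <- tibble::tibble(delta_cost = runif(200, 10, 100),
                              delta_effect = -runif(200, 0.1, 1))
  expect_true(all(ceac(dominated)$probability == 0))
  # constructed cloud: exactly half the draws have NMB > 0 at 30k
  half <- tibble::tibble(delta_cost = c(rep(1000, 50), rep(50000, 50)),
                         delta_effect = rep(1, 100))
  expect_equal(ceac(half, 30000)$probability, 0.5)
  # lambda = 0 counts the cost-saving draws
  mixed <- tibble::tibble(delta_cost = c(-5, -1, 2, 7),
                          delta_effect = rep(0.1, 4))
  expect_equal(ceac(mixed, 0)$probability, 0.5)
  # with all delta_effect > 0 the curve is non-decreasing in lambda
  set.seed(12)
  cloud <- tibble::tibble(delta_cost = rnorm(500, 0, 2000),
                          delta_effect = runif(500, 0.01, 1))
  curve <- ceac(cloud)
  expect_true(all(diff(curve$probability) >= 0))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_error(ceac(cloud, numeric()), class = "erpcea_domain_error")
  expect_error(ceac(cloud, c(2, 1)), class = "erpcea_domain_error")
})

test_that("net monetary benefit is linear in the increments", {
  expect_equal(net_monetary_benefit(30000, -100, 0.01), 400)
  k <- 3.7
  expect_equal(net_monetary_benefit(20000, k * -100, k * 0.01),
               k * net_monetary_benefit(20000, -100, 0.01))
})

test_that("percentile intervals and quadrant shares behave", {
  const <- tibble::tibble(delta_cost = rep(-5, 50),
                          delta_effect = rep(0.2, 50))
  iv <- interval_95(const)
  expect_equal(iv$intervals$lower, iv$intervals$upper)
  expect_equal(sum(iv$quadrants$share), 1)
  expect_equal(iv$icer_median, -25)
  set.seed(13)
  normal <- tibble::tibble(delta_cost = rnorm(1e5),
                           delta_effect = rep(1, 1e5))
  iv2 <- interval_95(normal)
  expect_equal(iv2$intervals$lower[1], -1.96, tolerance = 0.03)
  expect_equal(iv2$intervals$upper[1], 1.96, tolerance = 0.03)
  expect_error(interval_95(const[1:10, ]), class = "erpcea_domain_error")
})

test_that("cloud mean increments track the base case for mild spread", {
  cfg <- psa_config(markov_spec(), n_iterations = 2000, seed = 17)
  cloud <- run_psa(cfg)
  base <- glance(run_cea(markov_spec()))
  se_e <- stats::sd(cloud$delta_effect) / sqrt(nrow(cloud))
  expect_lt(abs(mean(cloud$delta_effect) - base$delta_effect), 3 * se_e)
  g <- glance(cloud)
  expect_equal(g$n, 2000)
  expect_equal(g$n_resampled, 0L)
})
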