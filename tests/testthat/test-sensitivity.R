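baseline_totals <- function(port) {
  aggregate_portfolio(port$scenarios, port$schedule)$totals
}

test_that("one-way analysis reproduces the baseline at the baseline value", {
  port <- dutch()
  base <- baseline_totals(port)
  p <- param_ref("hcp_cost_per_actionable", low = 16.39, high = 20)
  tab <- one_way(port$scenarios, port$schedule, p, n_points = 2)
  expect_equal(tab$deaths_prevented[1], base$deaths_prevented)
  expect_equal(tab$cost_total[1], base$cost_total)
  expect_equal(tab$cea[1], base$cea)
})

test_that("pooled CEA rises strictly with the test cost", {
  port <- dutch()
  tab <- one_way(port$scenarios, port$schedule,
                 param_ref("test_cost", low = 0, high = 132), n_points = 12)
  expect_true(all(diff(tab$cea) > 0))
  expect_true(all(diff(tab$deaths_prevented) == 0)) # cost enters numerator only
})

test_that("silencing the clopidogrel risk reduction removes its share", {
  port <- dutch()
  base <- baseline_totals(port)
  p <- param_ref("arr_multiplier", scenario = "Clopidogrel", low = 0, high = 1)
  tab <- one_way(port$scenarios, port$schedule, p, n_points = 2)
  remaining <- tab$deaths_prevented[tab$value == 0]
  clop <- deaths_prevented(dutch_scenario(port, "Clopidogrel"))
  expect_equal(remaining, base$deaths_prevented - clop)
  expect_gt(clop / base$deaths_prevented, 0.98)
})

test_that("out-of-domain parameter values raise a validation error", {
  port <- dutch()
  expect_error(
    one_way(port$scenarios, port$schedule,
            param_ref("test_cost", low = -10, high = 10), n_points = 3),
    class = "pgxcea_validation_error")
  expect_error(param_ref("not_a_field"), class = "pgxcea_validation_error")
  expect_error(param_ref("risk_tested"), class = "pgxcea_validation_error")
})

test_that("threshold search matches the closed-form linear solution", {
  port <- dutch()
  iri <- list(dutch_scenario(port, "Irinotecan"))
  sch <- port$schedule
  # cost_total(tc) = N*tc + hcp + drug_delta is linear in the test cost
  cb <- cost_breakdown(iri[[1]], sch)
  tc_star <- -(cb$cost_hcp + cb$cost_drug_delta) / iri[[1]]$initiators
  found <- threshold_search(iri, sch,
                            param_ref("test_cost", low = 0, high = 500),
                            target = 0, quantity = "cost_total")
  expect_lt(abs(found - tc_star), 1)

  # a uniform test cost hitting the baseline pooled CEA must equal the
  # baseline mean test cost per initiator (cost is linear in the test cost)
  base <- aggregate_portfolio(port$scenarios, sch)$totals
  v <- threshold_search(port$scenarios, sch,
                        param_ref("test_cost", low = 0, high = 132),
                        target = base$cea, quantity = "cea")
  expect_lt(abs(v - base$test_cost_per_initiator), 1)

  # no sign change over the bracket
  expect_error(
    threshold_search(port$scenarios, sch,
                     param_ref("test_cost", low = 0, high = 10),
                     target = -1e9, quantity = "cea"),
    class = "pgxcea_not_bracketed_error")
})

test_that("degenerate PSA distributions reproduce the baseline in every draw", {
  port <- dutch()
  base <- baseline_totals(port)
  res <- psa(port$scenarios, port$schedule,
             list(param_ref("test_cost", scenario = "Clopidogrel",
                            dist = list(dist = "fixed", value = 132)),
                  param_ref("hcp_cost_per_actionable",
                            dist = list(dist = "fixed", value = 16.39))),
             n_draws = 5, seed = 4L)
  expect_true(all(res$draws$deaths_prevented == base$deaths_prevented))
  expect_true(all(res$draws$cost_total == base$cost_total))
})

test_that("PSA is reproducible and unbiased for mean-matched distributions", {
  s <- toy_scenario()
  sch <- flat_schedule()
  # beta matched to the baseline actionable tested-arm risk of 0.02
  kappa <- 2000
  p <- param_ref("risk_tested", scenario = "toy-drug", phenotype = "P2",
                 dist = list(dist = "beta", shape1 = 0.02 * kappa,
                             shape2 = 0.98 * kappa))
  r1 <- psa(list(s), sch, list(p), n_draws = 400, seed = 21L)
  r2 <- psa(list(s), sch, list(p), n_draws = 400, seed = 21L)
  expect_identical(r1$summary, r2$summary)

  base <- deaths_prevented(s) # linear in risk_tested, so draws are unbiased
  m <- mean(r1$draws$deaths_prevented)
  se <- stats::sd(r1$draws$deaths_prevented) / sqrt(nrow(r1$draws))
  expect_lt(abs(m - base), 2 * se + 1e-9)
  expect_error(psa(list(s), sch, list(param_ref("test_cost")), n_draws = 2),
               class = "pgxcea_validation_error")
  expect_error(
    param_ref("test_cost", dist = list(dist = "beta", shape1 = -1, shape2 = 1)),
    class = "pgxcea_validation_error")
})
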