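test_that("the generator is deterministic and rejects degenerate settings", {
  spec <- generator_spec(n_scenarios = 5, seed = 11L)
  a <- generate_portfolio(spec)
  b <- generate_portfolio(spec)
  expect_identical(a, b)

  expect_error(generator_spec(risk_scale = 0.6, arr_scale = 0.5),
               class = "pgxcea_validation_error")
  expect_error(generator_spec(strata_range = c(5, 2)),
               class = "pgxcea_validation_error")
})

test_that("zero risk-reduction scale yields null portfolios", {
  port <- generate_portfolio(generator_spec(n_scenarios = 8, arr_scale = 0,
                                            seed = 3L))
  expect_true(all(purrr::map_dbl(port, deaths_prevented) == 0))
})

test_that("generated scenarios always satisfy the scenario invariants", {
  port <- generate_portfolio(generator_spec(n_scenarios = 200, seed = 7L))
  for (s in port) {
    expect_silent(validate_scenario(s))
    expect_equal(sum(s$strata$frequency), 1, tolerance = 1e-12)
    act <- s$strata$action != "none"
    expect_true(all(s$strata$risk_tested[act] <= s$strata$risk_untested[act]))
    expect_true(all(s$strata$risk_tested[!act] == s$strata$risk_untested[!act]))
  }
})

test_that("the microsimulation matches the analytic cohort expectation", {
  # degenerate case: no risk anywhere, no deaths in either arm
  zero <- toy_scenario(strata = toy_strata(risk_untested = c(0, 0),
                                           risk_tested = c(0, 0)))
  sim0 <- microsimulate(zero, n_patients = 1e4, seed = 5L)
  expect_equal(sim0$n_deaths_soc, 0)
  expect_equal(sim0$n_deaths_pgx, 0)
  expect_equal(sim0$deaths_prevented, 0)

  # determinism under a fixed seed
  s <- toy_scenario()
  expect_identical(microsimulate(s, 1e4, seed = 9L),
                   microsimulate(s, 1e4, seed = 9L))

  # 3-SE agreement on the azathioprine scenario (analytic 2.2535)
  aza <- dutch_scenario(dutch(), "Azathioprine")
  sim <- microsimulate(aza, n_patients = 1e6, seed = 20260923L)
  expect_lt(abs(deaths_prevented(aza) - sim$deaths_prevented), 3 * sim$se)
})

test_that("common random numbers make prevention non-negative per replicate", {
  port <- generate_portfolio(generator_spec(n_scenarios = 20, seed = 13L))
  for (s in port[1:20]) {
    sim <- microsimulate(s, n_patients = 2e4, seed = 17L)
    expect_gte(sim$n_deaths_soc, sim$n_deaths_pgx)
  }
})

test_that("the Monte-Carlo error shrinks as one over root n", {
  s <- toy_scenario()
  ratios <- purrr::map_dbl(1:10, function(seed) {
    se_small <- microsimulate(s, n_patients = 2e4, seed = seed)$se
    se_big <- microsimulate(s, n_patients = 8e4, seed = seed + 100L)$se
    se_small / se_big
  })
  # quadrupling the sample should halve the standard error
  expect_equal(mean(ratios), 2, tolerance = 0.2)
})

test_that("analytic deaths prevented sit inside the simulated 99.7% interval", {
  port <- generate_portfolio(generator_spec(n_scenarios = 50, seed = 20260923L))
  for (s in port) {
    sim <- microsimulate(s, n_patients = 1e5, seed = 20260923L)
    analytic <- deaths_prevented(s)
    # H0 standard error from the analytic prevention probability, so the
    # band is valid even when no discordant deaths were simulated
    p <- analytic / s$initiators
    se0 <- s$initiators * sqrt(p * (1 - p) / sim$n_patients)
    expect_lt(abs(analytic - sim$deaths_prevented),
              3 * max(sim$se, se0) + 1e-12)
  }
})
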