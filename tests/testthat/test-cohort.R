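test_that("initiator estimation multiplies users by the ratio, half-up", {
  expect_equal(estimate_initiators(10000, 1.0), 10000)
  expect_equal(estimate_initiators(0, 0.5), 0)
  expect_equal(estimate_initiators(200000, 0.5895), 117900)
  expect_equal(estimate_initiators(101, 0.5), 51) # 50.5 rounds half-up
  expect_error(estimate_initiators(-1, 0.5), class = "pgxcea_validation_error")
  expect_error(estimate_initiators(10, 1.5), class = "pgxcea_validation_error")
})

test_that("expected deaths equal the frequency-weighted cohort sum", {
  s <- toy_scenario() # 1000 * (0.9*0.01 + 0.1*0.05)
  expect_equal(expected_deaths(s, "soc"), 14)
  expect_equal(expected_deaths(s, "pgx"), 1000 * (0.9 * 0.01 + 0.1 * 0.02))

  zero <- toy_scenario(strata = toy_strata(risk_untested = c(0, 0),
                                           risk_tested = c(0, 0)))
  expect_equal(expected_deaths(zero, "soc"), 0)
  expect_equal(expected_deaths(zero, "pgx"), 0)

  aza <- dutch_scenario(dutch(), "Azathioprine")
  expect_equal(round_half_up(expected_deaths(aza, "soc"), 1), 15.8)
  expect_equal(round_half_up(expected_deaths(aza, "pgx"), 1), 13.5)
})

test_that("deaths prevented follow the risk-reduction identity", {
  aza <- dutch_scenario(dutch(), "Azathioprine")
  prev <- deaths_prevented(aza)
  expect_equal(round_half_up(prev, 1), 2.3)
  expect_equal(prev, 6979 * (0.087 * 0.0036 + 0.001 * 0.0097),
               tolerance = 1e-9)
  expect_equal(prev, expected_deaths(aza, "soc") - expected_deaths(aza, "pgx"))

  null <- toy_scenario(strata = toy_strata(risk_tested = c(0.01, 0.05)))
  expect_equal(deaths_prevented(null), 0)
})

test_that("NNG is the reciprocal frequency-weighted ARR, with a typed guard", {
  single <- toy_scenario(strata = toy_strata(
    freq = 1, action = "dose_adjust", risk_untested = 0.6, risk_tested = 0.1,
    phenotype = "P1"))
  expect_equal(nng(single), 2)

  aza <- dutch_scenario(dutch(), "Azathioprine")
  expect_equal(round_half_up(nng(aza)), 3097)

  null <- toy_scenario(strata = toy_strata(risk_tested = c(0.01, 0.05)))
  expect_error(nng(null), class = "pgxcea_undefined_nng")
})

test_that("actionable counts follow the guideline action flags", {
  port <- dutch()
  expect_equal(round_half_up(actionable_count(dutch_scenario(port, "Azathioprine"))),
               614)
  expect_equal(round_half_up(actionable_count(dutch_scenario(port, "Clopidogrel"))),
               33248)
  none <- toy_scenario(strata = toy_strata(
    action = c("none", "none"), risk_tested = c(0.01, 0.05)))
  expect_equal(actionable_count(none), 0)
  expect_equal(actionable_count(toy_scenario(), fraction = TRUE), 0.1)
})

test_that("relative risk reduction divides prevented by SoC deaths", {
  aza <- cohort_result(dutch_scenario(dutch(), "Azathioprine"))
  # printed inputs give 14.3%; the published 14.5% uses unrounded deaths
  expect_equal(relative_risk_reduction(aza), aza$deaths_prevented / aza$deaths_soc)
  expect_equal(round_half_up(100 * relative_risk_reduction(aza), 1), 14.3)

  null <- cohort_result(toy_scenario(strata = toy_strata(risk_tested = c(0.01, 0.05))))
  expect_equal(relative_risk_reduction(null), 0)

  no_deaths <- cohort_result(toy_scenario(strata = toy_strata(
    risk_untested = c(0, 0), risk_tested = c(0, 0))))
  expect_error(relative_risk_reduction(no_deaths), class = "pgxcea_undefined_rrr")
})

test_that("adoption and adherence scale the achieved benefit", {
  s <- toy_scenario()
  expect_equal(deaths_prevented(s, adoption = 0.5), 0.5 * deaths_prevented(s))
  expect_equal(deaths_prevented(s, adherence = 0), 0)
  expect_equal(actionable_count(s, adoption = 0.6, adherence = 0.5),
               0.3 * actionable_count(s))
  # arm decomposition still exact under partial uptake
  expect_equal(deaths_prevented(s, adoption = 0.7),
               expected_deaths(s, "soc") - expected_deaths(s, "pgx", adoption = 0.7))
})

test_that("half-up rounding rounds ties away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(418.5548), 419)
})
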