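test_that("scenario construction enforces structural invariants", {
  expect_s3_class(toy_scenario(), "dgi_scenario")

  # frequency sum must be within 0.005 of 1
  expect_error(
    toy_scenario(strata = toy_strata(freq = c(0.6, 0.3))),
    class = "pgxcea_validation_error")
  # printed-rounding slack: 0.998 is accepted
  expect_s3_class(
    toy_scenario(strata = toy_strata(freq = c(0.9, 0.098))),
    "dgi_scenario")

  # tested risk may not exceed untested risk on an actionable stratum
  expect_error(
    toy_strata(risk_untested = c(0.01, 0.02), risk_tested = c(0.01, 0.05)),
    class = "pgxcea_validation_error")

  # non-actionable strata must have identical risks in both arms
  expect_error(
    toy_strata(action = c("none", "none"),
               risk_untested = c(0.02, 0.05), risk_tested = c(0.01, 0.05)),
    class = "pgxcea_validation_error")

  # domain checks on scalars
  expect_error(toy_scenario(initiators = 0), class = "pgxcea_validation_error")
  expect_error(toy_scenario(certainty = 5), class = "pgxcea_validation_error")
  expect_error(toy_scenario(certainty = 2.5), class = "pgxcea_validation_error")
  expect_error(toy_scenario(test_cost = -1), class = "pgxcea_validation_error")
  expect_error(
    toy_scenario(strata = toy_strata(risk_untested = c(0.01, 1.2),
                                     risk_tested = c(0.01, 0.02))),
    class = "pgxcea_validation_error")
  expect_error(
    toy_strata(action = c("none", "bogus")),
    class = "pgxcea_validation_error")
})

test_that("initiators can be derived from users and the initiator ratio", {
  s <- dgi_scenario("d", "g", users = 200000, initiator_ratio = 0.5895,
                    strata = toy_strata(), test_cost = 132,
                    drug_cost_soc = 15, drug_cost_pgx = 38, certainty = 3)
  expect_equal(s$initiators, 117900)
  expect_error(
    dgi_scenario("d", "g", strata = toy_strata(), test_cost = 1,
                 drug_cost_soc = 1, drug_cost_pgx = 1, certainty = 1),
    class = "pgxcea_validation_error")
})

test_that("cost schedule derives the per-actionable cost from salaries", {
  sch <- cost_schedule(pharmacist_hourly = 40, physician_hourly = 80)
  expect_equal(sch$hcp_cost_per_actionable, 18 / 60 * 40 + 6 / 60 * 80)
  # direct override must agree with the salary-derived value when both given
  expect_error(
    cost_schedule(pharmacist_hourly = 40, physician_hourly = 80,
                  hcp_cost_per_actionable = 5),
    class = "pgxcea_validation_error")
  expect_equal(cost_schedule(hcp_cost_per_actionable = 16.39)$hcp_cost_per_actionable,
               16.39)
  expect_error(cost_schedule(), class = "pgxcea_validation_error")
})
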