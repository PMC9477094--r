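#' Specification for the synthetic portfolio generator
#'
#' Describes the random but structurally valid DGI portfolios used to
#' stress the analytic engine. Frequencies are drawn from a symmetric
#' simplex (Dirichlet) distribution whose concentration controls how rare
#' the rarest phenotype can get (published phenotype frequencies span
#' 0.001-0.925, i.e. heavily unbalanced, hence the default concentration
#' of 0.6). Each stratum carries a baseline (tested-arm) risk up to
#' `risk_scale`; actionable strata add an absolute risk reduction up to
#' `arr_scale` on top, so `risk_scale + arr_scale <= 1` keeps every risk a
#' probability.
#'
#' @param n_scenarios Number of scenarios to generate.
#' @param strata_range Integer `(min, max)` strata per scenario.
#' @param frequency_concentration Positive Dirichlet shape for the
#'   frequency simplex; small values produce rare phenotypes.
#' @param risk_scale Maximum baseline 1-year death risk.
#' @param arr_scale Maximum per-stratum absolute risk reduction.
#' @param initiator_range Integer `(min, max)` yearly initiators.
#' @param test_cost_range `(min, max)` test cost, EUR.
#' @param drug_cost_range `(min, max)` yearly per-initiator drug cost, EUR
#'   (both arms drawn independently, so the delta takes either sign).
#' @param seed Integer seed; identical specs generate identical portfolios.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(n_scenarios = 10, strata_range = c(2L, 6L),
                           frequency_concentration = 0.6,
                           risk_scale = 0.05, arr_scale = 0.02,
                           initiator_range = c(100L, 200000L),
                           test_cost_range = c(25, 200),
                           drug_cost_range = c(10, 20000),
                           seed = 1L) {
  check_number(n_scenarios, "n_scenarios", min = 1, integerish = TRUE)
  check_number(strata_range, "strata_range", min = 1, len = 2L,
               integerish = TRUE)
  check_number(frequency_concentration, "frequency_concentration",
               min = 1e-6)
  check_number(risk_scale, "risk_scale", min = 0, max = 1)
  check_number(arr_scale, "arr_scale", min = 0, max = 1)
  check_number(initiator_range, "initiator_range", min = 1, len = 2L)
  check_number(test_cost_range, "test_cost_range", min = 0, len = 2L)
  check_number(drug_cost_range, "drug_cost_range", min = 0, len = 2L)
  check_number(seed, "seed", integerish = TRUE)
  if (strata_range[2] < strata_range[1] ||
      initiator_range[2] < initiator_range[1] ||
      test_cost_range[2] < test_cost_range[1] ||
      drug_cost_range[2] < drug_cost_range[1]) {
    abort_validation("All (min, max) ranges must have max >= min.")
  }
  if (risk_scale + arr_scale > 1) {
    abort_validation("risk_scale + arr_scale must not exceed 1.")
  }
  structure(
    list(n_scenarios = as.integer(n_scenarios),
         strata_range = as.integer(strata_range),
         frequency_concentration = frequency_concentration,
         risk_scale = risk_scale, arr_scale = arr_scale,
         initiator_range = initiator_range,
         test_cost_range = test_cost_range,
         drug_cost_range = drug_cost_range,
         seed = as.integer(seed)),
    class = "generator_spec")
}

rdirichlet1 <- function(n, alpha) {
  g <- rgamma(n, shape = alpha)
  if (sum(g) == 0) g <- rep(1, n) # all-zero draw: fall back to uniform
  g / sum(g)
}

#' Generate a random, structurally valid DGI portfolio
#'
#' Draws `n_scenarios` scenarios under a [generator_spec()]. Every
#' generated scenario passes [validate_scenario()]: frequencies lie on the
#' simplex, non-actionable strata have identical risks across arms, and
#' tested-arm risks never exceed untested-arm risks. Each scenario gets at
#' least one actionable stratum (every published "essential" DGI has one);
#' further strata are actionable with probability one half.
#'
#' @param spec A [generator_spec()].
#' @return A list of [dgi_scenario()] objects.
#' @export
generate_portfolio <- function(spec) {
  if (!inherits(spec, "generator_spec")) {
    abort_validation("`spec` must be a `generator_spec`.")
  }
  withr::with_seed(spec$seed, {
    purrr::map(seq_len(spec$n_scenarios), function(i) {
      k <- sample(spec$strata_range[1]:spec$strata_range[2], 1L)
      freq <- rdirichlet1(k, spec$frequency_concentration)
      actionable <- c(TRUE, runif(k - 1) < 0.5)[sample.int(k)]
      action <- ifelse(actionable,
                       sample(c("dose_adjust", "alternative_drug"), k,
                              replace = TRUE),
                       "none")
      risk_tested <- runif(k, 0, spec$risk_scale)
      arr <- ifelse(actionable, runif(k, 0, spec$arr_scale), 0)
      strata <- phenotype_strata(
        phenotype = sprintf("PHENO%02d", seq_len(k)),
        frequency = freq, action = action,
        risk_untested = risk_tested + arr, risk_tested = risk_tested)
      dgi_scenario(
        drug = sprintf("synthetic-drug-%03d", i),
        gene = sprintf("SYNGENE%03d", i),
        initiators = round(runif(1, spec$initiator_range[1],
                                 spec$initiator_range[2])),
        strata = strata,
        test_cost = runif(1, spec$test_cost_range[1], spec$test_cost_range[2]),
        drug_cost_soc = runif(1, spec$drug_cost_range[1],
                              spec$drug_cost_range[2]),
        drug_cost_pgx = runif(1, spec$drug_cost_range[1],
                              spec$drug_cost_range[2]),
        certainty = sample(0:4, 1L))
    })
  })
}

#' Patient-level Monte-Carlo microsimulation of one scenario
#'
#' Independent oracle for the cohort expectations: each simulated patient
#' draws a phenotype from the categorical frequency distribution, then a
#' single uniform number decides death in both arms against the
#' per-stratum risks (common random numbers). Because
#' `risk_tested <= risk_untested`, a patient who dies in the PGx arm also
#' dies in the SoC arm, so the simulated deaths prevented is non-negative
#' in every replicate and the between-arm variance collapses to the
#' variance of the per-patient prevention indicator.
#'
#' Estimates are scaled from the `n_patients` sample to the scenario's
#' initiator count; the standard error reported for `deaths_prevented` is
#' on that scale.
#'
#' @param scenario A [dgi_scenario()].
#' @param n_patients Simulated patients (>= 1).
#' @param seed Integer seed.
#' @return List with `deaths_soc`, `deaths_pgx`, `deaths_prevented`
#'   (initiator-scaled estimates), `se` (standard error of
#'   `deaths_prevented`), raw counts `n_deaths_soc`, `n_deaths_pgx`, and
#'   `n_patients`, `seed`.
#' @export
microsimulate <- function(scenario, n_patients = 1e6, seed = 1L) {
  validate_scenario(scenario)
  check_number(n_patients, "n_patients", min = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  s <- scenario$strata
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(nrow(s), n_patients, replace = TRUE,
                      prob = s$frequency)
    u <- runif(n_patients)
    died_soc <- u < s$risk_untested[idx]
    died_pgx <- u < s$risk_tested[idx]
  })
  d <- as.numeric(died_soc) - as.numeric(died_pgx)
  scale <- scenario$initiators
  list(
    deaths_soc = scale * mean(died_soc),
    deaths_pgx = scale * mean(died_pgx),
    deaths_prevented = scale * mean(d),
    se = scale * stats::sd(d) / sqrt(n_patients),
    n_deaths_soc = sum(died_soc),
    n_deaths_pgx = sum(died_pgx),
    n_patients = as.integer(n_patients),
    seed = as.integer(seed)
  )
}
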