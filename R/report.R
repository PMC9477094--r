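# Report rendering: pure functions of the portfolio result plus the
# display-rounding rules (deaths 1 dp, euros/counts integer half-up,
# percentages 1 dp). CSVs carry plain numbers, no thousands separators.

#' Render the cost-side report table
#'
#' One row per DGI plus a TOTAL row: initiators, per-initiator test, HCP
#' and drug costs under both arms, and total incremental cost.
#'
#' @param result A [aggregate_portfolio()] result.
#' @param round Apply display rounding?
#' @return A tibble.
#' @export
render_table2 <- function(result, round = TRUE) {
  per <- result$per_scenario
  t <- result$totals
  eur <- function(x) if (round) round_half_up(x, 0) else x
  tab <- tibble::tibble(
    drug = per$drug,
    initiators = eur(per$initiators),
    test_cost_per_initiator = eur(per$cost_test / per$initiators),
    hcp_cost_per_initiator = eur(per$cost_hcp / per$initiators),
    drug_cost_soc_per_initiator = eur(per$drug_cost_soc),
    drug_cost_pgx_per_initiator = eur(per$drug_cost_pgx),
    drug_cost_delta_per_initiator = eur(per$cost_drug_delta / per$initiators),
    total_cost = eur(per$cost_total)
  )
  total <- tibble::tibble(
    drug = "TOTAL",
    initiators = eur(t$initiators),
    test_cost_per_initiator = eur(t$test_cost_per_initiator),
    hcp_cost_per_initiator = eur(t$cost_hcp / t$initiators),
    drug_cost_soc_per_initiator = eur(sum(per$initiators * per$drug_cost_soc) / t$initiators),
    drug_cost_pgx_per_initiator = eur(sum(per$initiators * per$drug_cost_pgx) / t$initiators),
    drug_cost_delta_per_initiator = eur(t$cost_drug_delta / t$initiators),
    total_cost = eur(t$cost_total)
  )
  dplyr::bind_rows(tab, total)
}

#' Render the cost-effectiveness report table
#'
#' One row per DGI plus a TOTAL row: actionable initiators, expected
#' deaths per arm, deaths prevented with relative risk reduction, number
#' needed to genotype, certainty score and cost per death prevented.
#' Undefined ratios render as `NA` (shown as empty cells in CSV).
#'
#' @inheritParams render_table2
#' @return A tibble.
#' @export
render_table3 <- function(result, round = TRUE) {
  per <- result$per_scenario
  t <- result$totals
  eur <- function(x) if (round) round_half_up(x, 0) else x
  dth <- function(x) if (round) round_half_up(x, 1) else x
  pct <- function(x) if (round) round_half_up(100 * x, 1) else 100 * x
  tab <- tibble::tibble(
    drug = per$drug,
    initiators = eur(per$initiators),
    n_actionable = eur(per$n_actionable),
    actionable_pct = pct(per$actionable_fraction),
    deaths_soc = dth(per$deaths_soc),
    deaths_pgx = dth(per$deaths_pgx),
    deaths_prevented = dth(per$deaths_prevented),
    rrr_pct = pct(per$rrr),
    nng = eur(per$nng),
    certainty = per$certainty,
    cost_per_death_prevented = eur(per$cea)
  )
  # the published table prints per-DGI deaths to 1 decimal but the TOTAL
  # row to whole deaths
  total <- tibble::tibble(
    drug = "TOTAL",
    initiators = eur(t$initiators),
    n_actionable = eur(t$n_actionable),
    actionable_pct = pct(t$actionable_fraction),
    deaths_soc = eur(t$deaths_soc),
    deaths_pgx = eur(t$deaths_pgx),
    deaths_prevented = eur(t$deaths_prevented),
    rrr_pct = pct(t$rrr),
    nng = NA_real_,
    certainty = if (round) round_half_up(t$certainty_by_deaths_prevented, 1)
                else t$certainty_by_deaths_prevented,
    cost_per_death_prevented = eur(t$cea)
  )
  dplyr::bind_rows(tab, total)
}

#' Run the model on a config and write the report
#'
#' Loads a portfolio config, evaluates the full model, and writes the two
#' report CSVs plus the unrounded JSON bundle into `out_dir`. This is the
#' programmatic core of the `run` subcommand of the bundled command-line
#' script (`system.file("cli", "pgxcea.R", package = "pgxcea")`).
#'
#' @param config Path to a portfolio config (see [load_portfolio()]).
#' @param out_dir Output directory.
#' @param round Display rounding for the CSVs (JSON is always unrounded).
#' @param seed Seed recorded in the output metadata (the baseline model is
#'   deterministic; the seed feeds optional stochastic follow-ups).
#' @return Invisibly, a list with `status` (0 on success), the `result`
#'   and the written `files`.
#' @export
cmd_run <- function(config, out_dir, round = TRUE, seed = 1L) {
  port <- load_portfolio(config)
  result <- aggregate_portfolio(port$scenarios, port$schedule)
  files <- write_results(result, out_dir, round = round,
                         metadata = list(
                           input_hash = unname(tools::md5sum(config)),
                           input_file = basename(config),
                           seed = as.integer(seed)))
  invisible(list(status = 0L, result = result, files = files))
}

#' Verify a portfolio config
#'
#' Runs every structural invariant check on a config and, optionally, the
#' microsimulation agreement check: for each scenario the analytic deaths
#' prevented must lie within three Monte-Carlo standard errors of the
#' patient-level estimate.
#'
#' @param config Path to a portfolio config.
#' @param oracle Also run the microsimulation agreement check?
#' @param n_patients Simulated patients per scenario for the oracle check.
#' @param seed Seed for the oracle check.
#' @return A list with `status` (0 if all checks pass, 1 otherwise) and
#'   `checks`, a tibble with one row per check (`scenario`, `check`,
#'   `passed`, `detail`).
#' @export
cmd_verify <- function(config, oracle = FALSE, n_patients = 1e5, seed = 1L) {
  checks <- list()
  add <- function(scenario, check, passed, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      scenario = scenario, check = check, passed = passed, detail = detail)
  }
  port <- tryCatch(load_portfolio(config), pgxcea_error = function(cnd) cnd)
  if (inherits(port, "condition")) {
    add("<config>", "load_and_validate", FALSE, conditionMessage(port))
  } else {
    add("<config>", "load_and_validate", TRUE,
        sprintf("%d scenarios", length(port$scenarios)))
    for (s in port$scenarios) {
      d_soc <- expected_deaths(s, "soc")
      d_pgx <- expected_deaths(s, "pgx")
      prev <- deaths_prevented(s)
      add(s$drug, "arm_decomposition",
          isTRUE(all.equal(prev, d_soc - d_pgx, tolerance = 1e-12)))
      if (arr_per_initiator(s) > 0) {
        add(s$drug, "nng_identity",
            abs(nng(s) * prev - s$initiators) <= 1e-9 * s$initiators)
      }
      if (oracle) {
        sim <- microsimulate(s, n_patients = n_patients, seed = seed)
        ok <- is.na(sim$se) || sim$se == 0 ||
          abs(prev - sim$deaths_prevented) <= 3 * sim$se
        add(s$drug, "microsim_3se", ok,
            sprintf("analytic %.3f vs simulated %.3f (SE %.3f)",
                    prev, sim$deaths_prevented, sim$se))
      }
    }
  }
  checks <- dplyr::bind_rows(checks)
  list(status = if (all(checks$passed)) 0L else 1L, checks = checks)
}
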