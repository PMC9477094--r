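#' Incremental cost breakdown for one scenario
#'
#' One-year incremental cost of PGx-guided prescribing versus standard of
#' care, from a healthcare perspective:
#' \itemize{
#'   \item `cost_test` — every initiator is genotyped once:
#'     `initiators * test_cost` (scaled by adoption);
#'   \item `cost_hcp` — only actionable results are recorded and discussed:
#'     expected actionable count times the per-actionable schedule cost;
#'   \item `cost_drug_delta` — difference in yearly drug spend:
#'     `initiators * (drug_cost_pgx - drug_cost_soc)`; may be negative
#'     (dose reductions save drug);
#'   \item `cost_total` — the sum. Negative totals mean the intervention
#'     is cost-saving.
#' }
#'
#' @inheritParams expected_deaths
#' @param schedule A [cost_schedule()].
#' @return A `cost_breakdown`: list with `cost_test`, `cost_hcp`,
#'   `cost_drug_delta`, `cost_total` (EUR/year, unrounded).
#' @export
cost_breakdown <- function(scenario, schedule, adoption = 1, adherence = 1) {
  validate_scenario(scenario)
  validate_schedule(schedule)
  check_number(adoption, "adoption", min = 0, max = 1)
  cost_test <- adoption * scenario$initiators * scenario$test_cost
  cost_hcp <- actionable_count(scenario, adoption = adoption,
                               adherence = adherence) *
    schedule$hcp_cost_per_actionable
  cost_drug_delta <- adoption * adherence * scenario$initiators *
    (scenario$drug_cost_pgx - scenario$drug_cost_soc)
  structure(
    list(
      drug = scenario$drug,
      cost_test = cost_test,
      cost_hcp = cost_hcp,
      cost_drug_delta = cost_drug_delta,
      cost_total = cost_test + cost_hcp + cost_drug_delta
    ),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> %s: test %.0f + HCP %.0f + drug delta %.0f = %.0f EUR/year\n",
              x$drug, x$cost_test, x$cost_hcp, x$cost_drug_delta, x$cost_total))
  invisible(x)
}

#' Cost-effectiveness ratio
#'
#' Incremental cost per gene-drug-related death prevented. An intervention
#' that both saves money and prevents deaths has a negative ratio and is
#' flagged `dominant`.
#'
#' @param cost A [cost_breakdown()].
#' @param result A [cohort_result()] for the same scenario.
#' @return A `cea_ratio`: list with `ratio` (EUR per death prevented) and
#'   logical `dominant`.
#' @section Errors: signals `pgxcea_undefined_cea` when no deaths are
#'   prevented.
#' @export
cea_ratio <- function(cost, result) {
  if (!inherits(cost, "cost_breakdown")) {
    abort_validation("`cost` must be a `cost_breakdown` object.")
  }
  if (!inherits(result, "cohort_result")) {
    abort_validation("`result` must be a `cohort_result` object.")
  }
  if (result$deaths_prevented <= 0) {
    abort_undefined("cea", sprintf(
      "Cost-effectiveness ratio is undefined for '%s': no deaths prevented.",
      result$drug))
  }
  structure(
    list(
      ratio = cost$cost_total / result$deaths_prevented,
      dominant = cost$cost_total < 0
    ),
    class = "cea_ratio"
  )
}

#' @export
print.cea_ratio <- function(x, ...) {
  cat(sprintf("<cea_ratio> %.0f EUR per death prevented%s\n", x$ratio,
              if (x$dominant) " (dominant: cost-saving and life-saving)" else ""))
  invisible(x)
}
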