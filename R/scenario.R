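#' Phenotype strata for a drug-gene interaction
#'
#' Builds the validated tibble of predicted phenotype categories for one
#' drug-gene interaction (DGI). Each stratum carries its population
#' frequency, the kind of prescribing action the guideline recommends, and
#' the absolute risk of gene-drug-related death within one year under both
#' arms: `risk_untested` (standard of care) and `risk_tested` (PGx-guided
#' dose or drug selection).
#'
#' Non-actionable strata (`action = "none"`) must have identical risks in
#' both arms: if the test does not change the prescription it cannot change
#' the outcome. On actionable strata `risk_tested <= risk_untested`; the
#' absolute risk reduction (ARR) is their difference.
#'
#' @param phenotype Character vector of phenotype labels (e.g. "TPMT IM").
#' @param frequency Numeric vector of population frequencies in `[0, 1]`.
#' @param action Character vector: one of `"none"`, `"dose_adjust"`,
#'   `"alternative_drug"` per stratum.
#' @param risk_untested,risk_tested Per-stratum 1-year probabilities of
#'   gene-drug-related death under standard of care and PGx-guided care.
#' @return A tibble with one row per stratum, columns
#'   `phenotype, frequency, action, risk_untested, risk_tested`.
#' @examples
#' phenotype_strata(
#'   phenotype = c("EM", "IM"),
#'   frequency = c(0.9, 0.1),
#'   action = c("none", "dose_adjust"),
#'   risk_untested = c(0.002, 0.006),
#'   risk_tested = c(0.002, 0.002)
#' )
#' @export
phenotype_strata <- function(phenotype, frequency, action,
                             risk_untested, risk_tested) {
  strata <- tibble::tibble(
    phenotype = as.character(phenotype),
    frequency = as.numeric(frequency),
    action = as.character(action),
    risk_untested = as.numeric(risk_untested),
    risk_tested = as.numeric(risk_tested)
  )
  validate_strata(strata)
  strata
}

stratum_actions <- c("none", "dose_adjust", "alternative_drug")

validate_strata <- function(strata, where = "strata") {
  if (!is.data.frame(strata) || nrow(strata) == 0) {
    abort_validation(sprintf("`%s` must be a data frame with >= 1 row.", where))
  }
  needed <- c("phenotype", "frequency", "action", "risk_untested", "risk_tested")
  missing <- setdiff(needed, names(strata))
  if (length(missing)) {
    abort_validation(sprintf("`%s` lacks column(s): %s.", where,
                             paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(strata$action), stratum_actions)
  if (length(bad)) {
    abort_validation(sprintf(
      "`%s`: unknown action(s) %s (allowed: %s).", where,
      paste(sQuote(bad), collapse = ", "),
      paste(stratum_actions, collapse = ", ")))
  }
  check_number(strata$frequency, paste0(where, "$frequency"),
               min = 0, max = 1, len = nrow(strata))
  check_number(strata$risk_untested, paste0(where, "$risk_untested"),
               min = 0, max = 1, len = nrow(strata))
  check_number(strata$risk_tested, paste0(where, "$risk_tested"),
               min = 0, max = 1, len = nrow(strata))
  act <- strata$action != "none"
  if (any(strata$risk_tested[act] > strata$risk_untested[act] + 1e-12)) {
    i <- which(act & strata$risk_tested > strata$risk_untested + 1e-12)[1]
    abort_validation(sprintf(
      "`%s` row %d (%s): risk_tested (%g) exceeds risk_untested (%g) on an actionable stratum.",
      where, i, strata$phenotype[i], strata$risk_tested[i],
      strata$risk_untested[i]))
  }
  eq <- abs(strata$risk_tested - strata$risk_untested) > 1e-12
  if (any(!act & eq)) {
    i <- which(!act & eq)[1]
    abort_validation(sprintf(
      "`%s` row %d (%s): action is 'none' but risks differ across arms; testing cannot change the outcome of a non-actionable stratum.",
      where, i, strata$phenotype[i]))
  }
  invisible(strata)
}

#' Construct a drug-gene interaction scenario
#'
#' A `dgi_scenario` bundles everything the cohort model needs for one
#' drug-gene pair: the yearly number of drug initiators, the per-test and
#' per-initiator yearly drug costs under both arms, the phenotype strata
#' (see [phenotype_strata()]) and a 0-4 certainty grade of the underlying
#' risk evidence (4 = very certain, 0 = very uncertain).
#'
#' Stratum frequencies must sum to 1 within 0.005 (published frequencies
#' are rounded to three decimals). `users` and `initiator_ratio` are
#' optional provenance fields; when both are given and `initiators` is not,
#' initiators are derived with [estimate_initiators()].
#'
#' @param drug,gene Names of the drug and the pharmacogene.
#' @param initiators Patients starting the drug per year (positive).
#' @param strata Tibble from [phenotype_strata()].
#' @param test_cost Cost of the single-gene PGx test, EUR per initiator.
#' @param drug_cost_soc,drug_cost_pgx Average yearly drug cost per
#'   initiator under standard of care / PGx-guided treatment, EUR.
#' @param certainty Integer 0-4 evidence-certainty score.
#' @param users,initiator_ratio Optional: yearly users and the
#'   initiator/user ratio from which `initiators` was derived.
#' @return An object of class `dgi_scenario`.
#' @seealso [cohort_result()], [cost_breakdown()], [load_portfolio()]
#' @export
dgi_scenario <- function(drug, gene, initiators = NULL, strata,
                         test_cost, drug_cost_soc, drug_cost_pgx,
                         certainty, users = NA_real_,
                         initiator_ratio = NA_real_) {
  if (is.null(initiators)) {
    if (is.na(users) || is.na(initiator_ratio)) {
      abort_validation(
        "Provide `initiators`, or both `users` and `initiator_ratio`.")
    }
    initiators <- estimate_initiators(users, initiator_ratio)
  }
  scenario <- structure(
    list(
      drug = as.character(drug)[1],
      gene = as.character(gene)[1],
      initiators = as.numeric(initiators),
      users = as.numeric(users),
      initiator_ratio = as.numeric(initiator_ratio),
      test_cost = as.numeric(test_cost),
      drug_cost_soc = as.numeric(drug_cost_soc),
      drug_cost_pgx = as.numeric(drug_cost_pgx),
      strata = tibble::as_tibble(strata),
      certainty = as.numeric(certainty)
    ),
    class = "dgi_scenario"
  )
  validate_scenario(scenario)
  scenario
}

#' Validate a drug-gene interaction scenario
#'
#' Checks all structural invariants of a [dgi_scenario()]: positive
#' initiators, non-negative costs, certainty in 0..4, frequency sum within
#' 0.005 of 1, risk ordering on actionable strata, and equal risks on
#' non-actionable strata. Called by every model operation; exported so that
#' loaders and generators can fail early with a field-level message.
#'
#' @param scenario A `dgi_scenario`.
#' @return The scenario, invisibly; signals a `pgxcea_validation_error`
#'   on the first violated invariant.
#' @export
validate_scenario <- function(scenario) {
  if (!inherits(scenario, "dgi_scenario")) {
    abort_validation("`scenario` must be a `dgi_scenario` object.")
  }
  where <- sprintf("scenario '%s'", scenario$drug)
  check_number(scenario$initiators, paste0(where, ": initiators"), min = 0)
  if (scenario$initiators <= 0) {
    abort_validation(paste0(where, ": initiators must be > 0."))
  }
  check_number(scenario$test_cost, paste0(where, ": test_cost"), min = 0)
  check_number(scenario$drug_cost_soc, paste0(where, ": drug_cost_soc"), min = 0)
  check_number(scenario$drug_cost_pgx, paste0(where, ": drug_cost_pgx"), min = 0)
  check_number(scenario$certainty, paste0(where, ": certainty"),
               min = 0, max = 4, integerish = TRUE)
  validate_strata(scenario$strata, where = paste0(where, " strata"))
  fsum <- sum(scenario$strata$frequency)
  if (abs(fsum - 1) > 0.005) {
    abort_validation(sprintf(
      "%s: stratum frequencies sum to %.4f; must be within 0.005 of 1.",
      where, fsum))
  }
  invisible(scenario)
}

#' @export
print.dgi_scenario <- function(x, ...) {
  cat(sprintf("<dgi_scenario> %s (%s), %s initiators/year\n",
              x$drug, x$gene, format(x$initiators, big.mark = ",")))
  cat(sprintf("  test %.2f EUR, drug SoC %.2f vs PGx %.2f EUR/initiator-year, certainty %d/4\n",
              x$test_cost, x$drug_cost_soc, x$drug_cost_pgx,
              as.integer(x$certainty)))
  print(x$strata, ...)
  invisible(x)
}
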