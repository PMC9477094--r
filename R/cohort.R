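# Cohort expectations for a single DGI scenario.
#
# Deaths under an arm are the cohort expectation
#   N * sum_pheno P_pheno * AR_pheno(arm),
# deaths prevented the frequency-weighted absolute risk reduction times N.
# `adoption` (fraction of initiators tested) and `adherence` (fraction of
# actionable results acted upon) enter as multipliers on the risk
# reduction and on the actionable count; both default to 1.

#' Estimate yearly drug initiators from users
#'
#' Converts a yearly user count into a yearly initiator count by the
#' initiator/user ratio observed in prescription records, rounding half-up
#' to a whole patient.
#'
#' @param users Yearly number of users of the drug (>= 0).
#' @param initiator_ratio Fraction of users who are initiators, in `[0, 1]`.
#' @return Integer-valued number of initiators per year.
#' @examples
#' estimate_initiators(200000, 0.5895) # 117900
#' @export
estimate_initiators <- function(users, initiator_ratio) {
  check_number(users, "users", min = 0)
  check_number(initiator_ratio, "initiator_ratio", min = 0, max = 1)
  round_half_up(users * initiator_ratio, 0)
}

arr_per_initiator <- function(scenario, adoption = 1, adherence = 1) {
  s <- scenario$strata
  adoption * adherence * sum(s$frequency * (s$risk_untested - s$risk_tested))
}

#' Expected gene-drug-related deaths in one arm
#'
#' @param scenario A [dgi_scenario()].
#' @param arm `"soc"` (standard of care, risks as untested) or `"pgx"`
#'   (PGx-guided care, risks as tested).
#' @param adoption,adherence Fractions in `[0, 1]` applied to the risk
#'   reduction achieved in the PGx arm; at 1 (the default) every initiator
#'   is tested and every actionable recommendation followed.
#' @return Expected deaths per year (unrounded).
#' @examples
#' s <- dgi_scenario("toy", "GENE", initiators = 1000,
#'   strata = phenotype_strata(c("EM", "PM"), c(0.9, 0.1),
#'     c("none", "dose_adjust"), c(0.01, 0.05), c(0.01, 0.02)),
#'   test_cost = 50, drug_cost_soc = 100, drug_cost_pgx = 100, certainty = 3)
#' expected_deaths(s, "soc") # 14
#' @export
expected_deaths <- function(scenario, arm = c("soc", "pgx"),
                            adoption = 1, adherence = 1) {
  validate_scenario(scenario)
  arm <- match.arg(arm)
  check_number(adoption, "adoption", min = 0, max = 1)
  check_number(adherence, "adherence", min = 0, max = 1)
  soc <- scenario$initiators *
    sum(scenario$strata$frequency * scenario$strata$risk_untested)
  if (arm == "soc") {
    return(soc)
  }
  # pgx arm as SoC minus the achieved reduction, so the arm decomposition
  # deaths_prevented = deaths_soc - deaths_pgx holds exactly at any uptake
  soc - scenario$initiators * arr_per_initiator(scenario, adoption, adherence)
}

#' Expected gene-drug-related deaths prevented per year
#'
#' The cohort expectation `N * sum_pheno P_pheno * ARR_pheno`, equal by
#' construction to `expected_deaths(soc) - expected_deaths(pgx)`.
#'
#' @inheritParams expected_deaths
#' @return Deaths prevented per year (unrounded).
#' @export
deaths_prevented <- function(scenario, adoption = 1, adherence = 1) {
  validate_scenario(scenario)
  check_number(adoption, "adoption", min = 0, max = 1)
  check_number(adherence, "adherence", min = 0, max = 1)
  scenario$initiators * arr_per_initiator(scenario, adoption, adherence)
}

#' Number needed to genotype
#'
#' Patients who must be genotyped to prevent one gene-drug-related death:
#' the reciprocal of the frequency-weighted absolute risk reduction. The
#' identity `nng * deaths_prevented = initiators` holds whenever the NNG
#' is defined.
#'
#' @inheritParams expected_deaths
#' @return NNG in patients (unrounded).
#' @section Errors: signals a `pgxcea_undefined_nng` condition when the
#'   total risk reduction is zero (no actionable benefit), rather than
#'   returning infinity.
#' @export
nng <- function(scenario, adoption = 1, adherence = 1) {
  validate_scenario(scenario)
  arr <- arr_per_initiator(scenario, adoption, adherence)
  if (arr <= 0) {
    abort_undefined("nng", sprintf(
      "NNG is undefined for scenario '%s': total absolute risk reduction is zero.",
      scenario$drug))
  }
  1 / arr
}

#' Expected number of initiators with an actionable result
#'
#' Initiators whose predicted phenotype triggers a dose adjustment or an
#' alternative drug: `initiators * sum(frequency)` over actionable strata,
#' scaled by adoption and adherence.
#'
#' @inheritParams expected_deaths
#' @param fraction If `TRUE`, return the actionable fraction of initiators
#'   instead of the expected count.
#' @return Expected count (or fraction) of actionable initiators.
#' @export
actionable_count <- function(scenario, fraction = FALSE,
                             adoption = 1, adherence = 1) {
  validate_scenario(scenario)
  check_number(adoption, "adoption", min = 0, max = 1)
  check_number(adherence, "adherence", min = 0, max = 1)
  f <- adoption * adherence *
    sum(scenario$strata$frequency[scenario$strata$action != "none"])
  if (fraction) f else scenario$initiators * f
}

#' Relative risk reduction of a cohort result
#'
#' Deaths prevented divided by deaths under standard of care.
#'
#' @param result A [cohort_result()].
#' @return RRR as a fraction.
#' @section Errors: signals `pgxcea_undefined_rrr` when there are no
#'   standard-of-care deaths to reduce.
#' @export
relative_risk_reduction <- function(result) {
  if (!inherits(result, "cohort_result")) {
    abort_validation("`result` must be a `cohort_result` object.")
  }
  if (result$deaths_soc <= 0) {
    abort_undefined("rrr",
      "Relative risk reduction is undefined: no deaths under standard of care.")
  }
  result$deaths_prevented / result$deaths_soc
}

#' Full cohort result for one scenario
#'
#' Evaluates the decision-analytic model for one drug-gene interaction and
#' returns all mortality-side quantities. The NNG is `NA` (not an error)
#' when undefined, so that portfolios containing a null-benefit scenario
#' can still be aggregated; [nng()] is the strict accessor.
#'
#' @inheritParams expected_deaths
#' @return A `cohort_result`: list with `drug`, `gene`, `initiators`,
#'   `deaths_soc`, `deaths_pgx`, `deaths_prevented`, `rrr`, `nng`,
#'   `n_actionable`, `actionable_fraction`, `certainty`.
#' @export
cohort_result <- function(scenario, adoption = 1, adherence = 1) {
  validate_scenario(scenario)
  d_soc <- expected_deaths(scenario, "soc")
  d_pgx <- d_soc - deaths_prevented(scenario, adoption, adherence)
  # restate as the arm difference so the stored triple is exactly
  # self-consistent in floating point
  prevented <- d_soc - d_pgx
  arr <- arr_per_initiator(scenario, adoption, adherence)
  structure(
    list(
      drug = scenario$drug,
      gene = scenario$gene,
      initiators = scenario$initiators,
      deaths_soc = d_soc,
      deaths_pgx = d_pgx,
      deaths_prevented = prevented,
      rrr = if (d_soc > 0) prevented / d_soc else NA_real_,
      nng = if (arr > 0) 1 / arr else NA_real_,
      n_actionable = actionable_count(scenario, adoption = adoption,
                                      adherence = adherence),
      actionable_fraction = actionable_count(scenario, fraction = TRUE,
                                             adoption = adoption,
                                             adherence = adherence),
      certainty = scenario$certainty
    ),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s: %.1f SoC vs %.1f PGx deaths/year, %.1f prevented (RRR %.1f%%), NNG %s\n",
              x$drug, x$deaths_soc, x$deaths_pgx, x$deaths_prevented,
              100 * x$rrr,
              if (is.na(x$nng)) "undefined" else format(round_half_up(x$nng, 0))))
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used throughout the reports: deaths to one decimal,
#' euro amounts and patient counts to the nearest integer, with ties going
#' away from zero (so 0.5 -> 1, unlike [round()]'s banker's rounding).
#' Model internals are never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
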