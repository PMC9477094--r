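#' Evidence-certainty score averaged over a portfolio
#'
#' Weighted mean of per-scenario certainty scores (0-4), weighted either
#' by expected deaths prevented or by number of initiators.
#'
#' @param scenarios List of [dgi_scenario()] objects.
#' @param weights `"deaths_prevented"` or `"initiators"`.
#' @return Weighted certainty score in `[0, 4]`.
#' @export
weighted_certainty <- function(scenarios,
                               weights = c("deaths_prevented", "initiators")) {
  weights <- match.arg(weights)
  if (length(scenarios) == 0) {
    abort_validation("`scenarios` must contain at least one scenario.")
  }
  purrr::walk(scenarios, validate_scenario)
  w <- switch(weights,
    deaths_prevented = purrr::map_dbl(scenarios, deaths_prevented),
    initiators = purrr::map_dbl(scenarios, function(s) s$initiators)
  )
  if (sum(w) <= 0) {
    abort_validation(sprintf("All %s weights are zero; weighted certainty is undefined.",
                             weights))
  }
  cert <- purrr::map_dbl(scenarios, function(s) s$certainty)
  sum(w * cert) / sum(w)
}

#' Evaluate a full DGI portfolio
#'
#' Runs the cohort and cost model on every scenario and forms the TOTAL
#' row. Every total is the sum (or ratio of sums) of per-scenario values;
#' there is no independent computation path for the totals.
#'
#' Pooled quantities: RRR = total prevented / total SoC deaths; cost per
#' death prevented = total incremental cost / total prevented; actionable
#' fraction = total actionable / total initiators.
#'
#' @param scenarios List of [dgi_scenario()] objects (non-empty).
#' @param schedule A [cost_schedule()].
#' @inheritParams expected_deaths
#' @return A `portfolio_result`: list with
#'   \itemize{
#'     \item `per_scenario` — tibble, one row per DGI with all cohort and
#'       cost fields plus `cea` and `dominant` (`cea` is `NA` when no
#'       deaths are prevented);
#'     \item `totals` — named list with summed deaths, costs, pooled RRR,
#'       pooled CEA, actionable counts and the two weighted certainty
#'       scores.
#'   }
#' @export
aggregate_portfolio <- function(scenarios, schedule,
                                adoption = 1, adherence = 1) {
  if (!is.list(scenarios) || length(scenarios) == 0 ||
      inherits(scenarios, "dgi_scenario")) {
    abort_validation("`scenarios` must be a non-empty list of dgi_scenario objects.")
  }
  validate_schedule(schedule)
  rows <- lapply(scenarios, function(s) { # lapply keeps condition classes
    res <- withCallingHandlers(
      {
        r <- cohort_result(s, adoption, adherence)
        cb <- cost_breakdown(s, schedule, adoption, adherence)
        list(r = r, cb = cb)
      },
      pgxcea_error = function(cnd) {
        abort_validation(sprintf("scenario '%s': %s", s$drug,
                                 conditionMessage(cnd)),
                         parent = cnd)
      }
    )
    r <- res$r; cb <- res$cb
    tibble::tibble(
      drug = r$drug, gene = r$gene, initiators = r$initiators,
      n_actionable = r$n_actionable,
      actionable_fraction = r$actionable_fraction,
      deaths_soc = r$deaths_soc, deaths_pgx = r$deaths_pgx,
      deaths_prevented = r$deaths_prevented,
      rrr = r$rrr, nng = r$nng, certainty = r$certainty,
      test_cost = s$test_cost, drug_cost_soc = s$drug_cost_soc,
      drug_cost_pgx = s$drug_cost_pgx,
      cost_test = cb$cost_test, cost_hcp = cb$cost_hcp,
      cost_drug_delta = cb$cost_drug_delta, cost_total = cb$cost_total,
      cea = if (r$deaths_prevented > 0) cb$cost_total / r$deaths_prevented else NA_real_,
      dominant = cb$cost_total < 0 && r$deaths_prevented > 0
    )
  })
  per <- dplyr::bind_rows(rows)

  tot_prev <- sum(per$deaths_prevented)
  tot_soc <- sum(per$deaths_soc)
  tot_cost <- sum(per$cost_total)
  tot_init <- sum(per$initiators)
  tot_act <- sum(per$n_actionable)
  totals <- list(
    initiators = tot_init,
    n_actionable = tot_act,
    actionable_fraction = tot_act / tot_init,
    deaths_soc = tot_soc,
    deaths_pgx = sum(per$deaths_pgx),
    deaths_prevented = tot_prev,
    rrr = if (tot_soc > 0) tot_prev / tot_soc else NA_real_,
    cost_test = sum(per$cost_test),
    cost_hcp = sum(per$cost_hcp),
    cost_drug_delta = sum(per$cost_drug_delta),
    cost_total = tot_cost,
    cost_per_initiator = tot_cost / tot_init,
    test_cost_per_initiator = sum(per$cost_test) / tot_init,
    hcp_cost_per_actionable = if (tot_act > 0) sum(per$cost_hcp) / tot_act else NA_real_,
    cea = if (tot_prev > 0) tot_cost / tot_prev else NA_real_,
    certainty_by_deaths_prevented =
      if (tot_prev > 0) sum(per$certainty * per$deaths_prevented) / tot_prev else NA_real_,
    certainty_by_initiators = sum(per$certainty * per$initiators) / tot_init
  )
  structure(
    list(per_scenario = per, totals = totals,
         adoption = adoption, adherence = adherence),
    class = "portfolio_result"
  )
}

#' @export
print.portfolio_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<portfolio_result> %d DGIs, %s initiators/year\n",
              nrow(x$per_scenario), format(t$initiators, big.mark = ",")))
  cat(sprintf("  deaths: %.1f SoC vs %.1f PGx, %.1f prevented (pooled RRR %.1f%%)\n",
              t$deaths_soc, t$deaths_pgx, t$deaths_prevented, 100 * t$rrr))
  cat(sprintf("  actionable initiators: %s (%.1f%%)\n",
              format(round_half_up(t$n_actionable), big.mark = ","),
              100 * t$actionable_fraction))
  cat(sprintf("  incremental cost: %.0f EUR/year; %.0f EUR per death prevented\n",
              t$cost_total, t$cea))
  invisible(x)
}
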