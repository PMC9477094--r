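#' Health-care-professional interpretation cost schedule
#'
#' Cost of recording and discussing one actionable PGx result. The default
#' time budget is 18 pharmacist-minutes (recording the result, discussing
#' it with physician and patient) plus 6 physician-minutes. When hourly
#' salaries are supplied the per-actionable cost is derived as the
#' minute-weighted sum; alternatively `hcp_cost_per_actionable` can be set
#' directly (the bundled Dutch portfolio does this, since the salary tables
#' behind the published figure are not public).
#'
#' @param pharmacist_minutes,physician_minutes Time per actionable result.
#' @param pharmacist_hourly,physician_hourly Hourly salaries, EUR/h.
#' @param hcp_cost_per_actionable Direct per-actionable cost, EUR.
#'   Overrides the salary-derived value when given.
#' @return An object of class `cost_schedule`.
#' @examples
#' cost_schedule(pharmacist_hourly = 40, physician_hourly = 80) # 20 EUR
#' cost_schedule(hcp_cost_per_actionable = 16.39)
#' @export
cost_schedule <- function(pharmacist_minutes = 18, physician_minutes = 6,
                          pharmacist_hourly = NULL, physician_hourly = NULL,
                          hcp_cost_per_actionable = NULL) {
  check_number(pharmacist_minutes, "pharmacist_minutes", min = 0)
  check_number(physician_minutes, "physician_minutes", min = 0)
  derived <- NA_real_
  if (!is.null(pharmacist_hourly) && !is.null(physician_hourly)) {
    check_number(pharmacist_hourly, "pharmacist_hourly", min = 0)
    check_number(physician_hourly, "physician_hourly", min = 0)
    derived <- pharmacist_minutes / 60 * pharmacist_hourly +
      physician_minutes / 60 * physician_hourly
  }
  if (is.null(hcp_cost_per_actionable)) {
    if (is.na(derived)) {
      abort_validation(paste0(
        "Provide either both hourly rates or `hcp_cost_per_actionable`."))
    }
    hcp_cost_per_actionable <- derived
  } else {
    check_number(hcp_cost_per_actionable, "hcp_cost_per_actionable", min = 0)
    if (!is.na(derived) &&
        abs(derived - hcp_cost_per_actionable) > 1e-6 * max(1, derived)) {
      abort_validation(sprintf(
        "hcp_cost_per_actionable (%.4f) disagrees with the minute-weighted salary value (%.4f).",
        hcp_cost_per_actionable, derived))
    }
  }
  structure(
    list(
      pharmacist_minutes = as.numeric(pharmacist_minutes),
      physician_minutes = as.numeric(physician_minutes),
      pharmacist_hourly = if (is.null(pharmacist_hourly)) NA_real_ else as.numeric(pharmacist_hourly),
      physician_hourly = if (is.null(physician_hourly)) NA_real_ else as.numeric(physician_hourly),
      hcp_cost_per_actionable = as.numeric(hcp_cost_per_actionable)
    ),
    class = "cost_schedule"
  )
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat(sprintf(
    "<cost_schedule> %.0f pharmacist-min + %.0f physician-min per actionable result = %.2f EUR\n",
    x$pharmacist_minutes, x$physician_minutes, x$hcp_cost_per_actionable))
  invisible(x)
}

validate_schedule <- function(schedule) {
  if (!inherits(schedule, "cost_schedule")) {
    abort_validation("`schedule` must be a `cost_schedule` object.")
  }
  check_number(schedule$hcp_cost_per_actionable,
               "schedule$hcp_cost_per_actionable", min = 0)
  invisible(schedule)
}
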