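# Sensitivity analyses over scalar model inputs. A ParamRef names one
# input (for one scenario or ALL), its exploration bounds, and optionally
# a sampling distribution for probabilistic analysis: beta for
# probabilities, gamma for costs, fixed for degenerate draws.

#' Reference to a scalar model input
#'
#' Addresses one tunable input of a portfolio for use with [one_way()],
#' [threshold_search()] and [psa()].
#'
#' Supported fields: scenario-level `test_cost`, `drug_cost_soc`,
#' `drug_cost_pgx`, `initiators` and `arr_multiplier` (a factor on every
#' stratum's absolute risk reduction, 1 = baseline, 0 = null
#' intervention); schedule-level `hcp_cost_per_actionable`; stratum-level
#' `risk_tested`, `risk_untested`, `frequency` (require `phenotype`;
#' frequencies are renormalised jointly to the simplex after the change).
#'
#' @param field Field name (see Details).
#' @param scenario Drug name the reference applies to, or `"ALL"`.
#' @param phenotype Stratum label, for stratum-level fields.
#' @param low,high Exploration bounds for [one_way()] and
#'   [threshold_search()].
#' @param dist Sampling distribution for [psa()]: one of
#'   `list(dist = "beta", shape1 =, shape2 =)`,
#'   `list(dist = "gamma", shape =, rate =)`,
#'   `list(dist = "fixed", value =)`.
#' @return A `param_ref` object.
#' @export
param_ref <- function(field, scenario = "ALL", phenotype = NULL,
                      low = NULL, high = NULL, dist = NULL) {
  fields <- c("test_cost", "drug_cost_soc", "drug_cost_pgx", "initiators",
              "arr_multiplier", "hcp_cost_per_actionable",
              "risk_tested", "risk_untested", "frequency")
  if (!is.character(field) || length(field) != 1 || !field %in% fields) {
    abort_validation(sprintf("Unknown field '%s'; use one of: %s.",
                             paste(field, collapse = ","),
                             paste(fields, collapse = ", ")))
  }
  stratum_level <- field %in% c("risk_tested", "risk_untested", "frequency")
  if (stratum_level && is.null(phenotype)) {
    abort_validation(sprintf("Field '%s' is stratum-level: give `phenotype`.",
                             field))
  }
  if (!is.null(dist)) validate_dist(dist)
  if (!is.null(low)) check_number(low, "low")
  if (!is.null(high)) check_number(high, "high")
  if (!is.null(low) && !is.null(high) && high < low) {
    abort_validation("`high` must be >= `low`.")
  }
  structure(list(field = field, scenario = scenario, phenotype = phenotype,
                 low = low, high = high, dist = dist),
            class = "param_ref")
}

validate_dist <- function(dist) {
  if (!is.list(dist) || is.null(dist$dist)) {
    abort_validation("`dist` must be a list with a `dist` element.")
  }
  switch(dist$dist,
    beta = {
      check_number(dist$shape1, "dist$shape1", min = 1e-12)
      check_number(dist$shape2, "dist$shape2", min = 1e-12)
    },
    gamma = {
      check_number(dist$shape, "dist$shape", min = 1e-12)
      check_number(dist$rate, "dist$rate", min = 1e-12)
    },
    fixed = check_number(dist$value, "dist$value"),
    abort_validation(sprintf(
      "Unknown distribution '%s' (use beta, gamma or fixed).", dist$dist))
  )
  invisible(dist)
}

draw_dist <- function(dist) {
  switch(dist$dist,
    beta = rbeta(1, dist$shape1, dist$shape2),
    gamma = rgamma(1, shape = dist$shape, rate = dist$rate),
    fixed = dist$value)
}

param_baseline <- function(scenarios, schedule, ref) {
  if (ref$field == "hcp_cost_per_actionable") {
    return(schedule$hcp_cost_per_actionable)
  }
  if (ref$field == "arr_multiplier") return(1)
  idx <- matched_scenarios(scenarios, ref)
  s <- scenarios[[idx[1]]]
  if (ref$field %in% c("risk_tested", "risk_untested", "frequency")) {
    j <- match(ref$phenotype, s$strata$phenotype)
    return(s$strata[[ref$field]][j])
  }
  s[[ref$field]]
}

matched_scenarios <- function(scenarios, ref) {
  if (identical(ref$scenario, "ALL")) return(seq_along(scenarios))
  idx <- which(purrr::map_chr(scenarios, "drug") == ref$scenario)
  if (length(idx) == 0) {
    abort_validation(sprintf("No scenario named '%s' in the portfolio.",
                             ref$scenario))
  }
  idx
}

apply_param <- function(scenarios, schedule, ref, value) {
  check_number(value, ref$field)
  if (ref$field == "hcp_cost_per_actionable") {
    if (value < 0) abort_validation("hcp_cost_per_actionable must be >= 0.")
    schedule$hcp_cost_per_actionable <- value
    return(list(scenarios = scenarios, schedule = schedule))
  }
  for (i in matched_scenarios(scenarios, ref)) {
    s <- scenarios[[i]]
    if (ref$field == "arr_multiplier") {
      if (value < 0) abort_validation("arr_multiplier must be >= 0.")
      arr <- s$strata$risk_untested - s$strata$risk_tested
      s$strata$risk_tested <- s$strata$risk_untested - value * arr
    } else if (ref$field %in% c("risk_tested", "risk_untested", "frequency")) {
      j <- match(ref$phenotype, s$strata$phenotype)
      if (is.na(j)) {
        abort_validation(sprintf("Scenario '%s' has no stratum '%s'.",
                                 s$drug, ref$phenotype))
      }
      s$strata[[ref$field]][j] <- value
      if (ref$field == "frequency") {
        s$strata$frequency <- s$strata$frequency / sum(s$strata$frequency)
      }
    } else {
      s[[ref$field]] <- value
    }
    validate_scenario(s) # domain check: out-of-domain value -> typed error
    scenarios[[i]] <- s
  }
  list(scenarios = scenarios, schedule = schedule)
}

portfolio_summary_row <- function(scenarios, schedule) {
  t <- aggregate_portfolio(scenarios, schedule)$totals
  tibble::tibble(deaths_prevented = t$deaths_prevented,
                 cost_total = t$cost_total, cea = t$cea)
}

#' One-way (tornado-style) sensitivity analysis
#'
#' Evaluates the full portfolio on an equally spaced grid of one input,
#' holding everything else at baseline.
#'
#' @param scenarios List of [dgi_scenario()] objects.
#' @param schedule A [cost_schedule()].
#' @param param A [param_ref()] with `low` and `high` set.
#' @param n_points Grid size (>= 2).
#' @return Tibble with columns `value`, `deaths_prevented`, `cost_total`,
#'   `cea`.
#' @export
one_way <- function(scenarios, schedule, param, n_points = 11) {
  stopifnot(inherits(param, "param_ref"))
  if (is.null(param$low) || is.null(param$high)) {
    abort_validation("`param` needs `low` and `high` bounds for one_way().")
  }
  check_number(n_points, "n_points", min = 2, integerish = TRUE)
  grid <- seq(param$low, param$high, length.out = n_points)
  purrr::map_dfr(grid, function(v) {
    mod <- apply_param(scenarios, schedule, param, v)
    dplyr::bind_cols(tibble::tibble(value = v),
                     portfolio_summary_row(mod$scenarios, mod$schedule))
  })
}

#' Threshold search on a monotone input
#'
#' Finds the input value at which a pooled portfolio quantity (cost per
#' death prevented, or total incremental cost) crosses a target, by
#' bisection over `[low, high]`. The quantity must be monotone over the
#' bracket; if the target is not bracketed a
#' `pgxcea_not_bracketed_error` is raised.
#'
#' Bisection stops when the bracket is narrower than 1 (EUR, for cost
#' inputs) or than `1e-6` relative to the midpoint, whichever happens
#' first.
#'
#' @inheritParams one_way
#' @param target Target value of the chosen quantity.
#' @param quantity `"cea"` (pooled cost per death prevented, the default)
#'   or `"cost_total"`.
#' @return The input value at the crossing.
#' @export
threshold_search <- function(scenarios, schedule, param, target,
                             quantity = c("cea", "cost_total")) {
  stopifnot(inherits(param, "param_ref"))
  quantity <- match.arg(quantity)
  if (is.null(param$low) || is.null(param$high)) {
    abort_validation("`param` needs `low` and `high` bounds for threshold_search().")
  }
  f <- function(v) {
    mod <- apply_param(scenarios, schedule, param, v)
    portfolio_summary_row(mod$scenarios, mod$schedule)[[quantity]] - target
  }
  lo <- param$low; hi <- param$high
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) {
    abort_not_bracketed(sprintf(
      "Target %s = %g is not bracketed on [%g, %g] (endpoint offsets %g and %g).",
      quantity, target, lo, hi, flo, fhi))
  }
  repeat {
    mid <- (lo + hi) / 2
    if ((hi - lo) < 1 || (hi - lo) < 1e-6 * max(abs(mid), 1e-12)) {
      return(mid)
    }
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
}

#' Probabilistic sensitivity analysis
#'
#' Draws every referenced input from its distribution `n_draws` times and
#' re-evaluates the full portfolio for each draw (no approximation).
#' Probability draws that violate `risk_tested <= risk_untested` (or any
#' other structural invariant) are redrawn, up to 100 attempts per
#' parameter per iteration.
#'
#' @inheritParams one_way
#' @param params List of [param_ref()] objects, each with a `dist`.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed; identical seeds give identical results.
#' @return List with `draws` (tibble: draw index, each sampled parameter,
#'   `deaths_prevented`, `cost_total`, `cea`) and `summary` (tibble of
#'   mean and 2.5/97.5 percentiles per output, plus `prob_cost_saving`).
#' @export
psa <- function(scenarios, schedule, params, n_draws = 1000, seed = 1L) {
  if (inherits(params, "param_ref")) params <- list(params)
  purrr::walk(params, function(p) {
    stopifnot(inherits(p, "param_ref"))
    if (is.null(p$dist)) {
      abort_validation(sprintf("param_ref '%s' has no distribution for psa().",
                               p$field))
    }
  })
  check_number(n_draws, "n_draws", min = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  pnames <- vapply(seq_along(params), function(i) {
    p <- params[[i]]
    paste0(p$field, if (!is.null(p$phenotype)) paste0(".", p$phenotype),
           if (!identical(p$scenario, "ALL")) paste0(".", p$scenario),
           ".", i)
  }, character(1))
  draws <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_draws), function(it) {
      sc <- scenarios; sh <- schedule
      vals <- numeric(length(params))
      for (i in seq_along(params)) {
        p <- params[[i]]
        ok <- FALSE
        for (attempt in seq_len(100)) {
          v <- draw_dist(p$dist)
          mod <- tryCatch(apply_param(sc, sh, p, v),
                          pgxcea_validation_error = function(cnd) NULL)
          if (!is.null(mod)) {
            sc <- mod$scenarios; sh <- mod$schedule
            vals[i] <- v; ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort_validation(sprintf(
            "psa(): no legal draw for '%s' in 100 attempts at iteration %d.",
            p$field, it))
        }
      }
      out <- portfolio_summary_row(sc, sh)
      dplyr::bind_cols(tibble::tibble(draw = it),
                       tibble::as_tibble(as.list(stats::setNames(vals, pnames))),
                       out)
    })
  })
  summarise_col <- function(x) {
    c(mean = mean(x), q2.5 = unname(quantile(x, 0.025)),
      q97.5 = unname(quantile(x, 0.975)))
  }
  summary <- purrr::map_dfr(
    c("deaths_prevented", "cost_total", "cea"),
    function(col) {
      s <- summarise_col(draws[[col]])
      tibble::tibble(quantity = col, mean = s["mean"],
                     q2.5 = s["q2.5"], q97.5 = s["q97.5"])
    })
  list(draws = draws, summary = summary,
       prob_cost_saving = mean(draws$cost_total < 0), seed = as.integer(seed))
}
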