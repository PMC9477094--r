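#' Load a portfolio configuration
#'
#' Reads a YAML or JSON portfolio config (format auto-detected from the
#' file extension) into validated [dgi_scenario()] objects plus the
#' [cost_schedule()]. The config has a `schedule:` block (either
#' `hcp_cost_per_actionable` or both hourly salary rates) and a
#' `scenarios:` list; each scenario either inlines its `strata:` or names
#' a `strata_file:` CSV (path relative to the config) with header columns
#' exactly `drug,gene,phenotype,frequency,action,risk_untested,risk_tested`,
#' from which the rows matching the scenario's drug are taken.
#'
#' All scenario invariants (frequency sum within 0.005 of 1, risk ordering,
#' equal risks on non-actionable strata) are checked on load; violations
#' raise a validation error naming the file, scenario and field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A list with elements `scenarios` (list of `dgi_scenario`) and
#'   `schedule` (`cost_schedule`).
#' @examples
#' port <- load_portfolio(system.file("extdata", "dutch_portfolio.yaml",
#'                                    package = "pgxcea"))
#' length(port$scenarios)
#' @export
load_portfolio <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("Config file '%s' does not exist.", path))
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE),
    abort_io(sprintf("Unsupported config extension '.%s' (use .yaml/.yml/.json).", ext))
  )
  if (is.null(cfg$scenarios) || length(cfg$scenarios) == 0) {
    abort_validation(sprintf("'%s': config contains no scenarios.", path))
  }
  schedule <- do.call(cost_schedule, as.list(cfg$schedule %||% list(
    hcp_cost_per_actionable = 0)))
  base_dir <- dirname(path)
  strata_cache <- new.env(parent = emptyenv())
  # lapply, not purrr::map: map would wrap our typed conditions in a
  # purrr_error_indexed and callers could no longer catch them by class
  scenarios <- lapply(cfg$scenarios, function(sc) {
    drug <- sc[["drug"]] %||% "<unnamed>"
    # exact [[ indexing: `$` would partial-match `strata` to `strata_file`
    strata <- if (!is.null(sc[["strata"]])) {
      inline_strata(sc[["strata"]])
    } else if (!is.null(sc[["strata_file"]])) {
      read_strata_file(file.path(base_dir, sc[["strata_file"]]), drug,
                       cache = strata_cache)
    } else {
      abort_validation(sprintf(
        "'%s', scenario '%s': provide `strata` inline or a `strata_file`.",
        path, drug))
    }
    withCallingHandlers(
      dgi_scenario(
        drug = drug, gene = sc[["gene"]] %||% NA_character_,
        initiators = sc[["initiators"]],
        users = sc[["users"]] %||% NA_real_,
        initiator_ratio = sc[["initiator_ratio"]] %||% NA_real_,
        test_cost = sc[["test_cost"]],
        drug_cost_soc = sc[["drug_cost_soc"]],
        drug_cost_pgx = sc[["drug_cost_pgx"]],
        certainty = sc[["certainty"]],
        strata = strata
      ),
      pgxcea_validation_error = function(cnd) {
        abort_validation(sprintf("'%s', scenario '%s': %s", path, drug,
                                 conditionMessage(cnd)), parent = cnd)
      }
    )
  })
  list(scenarios = scenarios, schedule = schedule)
}

inline_strata <- function(x) {
  # a list of per-stratum records (YAML/JSON) or an already-tabular frame
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  dplyr::bind_rows(purrr::map(x, tibble::as_tibble))
}

strata_cols <- c("drug", "gene", "phenotype", "frequency", "action",
                 "risk_untested", "risk_tested")

read_strata_file <- function(path, drug, cache = NULL) {
  key <- normalizePath(path, mustWork = FALSE)
  tab <- if (!is.null(cache) && !is.null(cache[[key]])) {
    cache[[key]]
  } else {
    if (!file.exists(path)) {
      abort_io(sprintf("Strata file '%s' does not exist.", path))
    }
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(strata_cols, names(tab))
    if (length(missing)) {
      abort_validation(sprintf("'%s' lacks column(s): %s.", path,
                               paste(missing, collapse = ", ")))
    }
    if (!is.null(cache)) cache[[key]] <- tab
    tab
  }
  rows <- tab[tab$drug == drug, ]
  if (nrow(rows) == 0) {
    abort_validation(sprintf("'%s': no strata rows for drug '%s'.", path, drug))
  }
  rows[, setdiff(strata_cols, c("drug", "gene"))]
}

#' The bundled Dutch "essential"-DGI portfolio
#'
#' Loads the seven-drug Dutch portfolio shipped with the package
#' (clopidogrel-CYP2C19, capecitabine/fluorouracil-DPYD,
#' azathioprine/mercaptopurine/tioguanine-TPMT, irinotecan-UGT1A1):
#' 148,128 drug initiators per year. Printed inputs (initiator counts,
#' phenotype frequencies, absolute risk reductions, unit costs, certainty
#' scores) are stored as published; per-stratum absolute death risks are
#' reconstructed from the published deaths-with-standard-of-care anchors
#' (see [fixture_provenance()] for the field-by-field ledger).
#'
#' @return As [load_portfolio()]: list of `scenarios` and `schedule`.
#' @export
dutch_essential_portfolio <- function() {
  load_portfolio(system.file("extdata", "dutch_portfolio.yaml",
                             package = "pgxcea", mustWork = TRUE))
}

#' Provenance ledger of the bundled portfolio
#'
#' Every number in the bundled Dutch portfolio carries a provenance tag:
#' `paper` for values stored exactly as published, `derived` for values
#' reconstructed from published aggregates (per-stratum baseline risks,
#' the clopidogrel per-stratum risk reductions, the per-actionable HCP
#' interpretation cost), each with its derivation note. Published table
#' aggregates are included as `reference` rows (item `TOTAL` /
#' `*_printed` fields); they are never model inputs.
#'
#' @return A tibble with columns `item`, `field`, `value`, `provenance`,
#'   `source`.
#' @export
fixture_provenance <- function() {
  readr::read_csv(system.file("extdata", "dutch_provenance.csv",
                              package = "pgxcea", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Write portfolio results to disk
#'
#' Writes three files into `out_dir`: `table2.csv` (cost side, mirroring
#' the per-initiator cost table), `table3.csv` (effect and
#' cost-effectiveness side) and `results.json`, a machine-readable bundle
#' holding every unrounded per-scenario and total value plus run metadata
#' (input hash, seed, package version, timestamp). Re-reading the JSON
#' bundle reproduces the unrounded numbers exactly; rerunning with the
#' same inputs and seed yields a byte-identical payload apart from the
#' timestamp field.
#'
#' @param result A [aggregate_portfolio()] result.
#' @param out_dir Output directory (created if absent).
#' @param round Apply display rounding to the CSVs (deaths to 1 decimal,
#'   euros and counts to integers, percentages to 1 decimal)? The JSON
#'   bundle is always unrounded.
#' @param metadata Optional named list merged into the bundle metadata
#'   (e.g. `input_hash`, `seed`, `command`).
#' @return Invisibly, the paths of the written files.
#' @export
write_results <- function(result, out_dir, round = TRUE, metadata = list()) {
  if (!inherits(result, "portfolio_result")) {
    abort_validation("`result` must be a `portfolio_result`.")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) abort_io(sprintf("Cannot create output directory '%s'.", out_dir))
  t2 <- render_table2(result, round = round)
  t3 <- render_table3(result, round = round)
  p2 <- file.path(out_dir, "table2.csv")
  p3 <- file.path(out_dir, "table3.csv")
  pj <- file.path(out_dir, "results.json")
  readr::write_csv(t2, p2, progress = FALSE)
  readr::write_csv(t3, p3, progress = FALSE)
  meta <- utils::modifyList(
    list(package = "pgxcea",
         version = as.character(utils::packageVersion("pgxcea")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
         adoption = result$adoption, adherence = result$adherence),
    metadata)
  bundle <- list(metadata = meta,
                 per_scenario = result$per_scenario,
                 totals = result$totals)
  # 17 significant digits: doubles survive the JSON round trip bit-exactly
  jsonlite::write_json(bundle, pj, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(c(table2 = p2, table3 = p3, json = pj))
}

#' Re-read a results bundle
#'
#' Inverse of the JSON side of [write_results()]: returns the unrounded
#' per-scenario tibble, totals and metadata exactly as written.
#'
#' @param path Path to a `results.json` written by [write_results()].
#' @return List with `metadata`, `per_scenario` (tibble), `totals` (list).
#' @export
read_result_bundle <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("'%s' does not exist.", path))
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  b$per_scenario <- tibble::as_tibble(b$per_scenario)
  b$totals <- as.list(b$totals)
  b
}
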