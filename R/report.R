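# Report rendering: delimited outcome tables plus a run-metadata log.

#' Render a results report
#'
#' Writes the base-case comparison as a delimited table (one row per
#' outcome with intervention, comparator and incremental columns), plus
#' optional DSA, scenario and price-sweep tables, and a YAML run log with
#' the seed, cohort size and parameter fingerprint. Files round-trip to
#' numerically identical values via [read_report()].
#'
#' @param comparison A `cea_comparison` object.
#' @param dir Output directory (created if needed).
#' @param dsa Optional `cea_dsa` result.
#' @param scenarios Optional `cea_scenarios` result.
#' @param sweep Optional `cea_price_sweep` result.
#' @return The directory path, invisibly.
#' @export
render_report <- function(comparison, dir, dsa = NULL, scenarios = NULL,
                          sweep = NULL) {
  stopifnot(inherits(comparison, "cea_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(comparison$table, file.path(dir, "base_case.csv"))
  if (!is.null(dsa)) readr::write_csv(tibble::as_tibble(dsa), file.path(dir, "dsa.csv"))
  if (!is.null(scenarios)) {
    readr::write_csv(tibble::as_tibble(scenarios), file.path(dir, "scenarios.csv"))
  }
  if (!is.null(sweep)) {
    readr::write_csv(tibble::as_tibble(sweep), file.path(dir, "price_sweep.csv"))
  }
  yaml::write_yaml(list(
    intervention = unname(comparison$arms[["intervention"]]),
    comparator = unname(comparison$arms[["comparator"]]),
    n = comparison$n,
    seed = comparison$seed,
    fingerprint = comparison$fingerprint,
    delta_cost = comparison$delta_cost,
    delta_qaly = comparison$delta_qaly,
    icer = if (is.na(comparison$icer)) NULL else comparison$icer,
    dominance = comparison$dominance,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), file.path(dir, "run_log.yaml"))
  invisible(dir)
}

#' @rdname render_report
#' @export
read_report <- function(dir) {
  out <- list(
    base_case = readr::read_csv(file.path(dir, "base_case.csv"),
                                col_types = readr::cols(
                                  outcome = readr::col_character(),
                                  .default = readr::col_double())),
    run_log = yaml::read_yaml(file.path(dir, "run_log.yaml"))
  )
  for (extra in c("dsa", "scenarios", "price_sweep")) {
    f <- file.path(dir, paste0(extra, ".csv"))
    if (file.exists(f)) out[[extra]] <- readr::read_csv(f, show_col_types = FALSE)
  }
  out
}
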