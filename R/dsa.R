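# One-way deterministic sensitivity analysis, structural scenarios, and
# the drug price sweep. Every scenario re-runs BOTH arms with the shared
# seed so each comparison is internally paired (common random numbers),
# even when the perturbed parameter touches only one arm.

#' One-way deterministic sensitivity analysis
#'
#' For each specification, re-runs the paired-arm comparison with the
#' addressed parameter set to its low and to its high bound, and reports
#' the resulting cost/QALY deltas and ICER at each end. Results are
#' tornado-ordered by the absolute ICER range. All paths are validated
#' before any simulation starts.
#'
#' @param params A `cea_parameters` object.
#' @param specs Tibble/data frame with columns `path`, `low`, `high`, or
#'   `NULL` for the bundled default specification list (`params$dsa`).
#' @param n Patients per arm per run.
#' @param seed Integer seed (shared by every run).
#' @return A `cea_dsa` tibble: one row per spec and bound-pair with
#'   ICERs, dominance labels and the tornado `range`; the base-case ICER
#'   is attached as attribute `base_icer` (and `base_dominance`).
#' @export
run_dsa <- function(params = default_parameters(), specs = NULL,
                    n = 10000, seed = 1L) {
  if (is.null(specs)) {
    specs <- purrr::map_dfr(params$dsa, tibble::as_tibble)
  }
  specs <- tibble::as_tibble(specs)
  stopifnot(all(c("path", "low", "high") %in% names(specs)))
  valid <- parameter_paths(params)
  bad <- setdiff(specs$path, valid)
  if (length(bad) > 0) {
    abort(paste0("invalid DSA parameter path(s): ", paste(bad, collapse = ", ")))
  }
  base <- run_comparison(params, n = n, seed = seed)
  one_end <- function(path, value) {
    cmp <- run_comparison(perturb(params, path, value), n = n, seed = seed)
    list(icer = cmp$icer, label = cmp$dominance,
         delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly)
  }
  rows <- purrr::pmap_dfr(specs, function(path, low, high, ...) {
    lo <- one_end(path, low)
    hi <- one_end(path, high)
    tibble::tibble(
      path = path, low = low, high = high,
      icer_low = lo$icer, icer_high = hi$icer,
      label_low = lo$label, label_high = hi$label,
      delta_cost_low = lo$delta_cost, delta_cost_high = hi$delta_cost,
      delta_qaly_low = lo$delta_qaly, delta_qaly_high = hi$delta_qaly,
      range = abs(hi$icer - lo$icer)
    )
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$range))
  structure(rows, class = c("cea_dsa", class(rows)),
            base_icer = base$icer, base_dominance = base$dominance,
            n = n, seed = seed)
}

#' Structural scenario analyses
#'
#' Re-runs the paired comparison under the structural variants: 15-year
#' horizon, 1-month OI duration, no resistance development in either arm,
#' 0% and 6% discounting of costs and outcomes, and the worst-case /
#' no-decline settings for the terminal CD4 trajectory after last-line
#' failure.
#'
#' @inheritParams run_dsa
#' @return A `cea_scenarios` tibble: scenario, deltas, ICER/dominance,
#'   plus undiscounted deltas.
#' @export
run_structural_scenarios <- function(params = default_parameters(),
                                     n = 10000, seed = 1L) {
  scenarios <- list(
    base = identity,
    horizon_15y = function(p) perturb(p, "horizon.months", 180),
    oi_duration_1m = function(p) perturb(p, "disease.oi_duration_months", 1),
    no_resistance = function(p) {
      p <- perturb(p, "treatment.resistance_prob_on_failure.dtg", 0)
      perturb(p, "treatment.resistance_prob_on_failure.ral", 0)
    },
    discount_0 = function(p) {
      p <- perturb(p, "discount.rate_early", 0)
      perturb(p, "discount.rate_late", 0)
    },
    discount_6 = function(p) {
      p <- perturb(p, "discount.rate_early", 0.06)
      perturb(p, "discount.rate_late", 0.06)
    },
    terminal_decline_worst = function(p)
      perturb(p, "disease.terminal_scenario", "macs_decline"),
    terminal_decline_none = function(p)
      perturb(p, "disease.terminal_scenario", "no_decline")
  )
  rows <- purrr::imap_dfr(scenarios, function(f, name) {
    cmp <- run_comparison(f(params), n = n, seed = seed)
    gu <- function(k) {
      v <- cmp$table$incremental[cmp$table$outcome == k]
      if (length(v) == 1) v else NA_real_
    }
    tibble::tibble(
      scenario = name,
      delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
      delta_ly_undisc = cmp$delta_ly_undisc,
      delta_qaly_undisc = gu("qaly_undisc"),
      no_resistance_intervention_pct =
        cmp$table$intervention[cmp$table$outcome == "no_resistance_pct"],
      no_resistance_comparator_pct =
        cmp$table$comparator[cmp$table$outcome == "no_resistance_pct"],
      icer = cmp$icer, dominance = cmp$dominance
    )
  })
  structure(rows, class = c("cea_scenarios", class(rows)), n = n, seed = seed)
}

#' Intervention drug price sweep
#'
#' Scales the intervention arm's first-agent monthly acquisition cost
#' (the DTG component only, not its background therapy) by each
#' multiplier and re-runs the paired comparison. With shared seeds the
#' QALY delta is identical across multipliers, so the ICER is monotone in
#' the price.
#'
#' @inheritParams run_dsa
#' @param multipliers Positive factors on the intervention drug price.
#' @return A `cea_price_sweep` tibble: multiplier, deltas,
#'   ICER/dominance.
#' @export
price_sweep <- function(params = default_parameters(),
                        multipliers = c(0.8, 0.9, 1.0, 1.1, 1.2),
                        n = 10000, seed = 1L) {
  if (any(multipliers <= 0)) abort("multipliers must be > 0")
  base_price <- params$costs$art_monthly$dtg
  rows <- purrr::map_dfr(multipliers, function(m) {
    cmp <- run_comparison(perturb(params, "costs.art_monthly.dtg", base_price * m),
                          n = n, seed = seed)
    tibble::tibble(multiplier = m, price = base_price * m,
                   delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
                   icer = cmp$icer, dominance = cmp$dominance)
  })
  structure(rows, class = c("cea_price_sweep", class(rows)), n = n, seed = seed)
}
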