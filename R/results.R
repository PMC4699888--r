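# Arm comparison: incremental outcomes, ICER, dominance classification.

#' Construct arm results from an external summary table
#'
#' Builds a `cea_arm` object from a pre-computed outcome table (for
#' example published cohort means), so external results can be pushed
#' through the same comparison and reporting pipeline as simulated ones.
#'
#' @param summary Tibble/data frame with columns `outcome` and `value`
#'   (an `se` column is added as `NA` if absent).
#' @param arm Arm label.
#' @param n Cohort size behind the summary (`NA` allowed).
#' @param seed Seed behind the summary (`NA` allowed).
#' @param fingerprint Parameter fingerprint; arms built for the same
#'   comparison must share it.
#' @return A `cea_arm` object.
#' @export
arm_results <- function(summary, arm, n = NA_integer_, seed = NA_integer_,
                        fingerprint = "external") {
  summary <- tibble::as_tibble(summary)
  stopifnot(all(c("outcome", "value") %in% names(summary)))
  if (!"se" %in% names(summary)) summary$se <- NA_real_
  structure(list(arm = arm, n = n, seed = seed, mode = "full",
                 fingerprint = fingerprint,
                 summary = summary[, c("outcome", "value", "se")]),
            class = "cea_arm")
}

# Exhaustive ICER classification over the four delta-sign quadrants.
classify_icer <- function(delta_cost, delta_qaly, eps = 1e-12) {
  if (abs(delta_cost) < eps && abs(delta_qaly) < eps) {
    return(list(icer = NA_real_, label = "equivalent"))
  }
  if (abs(delta_qaly) < eps) {
    return(list(icer = NA_real_,
                label = if (delta_cost > 0) "dominated" else "dominant"))
  }
  ratio <- delta_cost / delta_qaly
  if (delta_qaly > 0 && delta_cost <= 0) return(list(icer = ratio, label = "dominant"))
  if (delta_qaly < 0 && delta_cost >= 0) return(list(icer = ratio, label = "dominated"))
  list(icer = ratio,
       label = if (delta_qaly > 0) "icer" else "less_costly_less_effective")
}

#' Compare two arms
#'
#' Joins two arms' outcome summaries, computes every incremental value
#' (intervention minus comparator), and the ICER from the unrounded
#' cohort means of discounted total cost and QALYs, with dominance
#' classification when the delta signs differ. Arms must have been run on
#' the same cohort: equal `n`, `seed` and parameter fingerprint.
#'
#' @param intervention,comparator `cea_arm` objects (e.g. DTG and RAL).
#' @return A `cea_comparison` object: `table` (outcome, intervention,
#'   comparator, incremental), `delta_cost`, `delta_qaly`, `icer`,
#'   `dominance` label.
#' @examples
#' p <- default_parameters()
#' a <- run_cohort("dtg", p, n = 200, seed = 1)
#' b <- run_cohort("ral", p, n = 200, seed = 1)
#' compare_arms(a, b)$icer
#' @export
compare_arms <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "cea_arm"), inherits(comparator, "cea_arm"))
  same <- identical(intervention$fingerprint, comparator$fingerprint) &&
    identical(intervention$n, comparator$n) &&
    identical(intervention$seed, comparator$seed)
  if (!same) {
    abort("arms are not comparable: n, seed and parameter fingerprint must match")
  }
  tab <- dplyr::inner_join(
    dplyr::rename(intervention$summary, intervention = "value"),
    dplyr::rename(comparator$summary, comparator = "value"),
    by = "outcome", suffix = c("_intervention", "_comparator"))
  tab <- dplyr::mutate(tab, incremental = .data$intervention - .data$comparator)
  tab <- tab[, c("outcome", "intervention", "comparator", "incremental")]
  gv <- function(k, col) {
    v <- tab[[col]][tab$outcome == k]
    if (length(v) == 1) v else NA_real_
  }
  delta_cost <- gv("total_cost", "incremental")
  delta_qaly <- gv("qaly", "incremental")
  cls <- classify_icer(delta_cost, delta_qaly)
  structure(list(
    table = tab,
    arms = c(intervention = intervention$arm, comparator = comparator$arm),
    n = intervention$n, seed = intervention$seed,
    fingerprint = intervention$fingerprint,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    delta_ly_undisc = gv("ly_undisc", "incremental"),
    delta_ly_disc = gv("ly_disc", "incremental"),
    icer = cls$icer, dominance = cls$label
  ), class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("<cea_comparison> ", toupper(x$arms[["intervention"]]), " vs ",
      toupper(x$arms[["comparator"]]), "  (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  incremental cost:  %12s EUR\n",
              format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  incremental QALYs: %12s\n", format(round(x$delta_qaly, 3))))
  if (x$dominance == "icer") {
    cat(sprintf("  ICER:              %12s EUR/QALY\n",
                format(round(x$icer), big.mark = ",")))
  } else {
    cat("  classification:    ", x$dominance, "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.cea_comparison <- function(x, ...) {
  tidyr::pivot_longer(x$table, cols = c("intervention", "comparator", "incremental"),
                      names_to = "column", values_to = "value")
}

#' @export
glance.cea_comparison <- function(x, ...) {
  gv <- function(k, col) {
    v <- x$table[[col]][x$table$outcome == k]
    if (length(v) == 1) v else NA_real_
  }
  tibble::tibble(
    intervention = x$arms[["intervention"]],
    comparator = x$arms[["comparator"]],
    n = x$n,
    delta_cost = x$delta_cost,
    delta_qaly = x$delta_qaly,
    delta_ly_undisc = x$delta_ly_undisc,
    icer = x$icer,
    dominance = x$dominance,
    art_share_intervention_pct = gv("art_cost_share_pct", "intervention"),
    art_share_comparator_pct = gv("art_cost_share_pct", "comparator")
  )
}

#' Run both arms and compare
#'
#' Convenience wrapper: simulates the intervention and comparator arms on
#' the shared cohort and draw stream, then calls [compare_arms()].
#'
#' @inheritParams run_cohort
#' @param arms Character vector of length 2: intervention then comparator.
#' @return A `cea_comparison` object.
#' @export
run_comparison <- function(params = default_parameters(),
                           n = params$simulation$n_patients,
                           seed = params$simulation$seed,
                           arms = c("dtg", "ral")) {
  stopifnot(length(arms) == 2)
  a <- run_cohort(arms[1], params, n = n, seed = seed)
  b <- run_cohort(arms[2], params, n = n, seed = seed)
  compare_arms(a, b)
}
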