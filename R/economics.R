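# Per-month cost and QALY accrual rules. The engine applies the same
# rules vectorized across patients; these scalar forms are the documented
# single-state API and the reference for the ledger oracle tests.

#' Monthly cost accrual for one patient-month
#'
#' Components, all in EUR for one model month: the line's monthly ART
#' acquisition cost; routine HIV care by CD4 stratum and OI history; the
#' one-off OI episode cost in the onset month; the line-change cost in
#' switch months; the flat monthly laboratory-test cost; and, in the
#' death month only, the death cost keyed by OI-history recency (none /
#' resolved more than 30 days ago / active or resolved within 30 days,
#' implemented on the monthly grid as "active, or resolved this month or
#' the month before").
#'
#' @param state List with `cd4`, `oi_history` (any prior resolved OI),
#'   `active_oi` (`NULL` or list), `months_since_oi` (months since last
#'   resolution, `Inf` if none).
#' @param line A one-row line tibble (see [initial_line()]).
#' @param events List of flags: `oi_onset` (`NULL` or OI type string),
#'   `switch` (logical), `death` (logical).
#' @param params A `cea_parameters` object.
#' @return Named numeric vector: `art`, `routine`, `oi`, `switch`,
#'   `tests`, `death`, `total`.
#' @examples
#' p <- default_parameters()
#' st <- list(cd4 = 600, oi_history = FALSE, active_oi = NULL,
#'            months_since_oi = Inf)
#' monthly_cost(st, initial_line("dtg", p), list(), p)
#' @export
monthly_cost <- function(state, line, events = list(), params = default_parameters()) {
  costs <- params$costs
  s6 <- cd4_stratum6(state$cd4)
  if (s6 < 1L || s6 > 6L || is.na(s6)) abort("CD4 stratum could not be resolved")
  hist_key <- if (isTRUE(state$oi_history)) "history" else "no_history"
  routine <- costs$routine_monthly[[CD4_STRATA6[s6]]][[hist_key]]
  oi <- if (!is.null(events$oi_onset)) costs$oi_event[[events$oi_onset]] else 0
  sw <- if (isTRUE(events$switch)) costs$switch_cost else 0
  death <- 0
  if (isTRUE(events$death)) {
    recent <- !is.null(state$active_oi) ||
      (!is.null(state$months_since_oi) && state$months_since_oi <= 1)
    ever <- isTRUE(state$oi_history) || !is.null(state$active_oi)
    death <- if (!ever) {
      costs$death$no_history
    } else if (recent) {
      costs$death$history_le30d
    } else {
      costs$death$history_gt30d
    }
  }
  out <- c(art = line$art_cost, routine = routine, oi = oi, switch = sw,
           tests = costs$tests_monthly, death = death)
  c(out, total = sum(out))
}

#' Monthly quality-adjusted survival accrual
#'
#' One alive month contributes 1/12 life years and `u`/12 QALYs, where
#' `u` is the CD4-stratum utility, replaced during active-OI months by
#' the smaller of the OI-type utility and the CD4 utility (an OI never
#' improves a severely immunosuppressed state).
#'
#' @param state List with `cd4` and `active_oi` (`NULL` or a list with
#'   `type`).
#' @param params A `cea_parameters` object.
#' @return Named numeric vector: `life_years`, `qalys`.
#' @examples
#' p <- default_parameters()
#' monthly_qaly(list(cd4 = 300, active_oi = NULL), p)
#' @export
monthly_qaly <- function(state, params = default_parameters()) {
  u <- params$utilities$by_cd4[[CD4_STRATA4[cd4_stratum4(state$cd4)]]]
  if (!is.null(state$active_oi)) {
    u <- min(u, params$utilities$by_oi[[state$active_oi$type]])
  }
  c(life_years = 1 / 12, qalys = u / 12)
}

#' Discount a monthly accrual
#'
#' Multiplies every component of an accrual by the tiered discount factor
#' at the given month index (see [discount_factor()]); undiscounted
#' accruals are kept separately by the caller.
#'
#' @param increment Named numeric vector (costs or QALY accrual).
#' @param month_index Month index (>= 0; month 0 = model entry).
#' @param settings Discount settings (e.g. `params$discount`).
#' @return The increment scaled by the discount factor.
#' @export
apply_discounting <- function(increment, month_index, settings) {
  increment * discount_factor(month_index, settings)
}
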