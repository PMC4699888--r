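# Disease dynamics: CD4 trajectory, opportunistic infections, mortality.

#' Monthly CD4 gain while suppressed
#'
#' Front-loaded first-year schedule: two thirds of the line's annual
#' (week-48) gain accrue in months 1-2, the remaining third uniformly over
#' months 3-11 (so months 1-11 sum exactly to the annual gain); months
#' 12-23 accrue the second-year annual gain in twelfths, and months >= 24
#' the later-years gain in twelfths. No gain accrues while unsuppressed.
#' On subsequent lines the cumulative gain is capped at the total gain the
#' patient actually obtained on the first line; the resulting CD4 count is
#' capped at `params$disease$cd4_cap` by the engine.
#'
#' @param line A one-row line tibble (see [initial_line()]).
#' @param month_on_line Month on the line (1-based, >= 1).
#' @param suppressed Logical: virologically suppressed this month.
#' @param params A `cea_parameters` object.
#' @param first_line_total_gain Total CD4 gain realized on the first line
#'   (cells/uL); `Inf` while still on the first line.
#' @param line_gain_cum Cumulative gain already realized on the current
#'   line (cells/uL).
#' @return Gain in cells/uL for this month (>= 0).
#' @examples
#' l <- initial_line("dtg", default_parameters())
#' monthly_cd4_gain(l, 1, TRUE, default_parameters())  # (2/3 * 190) / 2
#' @export
monthly_cd4_gain <- function(line, month_on_line, suppressed, params,
                             first_line_total_gain = Inf, line_gain_cum = 0) {
  stopifnot(month_on_line >= 1)
  if (!isTRUE(suppressed)) return(0)
  raw <- cd4_gain_schedule(month_on_line, line$cd4_gain_y1, line$cd4_gain_y2,
                           line$cd4_gain_later)
  min(raw, max(0, first_line_total_gain - line_gain_cum))
}

# Vectorized raw schedule (no caps); m is month-on-line (1-based).
cd4_gain_schedule <- function(m, g1, g2, g3) {
  (m <= 2) * (2 / 3 * g1) / 2 +
    (m >= 3 & m <= 11) * (1 / 3 * g1) / 9 +
    (m >= 12 & m <= 23) * g2 / 12 +
    (m >= 24) * g3 / 12
}

#' Terminal CD4 decline after last-line failure
#'
#' Monthly CD4 change (<= 0, cells/uL) applied to patients flagged as
#' failing the final treatment line. The base case uses the configured
#' base decline; `macs_decline` the steeper worst-case table;
#' `no_decline` returns 0 (optimistic scenario). The engine floors CD4 at
#' zero.
#'
#' @param scenario One of `"base"`, `"macs_decline"`, `"no_decline"`.
#' @param params A `cea_parameters` object.
#' @return Monthly CD4 change (<= 0).
#' @export
terminal_cd4_decline <- function(scenario = c("base", "macs_decline", "no_decline"),
                                 params = default_parameters()) {
  scenario <- match.arg(scenario)
  switch(scenario,
         base = -params$disease$terminal_decline_monthly,
         macs_decline = -params$disease$terminal_decline_macs_monthly,
         no_decline = 0)
}

# Matrix of monthly OI hazards: rows = six CD4 strata (ascending), cols =
# the five OI types in their fixed allocation order.
oi_hazard_matrix <- function(params) {
  h <- params$disease$oi_hazard_monthly
  m <- do.call(rbind, lapply(CD4_STRATA6, function(s) unlist(h[[s]])[OI_TYPES]))
  dimnames(m) <- list(CD4_STRATA6, OI_TYPES)
  m
}

#' Monthly opportunistic-infection onset draw
#'
#' Per-type monthly Bernoulli hazards from the (CD4 stratum, OI history)
#' hazard table; at most one OI can start per month and only while no OI
#' is active. Types are tried in the fixed order bacterial, fungal,
#' protozoal, viral, other, with exclusive allocation (the first firing
#' type wins), which keeps runs reproducible.
#'
#' @param state List with at least `cd4`, `oi_history` and `active_oi`
#'   (`NULL` or a list with `type`, `months_remaining`).
#' @param params A `cea_parameters` object.
#' @param rng_draws Numeric vector of five uniform draws (one per type).
#' @return `NULL`, or a list `(type, months_remaining)` for a new episode
#'   lasting `params$disease$oi_duration_months`.
#' @export
sample_oi <- function(state, params, rng_draws) {
  stopifnot(length(rng_draws) == 5L)
  if (!is.null(state$active_oi)) return(NULL)
  haz <- oi_hazard_matrix(params)[cd4_stratum6(state$cd4), ]
  if (isTRUE(state$oi_history)) haz <- pmin(1, haz * params$disease$oi_history_multiplier)
  fired <- which(rng_draws < haz)
  if (length(fired) == 0L) return(NULL)
  list(type = OI_TYPES[min(fired)],
       months_remaining = params$disease$oi_duration_months)
}

# Background annual qx lookup (vectorized): age years, sex integer 1=M 2=F.
background_qx <- function(age_years, sex_i, params) {
  lt <- params$mortality$life_table
  band <- findInterval(age_years, lt$age_start)
  band[band < 1L] <- 1L
  ifelse(sex_i == 1L, lt$qx_male[band], lt$qx_female[band])
}

annual_to_monthly <- function(q) 1 - (1 - q)^(1 / 12)

#' Monthly death draw
#'
#' Background all-cause mortality (abridged life table by age band and
#' sex, converted to a monthly probability) competes with
#' HIV-attributable excess mortality by CD4 stratum; during active-OI
#' months the HIV component is multiplied by the acute-OI factor. The two
#' causes are drawn independently with the HIV cause tested first. A death
#' during an active OI or within the month after its resolution is
#' attributed to HIV/AIDS with OI.
#'
#' @param state List with `age_years`, `sex` (`"M"`/`"F"`), `cd4`,
#'   `active_oi` (`NULL` or list), and optionally `months_since_oi` (months
#'   since last OI resolution; `Inf` if none).
#' @param params A `cea_parameters` object.
#' @param rng_draws Two uniform draws: HIV cause, background cause.
#' @return `NULL` if the patient survives the month, else one of
#'   `"hiv_aids"`, `"hiv_aids_oi"`, `"other"`.
#' @export
sample_death <- function(state, params, rng_draws) {
  stopifnot(length(rng_draws) == 2L)
  s6 <- cd4_stratum6(state$cd4)
  qh <- annual_to_monthly(params$mortality$hiv_excess_annual[[CD4_STRATA6[s6]]])
  if (!is.null(state$active_oi)) {
    qh <- min(1, qh * params$mortality$acute_oi_multiplier)
  }
  qb <- annual_to_monthly(background_qx(state$age_years,
                                        ifelse(state$sex == "M", 1L, 2L), params))
  recent_oi <- !is.null(state$active_oi) ||
    (!is.null(state$months_since_oi) && state$months_since_oi <= 1)
  if (rng_draws[1] < qh) {
    if (recent_oi) "hiv_aids_oi" else "hiv_aids"
  } else if (rng_draws[2] < qb) {
    "other"
  } else {
    NULL
  }
}
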