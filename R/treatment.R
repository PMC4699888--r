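# Treatment-line state machine: per-arm ordered line sequences (branching
# once on post-line-1 INI-resistance status) and per-line virologic
# efficacy.

# Flatten one arm's algorithm into a line table the engine can index by a
# single integer `lid`. Rows 1..k are the no-resistance path; the
# INI-resistance path shares line 1 and continues in the trailing rows.
arm_line_table <- function(arm, params) {
  arm <- match.arg(tolower(arm), c("dtg", "ral"))
  tr <- params$treatment
  build_path <- function(keys, status) {
    purrr::imap_dfr(keys, function(key, i) {
      d <- tr$definitions[[key]]
      e <- params$efficacy[[d$efficacy]]
      tibble::tibble(
        key = key,
        label = d$label,
        path = status,
        line_index = i,
        suppression_rate_y1 = e$suppression_rate_y1,
        suppression_ci_low = e$suppression_ci[1],
        suppression_ci_high = e$suppression_ci[2],
        late_failure_m12_23 = e$late_failure_m12_23,
        late_failure_m24plus = e$late_failure_m24plus,
        cd4_gain_y1 = e$cd4_gain_y1,
        cd4_gain_y2 = e$cd4_gain_y2,
        cd4_gain_later = e$cd4_gain_later,
        art_cost = sum(unlist(params$costs$art_monthly[d$art_components])),
        is_salvage = isTRUE(d$salvage)
      )
    })
  }
  nr <- build_path(tr$lines[[arm]]$no_resistance, "no_resistance")
  rs <- build_path(tr$lines[[arm]]$ini_resistance, "ini_resistance")
  stopifnot(identical(nr$key[1], rs$key[1]))  # shared first line
  tab <- dplyr::bind_rows(nr, rs[-1, ])
  n_nr <- nrow(nr)
  n_rs <- nrow(rs) - 1L  # trailing resistance-path rows (line 1 shared)
  tab$lid <- seq_len(nrow(tab))
  # successor lid within each path; NA marks the terminal (absorbing) line
  nxt <- rep(NA_integer_, nrow(tab))
  if (n_nr > 1L) nxt[1:(n_nr - 1L)] <- 2:n_nr
  if (n_rs > 1L) nxt[(n_nr + 1L):(n_nr + n_rs - 1L)] <- (n_nr + 2L):(n_nr + n_rs)
  tab$next_lid <- nxt
  # successor when INI resistance is acquired at first-line failure
  nxr <- rep(NA_integer_, nrow(tab))
  if (n_rs >= 1L) nxr[1] <- n_nr + 1L
  tab$next_lid_resistant <- nxr
  tab$arm <- arm
  tab
}

#' First treatment line of an arm
#'
#' @param arm `"dtg"` or `"ral"` (case-insensitive).
#' @param params A `cea_parameters` object.
#' @return A one-row tibble describing the line: label, week-48
#'   suppression rate, late-failure rates, CD4 gain schedule parameters,
#'   monthly ART cost and salvage flag.
#' @examples
#' initial_line("dtg", default_parameters())$suppression_rate_y1
#' @export
initial_line <- function(arm, params = default_parameters()) {
  tab <- arm_line_table(arm, params)
  tab[1, ]
}

#' Successor treatment line
#'
#' Applies the arm's line algorithm: after the first line patients without
#' INI resistance continue on the no-resistance path, patients with
#' acquired resistance switch to the resistance path; later transitions
#' only advance within the already-selected path. Beyond the final salvage
#' line there is no successor: `NULL` is returned (the patient stays on
#' the final regimen, flagged as failing the last line).
#'
#' @param arm `"dtg"` or `"ral"`.
#' @param current_line_index Line index within the patient's path (1-based).
#' @param ini_resistant Logical: INI resistance acquired at first-line
#'   virologic failure.
#' @param params A `cea_parameters` object.
#' @return A one-row line tibble, or `NULL` (terminal marker).
#' @export
next_line <- function(arm, current_line_index, ini_resistant,
                      params = default_parameters()) {
  tab <- arm_line_table(arm, params)
  path <- if (isTRUE(ini_resistant)) "ini_resistance" else "no_resistance"
  cur <- tab[tab$path == path & tab$line_index == current_line_index, ]
  if (nrow(cur) == 0 && current_line_index == 1L) {
    cur <- tab[1, ]  # line 1 is shared between paths
  }
  if (nrow(cur) == 0) abort("current line does not exist on this path")
  nxt <- tab[tab$path == path & tab$line_index == current_line_index + 1L, ]
  if (nrow(nxt) == 0) NULL else nxt
}

#' Week-48 virologic outcome on a line
#'
#' Bernoulli response with the line's annual suppression rate: responders
#' are suppressed throughout the line's first year and thereafter until
#' late failure; non-responders trigger a first-year failure transition at
#' month 12 on the line.
#'
#' @param line A one-row line tibble.
#' @param rng_draw Uniform(0,1) draw.
#' @return List with `suppressed_at_48w` flag.
#' @export
year1_outcome <- function(line, rng_draw) {
  list(suppressed_at_48w = rng_draw < line$suppression_rate_y1)
}

#' Monthly late-failure (viral rebound) probability
#'
#' Constant within the months 12-23 window on the line and from month 24
#' onward; not defined before month 12 (the first year is governed by the
#' week-48 response).
#'
#' @param line A one-row line tibble.
#' @param months_since_line_start Months on the line (>= 12).
#' @return Monthly rebound probability.
#' @examples
#' l <- initial_line("dtg", default_parameters())
#' monthly_late_failure_prob(l, 15)
#' @export
monthly_late_failure_prob <- function(line, months_since_line_start) {
  if (any(months_since_line_start < 12)) {
    abort("late failure is defined from month 12 on the line (year 1 is governed by the week-48 response)")
  }
  ifelse(months_since_line_start <= 23,
         line$late_failure_m12_23, line$late_failure_m24plus)
}

#' Resistance acquisition at first-line virologic failure
#'
#' Bernoulli draw against the arm-specific per-failure probability;
#' resistance can only be acquired at a virologic failure of the first
#' model line and persists for life.
#'
#' @param arm `"dtg"` or `"ral"`.
#' @param line_index Line index of the failing line (must be 1).
#' @param params A `cea_parameters` object.
#' @param rng_draw Uniform(0,1) draw.
#' @return Logical flag.
#' @export
resistance_on_failure <- function(arm, line_index, params, rng_draw) {
  arm <- match.arg(tolower(arm), c("dtg", "ral"))
  if (line_index != 1L) {
    abort("resistance can only be acquired at first-line virologic failure")
  }
  rng_draw < params$treatment$resistance_prob_on_failure[[arm]]
}

#' Adverse-event discontinuation draw
#'
#' Monthly Bernoulli with the constant AE discontinuation probability.
#' A positive draw triggers the same successor logic as treatment failure
#' but without any resistance acquisition.
#'
#' @param line A one-row line tibble (present for signature symmetry; the
#'   rate is line-independent in the base case).
#' @param params A `cea_parameters` object.
#' @param rng_draw Uniform(0,1) draw.
#' @return Logical flag.
#' @export
ae_discontinuation <- function(line, params, rng_draw) {
  rng_draw < params$treatment$ae_discontinuation_monthly
}
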