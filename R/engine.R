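# Cohort engine: per-patient monthly event loop, vectorized across
# patients. Randomness is consumed as one fixed-size matrix of uniforms
# per model month (11 columns per patient-month, generated whether or not
# a patient is still alive), so the draw stream is identical across arms
# and across parameter perturbations: patient i sees the same numbers
# wherever the compared settings coincide (common random numbers).
#
# Draw columns: 1 HIV-cause death, 2 background death, 3-7 OI onset
# (bacterial, fungal, protozoal, viral, other), 8 late failure, 9 AE
# discontinuation, 10 week-48 response of a newly started line, 11
# resistance acquisition at first-line failure. The first line's week-48
# response uses the cohort's reserved `u_line1` draw.

N_DRAW_COLS <- 11L

#' Simulate one arm over a cohort
#'
#' Runs the monthly event loop for every patient until death, the age
#' cap, or the configured horizon: death draws, OI onset/resolution,
#' virologic evaluation (week-48 response at month 12 on a line, monthly
#' late failure afterwards), AE discontinuation, line transition, CD4
#' update, and cost/QALY accrual with tiered discounting — in that fixed
#' order. Identical `(arm, params, n, seed)` give identical results, and
#' the baseline cohort and draw stream are shared across arms.
#'
#' @param arm `"dtg"` or `"ral"`.
#' @param params A `cea_parameters` object.
#' @param n Cohort size; defaults to `params$simulation$n_patients`.
#' @param seed Integer seed; defaults to `params$simulation$seed`.
#' @param cohort Optional pre-built cohort tibble (see [sample_cohort()]);
#'   when supplied, `n` is taken from it.
#' @param mode `"full"` (lifetime) or `"line1"` (simulate only until each
#'   patient exits the first treatment line; used for resistance
#'   calibration).
#' @param keep_patients Keep the per-patient outcome tibble in the result.
#' @param keep_log Record a per-patient-month event log (small `n` only).
#' @param draw_override Optional `function(month, n)` returning the
#'   `n x 11` uniform matrix for that month, replacing the RNG (scripted
#'   trajectories for oracle tests).
#' @return A `cea_arm` object: `summary` (tibble of outcome, value, se),
#'   `n`, `seed`, `arm`, `fingerprint`, and optionally `patients`/`log`.
#' @examples
#' res <- run_cohort("dtg", default_parameters(), n = 200, seed = 1)
#' tidy(res)
#' @export
run_cohort <- function(arm, params = default_parameters(),
                       n = params$simulation$n_patients,
                       seed = params$simulation$seed,
                       cohort = NULL,
                       mode = c("full", "line1"),
                       keep_patients = FALSE, keep_log = FALSE,
                       draw_override = NULL) {
  arm <- match.arg(tolower(arm), c("dtg", "ral"))
  mode <- match.arg(mode)
  if (is.null(cohort)) {
    if (n < 1) abort("n must be >= 1")
    cohort <- sample_cohort(n, params, seed)
  }
  n <- nrow(cohort)
  # Engine draws use a stream offset from the cohort-sampling stream so
  # baseline attributes and event draws are not correlated.
  engine_seed <- as.integer((as.numeric(seed) + 999983) %% .Machine$integer.max)
  set.seed(engine_seed)

  po <- simulate_cohort_impl(cohort, arm, params, mode = mode,
                             keep_log = keep_log,
                             draw_override = draw_override)
  out <- list(
    arm = arm,
    n = n,
    seed = seed,
    mode = mode,
    fingerprint = parameter_fingerprint(params),
    summary = summarize_arm(po, mode)
  )
  if (keep_patients) out$patients <- po$patients
  if (keep_log) out$log <- po$log
  structure(out, class = "cea_arm")
}

#' Simulate a single patient
#'
#' Wraps the cohort engine around a one-row cohort; `run_cohort()` with
#' `n = 1` and the same seed gives the same trajectory.
#'
#' @param patient One-row cohort tibble (see [sample_cohort()]).
#' @inheritParams run_cohort
#' @return One-row per-patient outcome tibble (the event log as attribute
#'   `"log"` when `keep_log = TRUE`).
#' @export
simulate_patient <- function(patient, arm, params = default_parameters(),
                             seed = 1L, keep_log = FALSE,
                             draw_override = NULL) {
  res <- run_cohort(arm, params, cohort = patient, seed = seed,
                    keep_patients = TRUE, keep_log = keep_log,
                    draw_override = draw_override)
  out <- res$patients
  if (keep_log) attr(out, "log") <- res$log
  out
}

# The vectorized event loop. Returns list(patients = tibble, log = tibble?).
simulate_cohort_impl <- function(cohort, arm, params, mode = "full",
                                 keep_log = FALSE, draw_override = NULL) {
  n <- nrow(cohort)
  line_tab <- arm_line_table(arm, params)
  supp_v <- line_tab$suppression_rate_y1
  late1_v <- line_tab$late_failure_m12_23
  late2_v <- line_tab$late_failure_m24plus
  g1_v <- line_tab$cd4_gain_y1
  g2_v <- line_tab$cd4_gain_y2
  g3_v <- line_tab$cd4_gain_later
  art_v <- line_tab$art_cost
  next_v <- line_tab$next_lid
  next_res1 <- line_tab$next_lid_resistant[1]
  grp_v <- pmin(line_tab$line_index, 3L)  # 1 first, 2 second, 3 salvage
  label_v <- line_tab$label

  costs <- params$costs
  routine_mat <- do.call(rbind, lapply(CD4_STRATA6, function(s) {
    c(costs$routine_monthly[[s]]$no_history, costs$routine_monthly[[s]]$history)
  }))
  oi_cost_v <- unlist(costs$oi_event[OI_TYPES])
  u_cd4_v <- unlist(params$utilities$by_cd4[CD4_STRATA4])
  u_oi_v <- unlist(params$utilities$by_oi[OI_TYPES])
  haz6 <- oi_hazard_matrix(params)
  hist_mult <- params$disease$oi_history_multiplier
  qh6 <- annual_to_monthly(unlist(params$mortality$hiv_excess_annual[CD4_STRATA6]))
  oi_mult <- params$mortality$acute_oi_multiplier
  lt <- params$mortality$life_table
  qxm_m <- annual_to_monthly(lt$qx_male)
  qxf_m <- annual_to_monthly(lt$qx_female)
  ae_p <- params$treatment$ae_discontinuation_monthly
  p_res <- params$treatment$resistance_prob_on_failure[[arm]]
  dur <- params$disease$oi_duration_months
  cap <- params$disease$cd4_cap
  td <- terminal_cd4_decline(params$disease$terminal_scenario, params)
  sw_cost <- costs$switch_cost
  tests_c <- costs$tests_monthly
  d_no <- costs$death$no_history
  d_gt <- costs$death$history_gt30d
  d_le <- costs$death$history_le30d
  disc <- params$discount
  apply_c <- disc$apply_to %in% c("costs", "both")
  apply_q <- disc$apply_to %in% c("qalys", "both")
  light <- mode == "line1"

  # mutable state
  alive <- rep(TRUE, n)
  age_m <- round(cohort$age_years * 12)
  sex_i <- ifelse(cohort$sex == "M", 1L, 2L)
  cd4 <- cohort$cd4
  lid <- rep(1L, n)
  mol <- rep(0L, n)
  resp <- cohort$u_line1 < supp_v[1]
  failing <- rep(FALSE, n)
  resistant <- rep(FALSE, n)
  line1_gain <- rep(Inf, n)
  line_gain_cum <- rep(0, n)
  oi_rem <- rep(0L, n)
  oi_type <- rep(0L, n)
  oi_hist <- cohort$oi_history
  msr <- rep(Inf, n)  # months since last OI resolution
  exited1 <- rep(FALSE, n)
  aids <- cohort$oi_history | cd4 < 200
  done <- rep(FALSE, n)  # line1 mode: exited or dead

  # accumulators
  zero <- numeric(n)
  c_art_u <- zero; c_art_d <- zero
  c_art1_u <- zero; c_art1_d <- zero
  c_rout_u <- zero; c_rout_d <- zero
  c_oi_u <- zero; c_oi_d <- zero
  c_death_u <- zero; c_death_d <- zero
  c_tests_u <- zero; c_tests_d <- zero
  c_sw_u <- zero; c_sw_d <- zero
  ly_u <- zero; ly_d <- zero
  qaly_u <- zero; qaly_d <- zero
  m_line <- matrix(0L, n, 3L)
  m_supp <- zero; m_fail <- zero
  aids_free_m <- zero
  oi_counts <- matrix(0L, n, 5L, dimnames = list(NULL, OI_TYPES))
  cause <- rep(0L, n)  # 0 none/censored, 1 hiv, 2 hiv+oi, 3 other
  death_month <- rep(NA_integer_, n)
  cd4_max_seen <- cd4

  hor <- floor(pmax(0, params$horizon$max_age_years * 12 - age_m))
  if (!is.na(params$horizon$months)) hor <- pmin(hor, params$horizon$months)
  t_max <- max(hor)
  fac_all <- discount_factor(seq_len(max(t_max, 1)) - 1, disc)

  log_rows <- if (keep_log) vector("list", t_max) else NULL

  for (t in seq_len(t_max)) {
    act <- alive & t <= hor & !done
    if (!any(act)) break
    U <- if (is.null(draw_override)) {
      matrix(runif(n * N_DRAW_COLS), n, N_DRAW_COLS)
    } else {
      draw_override(t, n)
    }
    idx <- which(act)
    cd4_0 <- cd4[idx]
    lid_0 <- lid[idx]
    resp_0 <- resp[idx]
    fail_0 <- failing[idx]
    hist_0 <- oi_hist[idx]
    rem_0 <- oi_rem[idx]
    type_0 <- oi_type[idx]
    msr_0 <- msr[idx]
    aids_0 <- aids[idx]
    s6 <- cd4_stratum6(cd4_0)
    s4 <- cd4_stratum4(cd4_0)
    active_0 <- rem_0 > 0L

    # (1) death draws: HIV cause tested first, background second
    qh <- qh6[s6]
    qh[active_0] <- pmin(1, qh[active_0] * oi_mult)
    band <- findInterval(age_m[idx] / 12, lt$age_start)
    band[band < 1L] <- 1L
    qb <- ifelse(sex_i[idx] == 1L, qxm_m[band], qxf_m[band])
    die_h <- U[idx, 1L] < qh
    die_b <- !die_h & U[idx, 2L] < qb
    die <- die_h | die_b
    live <- !die

    # (2) OI resolution/onset: at most one active episode; first firing
    # type in fixed order wins
    H <- haz6[s6, , drop = FALSE]
    H[hist_0, ] <- pmin(1, H[hist_0, , drop = FALSE] * hist_mult)
    fire <- U[idx, 3:7, drop = FALSE] < H & !active_0
    ot <- integer(length(idx))
    for (j in 5:1) ot[fire[, j]] <- j
    onset <- ot > 0L
    rem_now <- rem_0
    rem_now[onset] <- dur
    type_now <- type_0
    type_now[onset] <- ot[onset]
    active_now <- rem_now > 0L
    if (any(onset)) {
      oi_counts[cbind(idx[onset], ot[onset])] <-
        oi_counts[cbind(idx[onset], ot[onset])] + 1L
    }

    # (3) virologic evaluation
    mol_t <- mol[idx] + 1L
    y1fail <- live & !resp_0 & mol_t == 12L & !fail_0
    lr <- ifelse(mol_t <= 23L, late1_v[lid_0], late2_v[lid_0])
    latefail <- live & resp_0 & mol_t >= 12L & !fail_0 & U[idx, 8L] < lr
    virofail <- y1fail | latefail

    # (4) AE discontinuation (never on the terminal line, never with a
    # same-month virologic failure)
    has_next <- !is.na(next_v[lid_0])
    ae <- live & !virofail & !fail_0 & has_next & U[idx, 9L] < ae_p

    # (5) line transition
    trans <- virofail | ae
    resgain <- virofail & lid_0 == 1L & U[idx, 11L] < p_res
    new_lid <- next_v[lid_0]
    new_lid[resgain] <- next_res1
    to_term <- trans & is.na(new_lid)
    moving <- trans & !is.na(new_lid)

    # (6) CD4 update (start-of-month CD4 drives this month's risks/costs;
    # the update takes effect from next month)
    gain_i <- live & resp_0 & !trans & !fail_0
    raw <- cd4_gain_schedule(mol_t, g1_v[lid_0], g2_v[lid_0], g3_v[lid_0])
    room <- pmax(0, line1_gain[idx] - line_gain_cum[idx])
    g <- ifelse(gain_i, ifelse(lid_0 == 1L, raw, pmin(raw, room)), 0)
    g[fail_0 & live] <- td
    cd4_new <- pmin(pmax(cd4_0 + g, 0), cap)

    # (7) accrual: every patient alive at month start accrues the full
    # month (no half-cycle correction)
    if (!light) {
      fac <- fac_all[t]
      fC <- if (apply_c) fac else 1
      fQ <- if (apply_q) fac else 1
      art <- art_v[lid_0]
      rout <- routine_mat[cbind(s6, hist_0 + 1L)]
      oi_c <- ifelse(onset, oi_cost_v[pmax(ot, 1L)], 0)
      sw_c <- ifelse(moving, sw_cost, 0)
      recent <- active_now | msr_0 == 0
      ever <- hist_0 | active_now
      dth_c <- ifelse(die,
                      ifelse(!ever, d_no, ifelse(recent, d_le, d_gt)), 0)
      u <- u_cd4_v[s4]
      if (any(active_now)) {
        u[active_now] <- pmin(u[active_now], u_oi_v[type_now[active_now]])
      }
      c_art_u[idx] <- c_art_u[idx] + art
      c_art_d[idx] <- c_art_d[idx] + art * fC
      is1 <- lid_0 == 1L
      c_art1_u[idx[is1]] <- c_art1_u[idx[is1]] + art[is1]
      c_art1_d[idx[is1]] <- c_art1_d[idx[is1]] + art[is1] * fC
      c_rout_u[idx] <- c_rout_u[idx] + rout
      c_rout_d[idx] <- c_rout_d[idx] + rout * fC
      c_oi_u[idx] <- c_oi_u[idx] + oi_c
      c_oi_d[idx] <- c_oi_d[idx] + oi_c * fC
      c_death_u[idx] <- c_death_u[idx] + dth_c
      c_death_d[idx] <- c_death_d[idx] + dth_c * fC
      c_tests_u[idx] <- c_tests_u[idx] + tests_c
      c_tests_d[idx] <- c_tests_d[idx] + tests_c * fC
      c_sw_u[idx] <- c_sw_u[idx] + sw_c
      c_sw_d[idx] <- c_sw_d[idx] + sw_c * fC
      ly_u[idx] <- ly_u[idx] + 1 / 12
      ly_d[idx] <- ly_d[idx] + fQ / 12
      qaly_u[idx] <- qaly_u[idx] + u / 12
      qaly_d[idx] <- qaly_d[idx] + u * fQ / 12
      grp <- grp_v[lid_0]
      for (gg in 1:3) {
        sel <- grp == gg
        m_line[idx[sel], gg] <- m_line[idx[sel], gg] + 1L
      }
      on_supp <- resp_0 & !fail_0 & !virofail
      m_supp[idx] <- m_supp[idx] + on_supp
      m_fail[idx] <- m_fail[idx] + !on_supp
      aids_free_m[idx] <- aids_free_m[idx] + !aids_0
    }

    if (keep_log) {
      log_rows[[t]] <- tibble::tibble(
        month = t, id = cohort$id[idx],
        cd4_start = cd4_0, line_label = label_v[lid_0],
        month_on_line = mol_t,
        suppressed = resp_0 & !fail_0 & !virofail,
        failing_last = fail_0,
        oi_active = active_now,
        oi_type = ifelse(active_now, OI_TYPES[pmax(type_now, 1L)], NA_character_),
        oi_onset = onset, virologic_failure = virofail,
        ae_switch = ae, switched = moving, died = die
      )
    }

    # (8) commit state
    aids_new <- aids_0 | onset
    aids_new[live] <- aids_new[live] | cd4_new[live] < 200
    aids[idx] <- aids_new
    cd4[idx[live]] <- cd4_new[live]
    cd4_max_seen[idx[live]] <- pmax(cd4_max_seen[idx[live]], cd4_new[live])
    line_gain_cum[idx[gain_i]] <- line_gain_cum[idx[gain_i]] + g[gain_i]

    leave1 <- moving & lid_0 == 1L
    line1_gain[idx[leave1]] <- line_gain_cum[idx[leave1]]
    exited1[idx[leave1]] <- TRUE
    resistant[idx[resgain]] <- TRUE
    if (any(moving)) {
      im <- idx[moving]
      lid[im] <- new_lid[moving]
      mol[im] <- 0L
      resp[im] <- U[im, 10L] < supp_v[new_lid[moving]]
      line_gain_cum[im] <- 0
    }
    if (any(to_term)) {
      it <- idx[to_term]
      failing[it] <- TRUE
      resp[it] <- FALSE
      mol[it] <- mol[it] + 1L
    }
    stay <- live & !trans
    mol[idx[stay]] <- mol[idx[stay]] + 1L

    # OI clock for survivors
    il <- idx[live]
    dec <- rem_now[live] > 0L
    rem_next <- rem_now[live] - as.integer(dec)
    resolved <- dec & rem_next == 0L
    oi_rem[il] <- rem_next
    oi_type[il] <- ifelse(rem_next > 0L, type_now[live], 0L)
    oi_hist[il[resolved]] <- TRUE
    msr_next <- msr[il]
    msr_next[!dec] <- msr_next[!dec] + 1
    msr_next[resolved] <- 0
    msr[il] <- msr_next

    # deaths
    if (any(die)) {
      id_d <- idx[die]
      alive[id_d] <- FALSE
      death_month[id_d] <- t
      oi_linked <- (active_now | msr_0 == 0)[die]
      cause[id_d] <- ifelse(die_h[die], ifelse(oi_linked, 2L, 1L), 3L)
    }
    age_m[idx] <- age_m[idx] + 1L
    if (light) done <- done | exited1 | !alive
  }

  patients <- tibble::tibble(
    id = cohort$id,
    ly_undisc = ly_u, ly_disc = ly_d,
    qaly_undisc = qaly_u, qaly_disc = qaly_d,
    cost_art_undisc = c_art_u, cost_art_disc = c_art_d,
    cost_art_first_undisc = c_art1_u, cost_art_first_disc = c_art1_d,
    cost_routine_undisc = c_rout_u, cost_routine_disc = c_rout_d,
    cost_oi_undisc = c_oi_u, cost_oi_disc = c_oi_d,
    cost_death_undisc = c_death_u, cost_death_disc = c_death_d,
    cost_tests_undisc = c_tests_u, cost_tests_disc = c_tests_d,
    cost_switch_undisc = c_sw_u, cost_switch_disc = c_sw_d,
    cost_total_undisc = c_art_u + c_rout_u + c_oi_u + c_death_u + c_tests_u + c_sw_u,
    cost_total_disc = c_art_d + c_rout_d + c_oi_d + c_death_d + c_tests_d + c_sw_d,
    months_first_line = m_line[, 1L],
    months_second_line = m_line[, 2L],
    months_salvage = m_line[, 3L],
    months_suppressed = m_supp, months_failing = m_fail,
    oi_bacterial = unname(oi_counts[, 1L]), oi_fungal = unname(oi_counts[, 2L]),
    oi_protozoal = unname(oi_counts[, 3L]), oi_viral = unname(oi_counts[, 4L]),
    oi_other = unname(oi_counts[, 5L]),
    reached_aids = aids, aids_free_years = aids_free_m / 12,
    exited_line1 = exited1, ini_resistant = resistant,
    cd4_final = cd4, cd4_max = cd4_max_seen,
    death_cause = c("censored", "hiv_aids", "hiv_aids_oi", "other")[cause + 1L],
    death_month = death_month
  )
  list(patients = patients,
       log = if (keep_log) dplyr::bind_rows(log_rows) else NULL)
}

# Cohort-level summary of per-patient outcomes.
summarize_arm <- function(po, mode = "full") {
  p <- po$patients
  n <- nrow(p)
  mse <- function(x) sd(x) / sqrt(n)
  exited <- p$exited_line1
  no_res_pct <- if (any(exited)) 100 * (1 - mean(p$ini_resistant[exited])) else NA_real_
  if (mode == "line1") {
    return(tibble::tibble(
      outcome = c("no_resistance_pct", "exited_line1_n"),
      value = c(no_res_pct, sum(exited)),
      se = c(if (any(exited)) 100 * sd(!p$ini_resistant[exited]) / sqrt(sum(exited)) else NA_real_,
             NA_real_)
    ))
  }
  dead <- p$death_cause != "censored"
  pct_cause <- function(kk) {
    if (!any(dead)) return(NA_real_)
    100 * mean(p$death_cause[dead] %in% kk)
  }
  vals <- c(
    total_cost = mean(p$cost_total_disc),
    cost_art = mean(p$cost_art_disc),
    cost_art_first_line = mean(p$cost_art_first_disc),
    cost_art_subsequent = mean(p$cost_art_disc - p$cost_art_first_disc),
    cost_care = mean(p$cost_routine_disc),
    cost_death = mean(p$cost_death_disc),
    cost_tests = mean(p$cost_tests_disc),
    cost_oi = mean(p$cost_oi_disc),
    cost_switch = mean(p$cost_switch_disc),
    total_cost_undisc = mean(p$cost_total_undisc),
    ly_undisc = mean(p$ly_undisc),
    ly_disc = mean(p$ly_disc),
    qaly = mean(p$qaly_disc),
    qaly_undisc = mean(p$qaly_undisc),
    months_first_line = mean(p$months_first_line),
    months_second_line = mean(p$months_second_line),
    months_salvage = mean(p$months_salvage),
    months_on_art = mean(p$months_first_line + p$months_second_line + p$months_salvage),
    months_suppressed = mean(p$months_suppressed),
    months_failing = mean(p$months_failing),
    oi_bacterial_pct = 100 * mean(p$oi_bacterial > 0),
    oi_fungal_pct = 100 * mean(p$oi_fungal > 0),
    oi_protozoal_pct = 100 * mean(p$oi_protozoal > 0),
    oi_viral_pct = 100 * mean(p$oi_viral > 0),
    oi_other_pct = 100 * mean(p$oi_other > 0),
    aids_pct = 100 * mean(p$reached_aids),
    aids_free_years = mean(p$aids_free_years),
    no_resistance_pct = no_res_pct,
    mortality_hiv_pct = pct_cause(c("hiv_aids", "hiv_aids_oi")),
    mortality_hiv_oi_pct = pct_cause("hiv_aids_oi"),
    mortality_other_pct = pct_cause("other"),
    art_cost_share_pct = 100 * sum(p$cost_art_disc) / sum(p$cost_total_disc)
  )
  ses <- setNames(rep(NA_real_, length(vals)), names(vals))
  ses["total_cost"] <- mse(p$cost_total_disc)
  ses["ly_undisc"] <- mse(p$ly_undisc)
  ses["ly_disc"] <- mse(p$ly_disc)
  ses["qaly"] <- mse(p$qaly_disc)
  ses["qaly_undisc"] <- mse(p$qaly_undisc)
  tibble::tibble(outcome = names(vals), value = unname(vals), se = unname(ses))
}

#' Calibrate the resistance-acquisition probability
#'
#' Solves, by bisection on the per-failure acquisition probability, for
#' the value whose simulated proportion of patients exiting the first
#' treatment line alive without INI resistance matches a target. Each
#' evaluation re-simulates first-line exits with the same seed, so the
#' objective is deterministic and monotone in the probability.
#'
#' @param targets Named numeric vector of target no-resistance proportions
#'   in (0, 1], e.g. `c(dtg = 0.8872, ral = 0.5584)` (any subset of arms).
#' @param params A `cea_parameters` object.
#' @param n Patients per evaluation (reduced-n re-simulation).
#' @param seed Integer seed.
#' @param tol Tolerance on the proportion (0.005 = 0.5 percentage points).
#' @param max_iter Bisection iteration cap.
#' @return Named list per arm: `prob` (calibrated probability),
#'   `achieved` (simulated proportion), `iterations`.
#' @export
calibrate_resistance <- function(targets, params = default_parameters(),
                                 n = 20000, seed = 1L, tol = 0.005,
                                 max_iter = 30L) {
  stopifnot(!is.null(names(targets)), all(names(targets) %in% c("dtg", "ral")))
  if (any(targets <= 0 | targets > 1)) {
    abort("targets must be proportions in (0, 1]")
  }
  out <- list()
  for (arm in names(targets)) {
    target <- unname(targets[[arm]])
    path <- paste0("treatment.resistance_prob_on_failure.", arm)
    eval_p <- function(p) {
      r <- run_cohort(arm, perturb(params, path, p), n = n, seed = seed,
                      mode = "line1")
      r$summary$value[r$summary$outcome == "no_resistance_pct"] / 100
    }
    if (target >= 1) {
      out[[arm]] <- list(prob = 0, achieved = eval_p(0), iterations = 1L)
      next
    }
    floor_prop <- eval_p(1)
    if (target < floor_prop - tol) {
      abort(paste0(
        "target no-resistance proportion ", format(target), " for arm ", arm,
        " is unattainable: the attainable range at these parameters is [",
        format(round(floor_prop, 4)), ", 1]"))
    }
    lo <- 0; hi <- 1
    prob <- NA_real_; achieved <- NA_real_; it <- 0L
    repeat {
      it <- it + 1L
      mid <- (lo + hi) / 2
      prop <- eval_p(mid)
      if (abs(prop - target) <= tol || it >= max_iter || (hi - lo) < 1e-5) {
        prob <- mid; achieved <- prop
        break
      }
      if (prop > target) lo <- mid else hi <- mid
    }
    if (abs(achieved - target) > tol) {
      warn(paste0("calibration for arm ", arm, " stopped at |error| = ",
                  format(abs(achieved - target)), " > tol"))
    }
    out[[arm]] <- list(prob = prob, achieved = achieved, iterations = it)
  }
  out
}

#' @export
print.cea_arm <- function(x, ...) {
  cat("<cea_arm> arm=", toupper(x$arm), " n=", x$n, " seed=", x$seed,
      if (x$mode == "line1") " (first-line only)", "\n", sep = "")
  s <- x$summary
  key <- intersect(c("total_cost", "ly_undisc", "qaly", "no_resistance_pct"),
                   s$outcome)
  for (k in key) {
    cat(sprintf("  %-18s %s\n", k,
                format(round(s$value[s$outcome == k], 3), big.mark = ",")))
  }
  invisible(x)
}

#' @export
tidy.cea_arm <- function(x, ...) x$summary

#' @export
glance.cea_arm <- function(x, ...) {
  s <- x$summary
  g <- function(k) if (k %in% s$outcome) s$value[s$outcome == k] else NA_real_
  tibble::tibble(arm = x$arm, n = x$n, seed = x$seed,
                 total_cost = g("total_cost"), ly_undisc = g("ly_undisc"),
                 qaly = g("qaly"),
                 no_resistance_pct = g("no_resistance_pct"),
                 fingerprint = x$fingerprint)
}
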