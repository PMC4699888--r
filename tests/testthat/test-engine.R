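test_that("an event-free run has closed-form outcomes", {
  # guaranteed response, no failures/AEs/OIs/deaths, fixed CD4 stratum,
  # 120-month horizon: every month costs ART + routine + tests and yields
  # 0.900/12 QALYs
  qp <- quiet_params(120)
  qp2 <- perturb(qp, "cohort.cd4_min", 600)
  qp2 <- perturb(qp2, "cohort.cd4_max", 600)
  qp2 <- perturb(qp2, "cohort.cd4_meanlog", log(600))
  qp2 <- perturb(qp2, "cohort.oi_history_proportion", 0)
  r <- run_cohort("dtg", qp2, n = 20, seed = 1, keep_patients = TRUE)
  pt <- r$patients
  monthly <- (612 + 986) + 224 + qp2$costs$tests_monthly
  expect_equal(pt$ly_undisc, rep(10, 20))
  expect_equal(pt$cost_total_undisc, rep(120 * monthly, 20))
  expect_equal(pt$qaly_undisc, rep(9, 20), tolerance = 1e-12)
  expect_equal(pt$months_first_line, rep(120L, 20))  # absorbing success
  fac <- sum(discount_factor(0:119, qp2$discount))
  expect_equal(pt$cost_total_disc, rep(monthly * fac, 20), tolerance = 1e-9)
  expect_equal(pt$qaly_disc, rep(0.9 * fac / 12, 20), tolerance = 1e-9)
  expect_true(all(pt$death_cause == "censored"))
})

test_that("runs are deterministic and n = 1 matches the single-patient wrapper", {
  p <- base_params()
  a <- run_cohort("dtg", p, n = 300, seed = 5, keep_patients = TRUE)
  b <- run_cohort("dtg", p, n = 300, seed = 5, keep_patients = TRUE)
  expect_identical(a$summary, b$summary)
  expect_identical(a$patients, b$patients)
  co1 <- sample_cohort(1, p, seed = 9)
  direct <- simulate_patient(co1, "dtg", p, seed = 9)
  via_cohort <- run_cohort("dtg", p, cohort = co1, seed = 9,
                           keep_patients = TRUE)$patients
  expect_identical(direct, via_cohort)
})

test_that("identical arm parameterizations give exactly zero increments", {
  # make the comparator arm pharmacologically identical to the
  # intervention arm; with the shared cohort and draw stream every
  # incremental outcome must cancel exactly
  p <- base_params()
  e <- p$efficacy$dtg_obt1
  p_eq <- load_parameters(list(
    efficacy = list(ral_obt1 = e),
    treatment = list(resistance_prob_on_failure = list(
      dtg = p$treatment$resistance_prob_on_failure$dtg,
      ral = p$treatment$resistance_prob_on_failure$dtg)),
    costs = list(art_monthly = list(obt2_1 = 612 + 1698))))
  cmp <- run_comparison(p_eq, n = 2000, seed = 13)
  expect_equal(cmp$delta_cost, 0)
  expect_equal(cmp$delta_qaly, 0)
  expect_true(all(cmp$table$incremental == 0))
  expect_equal(cmp$dominance, "equivalent")
})

test_that("Monte Carlo standard errors shrink like one over root n", {
  p <- base_params()
  se_of <- function(n) {
    r <- run_cohort("dtg", p, n = n, seed = 17)
    r$summary$se[r$summary$outcome == "qaly"]
  }
  ratio <- se_of(1000) / se_of(4000)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("a scripted 36-month trajectory reproduces a hand-computed ledger", {
  # forced path: first-line responder, one fungal OI at month 20, death
  # from a background cause at month 36; every accrual is recomputed here
  # with explicit arithmetic, independent of the engine
  lt <- base_params()$mortality$life_table
  nb <- length(lt$age_start)
  zero6 <- setNames(as.list(rep(0, 6)),
                    c("gt500", "s351_500", "s201_350", "s101_200",
                      "s51_100", "s0_50"))
  oi_fungal_only <- lapply(zero6, function(x)
    list(bacterial = 0, fungal = 0.01, protozoal = 0, viral = 0, other = 0))
  p <- load_parameters(list(
    mortality = list(hiv_excess_annual = zero6,
                     life_table = list(age_start = lt$age_start,
                                       qx_male = rep(0.5, nb),
                                       qx_female = rep(0.5, nb))),
    disease = list(oi_hazard_monthly = oi_fungal_only)))
  draws <- scripted_draws(base = 0.5, overrides = list(
    `20` = c(`4` = 0.001),  # fungal onset
    `36` = c(`2` = 0)       # background death
  ))
  pt <- simulate_patient(one_patient(cd4 = 300, u_line1 = 0), "dtg", p,
                         seed = 1, draw_override = draws)

  # --- independent ledger ---------------------------------------------
  g <- numeric(35)
  g[1:2] <- (2 / 3 * 190) / 2
  g[3:11] <- (1 / 3 * 190) / 9
  g[12:23] <- 14 / 12
  g[24:35] <- 19 / 12
  cd4 <- 300 + c(0, cumsum(g))            # start-of-month CD4, months 1..36
  oi_months <- 20:22
  u <- ifelse(seq_len(36) %in% oi_months, 0.652, 0.900)
  routine <- vapply(seq_len(36), function(m) {
    hist <- m >= 23                        # OI resolved at the end of month 22
    x <- cd4[m]
    row <- if (x > 500) c(224, 275) else if (x > 350) c(296, 398) else
      if (x > 200) c(377, 775) else stop("unexpected stratum")
    row[hist + 1]
  }, numeric(1))
  art <- rep(612 + 986, 36)
  tests <- rep(30, 36)
  oi_cost <- ifelse(seq_len(36) == 20, 9119, 0)
  death_cost <- ifelse(seq_len(36) == 36, 14351, 0)  # history > 30 days
  fac <- 1.04^(-(0:35) / 12)
  total_u <- sum(art + routine + tests + oi_cost + death_cost)
  total_d <- sum((art + routine + tests + oi_cost + death_cost) * fac)

  expect_equal(pt$ly_undisc, 3)
  expect_equal(pt$ly_disc, sum(fac) / 12, tolerance = 1e-12)
  expect_equal(pt$qaly_undisc, sum(u) / 12, tolerance = 1e-12)
  expect_equal(pt$qaly_disc, sum(u * fac) / 12, tolerance = 1e-12)
  expect_equal(pt$cost_art_undisc, sum(art))
  expect_equal(pt$cost_routine_undisc, sum(routine))
  expect_equal(pt$cost_oi_undisc, 9119)
  expect_equal(pt$cost_death_undisc, 14351)
  expect_equal(pt$cost_tests_undisc, sum(tests))
  expect_equal(pt$cost_switch_undisc, 0)
  expect_equal(pt$cost_total_undisc, total_u)
  expect_equal(pt$cost_total_disc, total_d, tolerance = 1e-10)
  expect_equal(pt$months_first_line, 36L)
  expect_equal(pt$months_suppressed, 36)
  expect_equal(pt$oi_fungal, 1L)
  expect_equal(pt$death_cause, "other")
  expect_equal(pt$death_month, 36L)
  expect_false(pt$ini_resistant)
  expect_false(pt$exited_line1)
  expect_true(pt$reached_aids)
  expect_equal(pt$aids_free_years, 20 / 12)  # AIDS flagged at the OI onset
})

test_that("undiscounted QALYs replay exactly from the event log", {
  p <- base_params()
  r <- run_cohort("ral", p, n = 120, seed = 23, keep_patients = TRUE,
                  keep_log = TRUE)
  u_cd4 <- function(x) ifelse(x > 200, 0.900,
                              ifelse(x > 100, 0.870,
                                     ifelse(x > 50, 0.860, 0.830)))
  u_oi <- c(bacterial = 0.561, fungal = 0.652, protozoal = 0.652,
            viral = 0.561, other = 0.561)
  lg <- r$log
  u <- u_cd4(lg$cd4_start)
  oi <- lg$oi_active
  u[oi] <- pmin(u[oi], u_oi[lg$oi_type[oi]])
  replay <- tapply(u / 12, lg$id, sum)
  got <- setNames(r$patients$qaly_undisc, r$patients$id)
  expect_equal(unname(got[names(replay)]), as.numeric(replay),
               tolerance = 1e-12)
  # life years replay as alive-month counts
  expect_equal(unname(setNames(r$patients$ly_undisc,
                               r$patients$id)[names(replay)]),
               as.numeric(tapply(rep(1 / 12, nrow(lg)), lg$id, sum)),
               tolerance = 1e-12)
})

test_that("treatment-history flags are monotone over every patient path", {
  p <- base_params()
  r <- run_cohort("dtg", p, n = 400, seed = 29, keep_patients = TRUE,
                  keep_log = TRUE)
  ord <- c("DTG + OBT1" = 1, "DTG + OBT2.0" = 2, "OBT2.2" = 2,
           "Salvage 1" = 3, "Salvage 2" = 4)
  lg <- r$log[order(r$log$id, r$log$month), ]
  for (d in split(lg, lg$id)) {
    expect_true(all(diff(ord[d$line_label]) >= 0))    # lines never regress
    expect_true(all(diff(cumsum(d$oi_onset)) >= 0))
    expect_lte(length(unique(d$line_label)), 4)       # at most 4 lines
  }
  # resistance implies first-line exit, and the resistance path skips
  # Salvage 1 (at most 3 distinct lines)
  pt <- r$patients
  expect_true(all(!pt$ini_resistant | pt$exited_line1))
  res_ids <- pt$id[pt$ini_resistant]
  for (d in split(lg[lg$id %in% res_ids, ], lg$id[lg$id %in% res_ids])) {
    expect_lte(length(unique(d$line_label)), 3)
    expect_false("Salvage 1" %in% d$line_label)
  }
})

test_that("resistance calibration recovers known and closed-form targets", {
  # death- and AE-free dynamics: every patient eventually fails the first
  # line, so the no-resistance proportion is 1 - p exactly
  lt <- base_params()$mortality$life_table
  nb <- length(lt$age_start)
  zero6 <- setNames(as.list(rep(0, 6)),
                    c("gt500", "s351_500", "s201_350", "s101_200",
                      "s51_100", "s0_50"))
  p <- load_parameters(list(
    treatment = list(ae_discontinuation_monthly = 0,
                     resistance_prob_on_failure = list(dtg = 0.3, ral = 0.47)),
    mortality = list(hiv_excess_annual = zero6,
                     life_table = list(age_start = lt$age_start,
                                       qx_male = rep(0, nb),
                                       qx_female = rep(0, nb)))))
  r <- run_cohort("dtg", p, n = 4000, seed = 37, mode = "line1")
  prop <- r$summary$value[r$summary$outcome == "no_resistance_pct"] / 100
  expect_lt(abs(prop - 0.7), 0.025)  # 1 - p with binomial noise at n = 4000
  # calibration inverts the map
  cal <- calibrate_resistance(c(dtg = 0.7), p, n = 4000, seed = 37)
  expect_lt(abs(cal$dtg$achieved - 0.7), 0.005)
  expect_lt(abs(cal$dtg$prob - 0.3), 0.05)
  # degenerate target: full no-resistance needs probability zero
  cal1 <- calibrate_resistance(c(dtg = 1), p, n = 500, seed = 37)
  expect_equal(cal1$dtg$prob, 0)
  expect_equal(cal1$dtg$achieved, 1)
  # unattainable target reports the attainable range: with frequent AE
  # switches (which never confer resistance) the no-resistance floor is
  # well above zero even at probability one
  p_ae <- perturb(p, "treatment.ae_discontinuation_monthly", 0.05)
  expect_error(calibrate_resistance(c(dtg = 0.05), p_ae, n = 500, seed = 37),
               "unattainable")
})
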