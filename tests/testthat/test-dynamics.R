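test_that("the front-loaded CD4 schedule conserves the annual gain", {
  p <- base_params()
  l <- initial_line("dtg", p)
  gains <- vapply(1:11, function(m) monthly_cd4_gain(l, m, TRUE, p), numeric(1))
  expect_equal(gains[1], (2 / 3 * 190) / 2)
  expect_equal(gains[1], gains[2])
  expect_equal(gains[3], (1 / 3 * 190) / 9)
  expect_equal(sum(gains), 190)  # months 1-11 sum to the week-48 gain
  expect_equal(monthly_cd4_gain(l, 12, TRUE, p), 14 / 12)
  expect_equal(monthly_cd4_gain(l, 24, TRUE, p), 19 / 12)
  expect_equal(monthly_cd4_gain(l, 5, FALSE, p), 0)  # unsuppressed: no gain
  # same conservation for every configured line
  for (key in names(p$efficacy)) {
    e <- p$efficacy[[key]]
    ll <- l
    ll$cd4_gain_y1 <- e$cd4_gain_y1
    s <- sum(vapply(1:11, function(m) monthly_cd4_gain(ll, m, TRUE, p), numeric(1)))
    expect_equal(s, e$cd4_gain_y1)
  }
})

test_that("subsequent-line gains are capped at the realized first-line gain", {
  p <- base_params()
  l2 <- next_line("dtg", 1, FALSE, p)
  # patient gained only 50 cells on line 1; cumulative line-2 gain stops there
  expect_equal(monthly_cd4_gain(l2, 1, TRUE, p,
                                first_line_total_gain = 50, line_gain_cum = 0),
               min((2 / 3 * 176) / 2, 50))
  expect_equal(monthly_cd4_gain(l2, 2, TRUE, p,
                                first_line_total_gain = 50, line_gain_cum = 50), 0)
  expect_equal(monthly_cd4_gain(l2, 2, TRUE, p,
                                first_line_total_gain = 50, line_gain_cum = 48), 2)
})

test_that("terminal decline scenarios are ordered and floored", {
  p <- base_params()
  expect_equal(terminal_cd4_decline("no_decline", p), 0)
  expect_lt(terminal_cd4_decline("base", p), 0)
  expect_lt(terminal_cd4_decline("macs_decline", p),
            terminal_cd4_decline("base", p))
  expect_error(terminal_cd4_decline("steeper", p))
})

test_that("OI onset requires a firing hazard and an empty OI slot", {
  p <- base_params()
  st <- list(cd4 = 30, oi_history = FALSE, active_oi = NULL)
  # all hazards zero -> never
  none <- sample_oi(st, quiet_params(), runif(5))
  expect_null(none)
  # forced: draw 0 under positive hazard, first type in order wins
  ev <- sample_oi(st, p, c(0, 0, 1, 1, 1))
  expect_equal(ev$type, "bacterial")
  expect_equal(ev$months_remaining, 3)
  ev2 <- sample_oi(st, p, c(1, 0, 0, 1, 1))
  expect_equal(ev2$type, "fungal")
  # an active OI blocks concurrent onset
  busy <- list(cd4 = 30, oi_history = FALSE,
               active_oi = list(type = "viral", months_remaining = 2))
  expect_null(sample_oi(busy, p, rep(0, 5)))
})

test_that("OI history doubles hazards and raises lifetime OI counts", {
  p <- base_params()
  st_h <- list(cd4 = 150, oi_history = TRUE, active_oi = NULL)
  haz <- p$disease$oi_hazard_monthly$s101_200$bacterial
  # draw between 1x and 2x hazard fires only with history
  mid <- 1.5 * haz
  expect_null(sample_oi(list(cd4 = 150, oi_history = FALSE, active_oi = NULL),
                        p, c(mid, 1, 1, 1, 1)))
  expect_equal(sample_oi(st_h, p, c(mid, 1, 1, 1, 1))$type, "bacterial")
  # paired seeded cohorts: all-history vs no-history baseline
  p_h <- params_with(cohort = list(oi_history_proportion = 1))
  p_n <- params_with(cohort = list(oi_history_proportion = 0))
  tot <- function(pp) {
    r <- run_cohort("dtg", pp, n = 20000, seed = 31, keep_patients = TRUE)
    with(r$patients, sum(oi_bacterial + oi_fungal + oi_protozoal +
                           oi_viral + oi_other))
  }
  expect_gt(tot(p_h), tot(p_n))
})

test_that("death draws respect degenerate and monotone configurations", {
  qp <- quiet_params()
  st <- list(age_years = 50, sex = "M", cd4 = 40, active_oi = NULL,
             months_since_oi = Inf)
  expect_null(sample_death(st, qp, c(0.5, 0.5)))  # immortal configuration
  # forced HIV death, cause split by OI recency
  p1 <- params_with(mortality = list(hiv_excess_annual = list(
    gt500 = 1, s351_500 = 1, s201_350 = 1, s101_200 = 1, s51_100 = 1, s0_50 = 1)))
  expect_equal(sample_death(st, p1, c(0, 0.99)), "hiv_aids")
  st_oi <- modifyList(st, list(active_oi = list(type = "viral")))
  expect_equal(sample_death(st_oi, p1, c(0, 0.99)), "hiv_aids_oi")
  st_rec <- modifyList(st, list(months_since_oi = 1))
  expect_equal(sample_death(st_rec, p1, c(0, 0.99)), "hiv_aids_oi")
  # zero HIV excess forces an all-"other" cause split
  res <- run_cohort("dtg", params_with(mortality = list(hiv_excess_annual =
    list(gt500 = 0, s351_500 = 0, s201_350 = 0, s101_200 = 0,
         s51_100 = 0, s0_50 = 0))), n = 2000, seed = 41, keep_patients = TRUE)
  dead <- res$patients$death_cause[res$patients$death_cause != "censored"]
  expect_true(length(dead) > 0 && all(dead == "other"))
  # raising low-CD4 excess mortality lowers life expectancy (paired seeds)
  le <- vapply(c(0.15, 0.60), function(q) {
    pp <- params_with(mortality = list(hiv_excess_annual = list(s0_50 = q)))
    r <- run_cohort("dtg", pp, n = 5000, seed = 51)
    r$summary$value[r$summary$outcome == "ly_undisc"]
  }, numeric(1))
  expect_gt(le[1], le[2])
})

test_that("CD4 stays within [0, cap] and OI episodes last their configured span", {
  p <- params_with(cohort = list(cd4_meanlog = 6.6, cd4_max = 990))
  r <- run_cohort("dtg", p, n = 800, seed = 61, keep_patients = TRUE,
                  keep_log = TRUE)
  expect_true(all(r$patients$cd4_max <= p$disease$cd4_cap))
  expect_true(all(r$patients$cd4_final >= 0))
  expect_true(all(r$log$cd4_start >= 0 & r$log$cd4_start <= p$disease$cd4_cap))
  # every completed OI episode spans exactly oi_duration_months active
  # months (episodes cut short by death/censoring are excluded)
  oi_log <- r$log[r$log$oi_active, c("id", "month")]
  expect_gt(nrow(oi_log), 0)
  dur <- p$disease$oi_duration_months
  last_obs <- tapply(r$log$month, r$log$id, max)
  for (id in unique(as.character(oi_log$id))) {
    m <- sort(oi_log$month[oi_log$id == as.integer(id)])
    ep <- cumsum(c(1, diff(m) > 1))
    lens <- tapply(m, ep, length)
    ends <- tapply(m, ep, max)
    complete <- ends < last_obs[[id]]
    if (any(complete)) {
      expect_true(all(lens[complete] %% dur == 0))
    }
  }
})
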