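# Shared fixtures, built in code.

base_params <- function() default_parameters()

# Override helper: nested list merged onto the base case.
params_with <- function(...) load_parameters(list(...))

# A deterministic, event-free parameterization: guaranteed first-line
# response, no late failure, no AE switches, no OIs, no deaths. Useful
# for closed-form accrual checks.
quiet_params <- function(horizon_months = 120) {
  eff_quiet <- list(suppression_rate_y1 = 1.0, suppression_ci = c(1.0, 1.0),
                    late_failure_m12_23 = 0, late_failure_m24plus = 0)
  zero6 <- function(v) setNames(as.list(rep(v, 6)),
                                c("gt500", "s351_500", "s201_350",
                                  "s101_200", "s51_100", "s0_50"))
  zero_oi <- function() lapply(zero6(0), function(x)
    list(bacterial = 0, fungal = 0, protozoal = 0, viral = 0, other = 0))
  lt <- base_params()$mortality$life_table
  load_parameters(list(
    horizon = list(months = horizon_months),
    efficacy = list(dtg_obt1 = eff_quiet, ral_obt1 = eff_quiet,
                    second_line_no_res = eff_quiet,
                    second_line_ini_res = eff_quiet,
                    salvage1 = eff_quiet, salvage2 = eff_quiet),
    treatment = list(ae_discontinuation_monthly = 0),
    disease = list(oi_hazard_monthly = zero_oi()),
    mortality = list(
      hiv_excess_annual = zero6(0),
      life_table = list(age_start = lt$age_start,
                        qx_male = rep(0, length(lt$age_start)),
                        qx_female = rep(0, length(lt$age_start))))
  ))
}

# One-patient cohort with fixed attributes.
one_patient <- function(age = 40, sex = "M", cd4 = 300, oi_history = FALSE,
                        u_line1 = 0) {
  tibble::tibble(id = 1L, age_years = age, sex = sex, cd4 = cd4,
                 suppressed = FALSE, oi_history = oi_history,
                 u_line1 = u_line1)
}

# Draw override builder: a constant 11-column row, with per-month
# column overrides given as list(`20` = c(`4` = 0), ...).
scripted_draws <- function(base = 0.5, overrides = list()) {
  function(t, n) {
    row <- rep(base, 11L)
    ov <- overrides[[as.character(t)]]
    if (!is.null(ov)) row[as.integer(names(ov))] <- ov
    matrix(rep(row, each = n), n, 11L)
  }
}
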