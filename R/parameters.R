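#' Load model parameters
#'
#' Reads the bundled base-case configuration and, optionally, merges a
#' user override file (or list) onto it. Overrides are matched key-by-key
#' against the base configuration; unknown keys are rejected so typos
#' cannot silently fall back to defaults. The merged bundle is validated
#' (probabilities in \[0,1\], non-negative costs, utility monotonicity,
#' algorithm consistency, ...) before being returned.
#'
#' @param config Path to a YAML override file, a named list of overrides,
#'   or `NULL` for the base case.
#' @return A `cea_parameters` object (validated nested list).
#' @examples
#' p <- default_parameters()
#' p$costs$art_monthly$dtg
#' @export
load_parameters <- function(config = NULL) {
  base <- yaml::read_yaml(system.file("extdata", "base_case.yaml",
                                      package = "hivcea"))
  if (!is.null(config)) {
    over <- if (is.character(config)) yaml::read_yaml(config) else config
    if (!is.list(over)) {
      abort("configuration override must be a file path or a named list")
    }
    base <- merge_config(base, over, path = character())
  }
  params <- structure(base, class = "cea_parameters")
  validate_parameters(params)
  params
}

#' @rdname load_parameters
#' @export
default_parameters <- function() load_parameters(NULL)

# Recursive override merge; unknown keys error with their full path.
merge_config <- function(base, over, path) {
  if (is.null(names(over)) || any(names(over) == "")) {
    # unnamed list (e.g. dsa spec list): replace wholesale
    return(over)
  }
  for (key in names(over)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base)) {
      abort(paste0("unknown configuration key: ", here))
    }
    if (is.list(base[[key]]) && is.list(over[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], over[[key]], c(path, key))
    } else {
      base[[key]] <- over[[key]]
    }
  }
  base
}

#' Enumerate addressable parameter paths
#'
#' Returns every leaf entry of a parameter bundle as a dot-separated path
#' (e.g. `"efficacy.dtg_obt1.suppression_rate_y1"`). These are the paths
#' accepted by [perturb()] and by sensitivity-analysis specifications.
#'
#' @param params A `cea_parameters` object.
#' @return Character vector of dot-separated leaf paths.
#' @export
parameter_paths <- function(params) {
  walk_paths <- function(x, prefix) {
    if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
      return(paste(prefix, collapse = "."))
    }
    unlist(lapply(names(x), function(k) walk_paths(x[[k]], c(prefix, k))),
           use.names = FALSE)
  }
  setdiff(walk_paths(unclass(params), character()), "")
}

#' Perturb one parameter
#'
#' Returns a copy of the bundle with a single addressed entry replaced;
#' the input is untouched. Used by the one-way sensitivity analysis and
#' the price sweep. The result is re-validated.
#'
#' @param params A `cea_parameters` object.
#' @param path Dot-separated path to a leaf entry (see [parameter_paths()]).
#' @param value Replacement value (same shape as the addressed leaf).
#' @return A new `cea_parameters` object.
#' @examples
#' p <- default_parameters()
#' p2 <- perturb(p, "efficacy.dtg_obt1.suppression_rate_y1", 0.64)
#' p2$efficacy$dtg_obt1$suppression_rate_y1
#' @export
perturb <- function(params, path, value) {
  stopifnot(inherits(params, "cea_parameters"), is.character(path),
            length(path) == 1L)
  valid <- parameter_paths(params)
  if (!path %in% valid) {
    near <- head(sort(valid), 12L)
    abort(paste0(
      "unknown parameter path: ", path, "\nValid paths include: ",
      paste(near, collapse = ", "), ", ... (", length(valid), " total; see ",
      "parameter_paths())"))
  }
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- unclass(params)
  out[[keys]] <- value
  out <- structure(out, class = "cea_parameters")
  validate_parameters(out)
  out
}

#' Serialize a parameter bundle
#'
#' Writes the full bundle as YAML (same format as the input configuration)
#' for provenance logging; [load_parameters()] on the written file
#' reproduces an identical bundle.
#'
#' @param params A `cea_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(unclass(params), path, precision = 15L)
  invisible(path)
}

# Validation -----------------------------------------------------------------

chk <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("invalid parameters: ", msg))

chk_prob <- function(x, name) {
  chk(is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1),
      paste0(name, " must be a probability in [0,1]; got ",
             paste(format(x), collapse = ", ")))
}

chk_nonneg <- function(x, name) {
  chk(is.numeric(x) && all(!is.na(x)) && all(x >= 0),
      paste0(name, " must be non-negative; got ",
             paste(format(x), collapse = ", ")))
}

validate_parameters <- function(params) {
  p <- params

  # discounting
  chk_prob(p$discount$rate_early, "discount.rate_early")
  chk_prob(p$discount$rate_late, "discount.rate_late")
  chk(p$discount$switch_year > 0, "discount.switch_year must be > 0")
  chk(p$discount$apply_to %in% c("costs", "qalys", "both"),
      "discount.apply_to must be one of costs, qalys, both")

  # horizon / simulation
  chk(p$horizon$max_age_years > 18, "horizon.max_age_years must exceed 18")
  chk(is.na(p$horizon$months) || p$horizon$months >= 1,
      "horizon.months must be >= 1 (or NA for lifetime)")
  chk(p$simulation$n_patients >= 1, "simulation.n_patients must be >= 1")

  # cohort profile
  co <- p$cohort
  chk_prob(co$proportion_male, "cohort.proportion_male")
  chk_prob(co$proportion_suppressed, "cohort.proportion_suppressed")
  chk_prob(co$oi_history_proportion, "cohort.oi_history_proportion")
  chk(co$age_min >= 18, "cohort.age_min must be >= 18")
  chk(co$age_max >= co$age_min, "cohort.age_max must be >= age_min")
  chk(co$cd4_min >= 0, "cohort.cd4_min must be >= 0")
  chk(co$cd4_max >= co$cd4_min, "cohort.cd4_max must be >= cd4_min")
  chk(co$age_sd >= 0 && co$cd4_sdlog >= 0, "cohort dispersions must be >= 0")

  # efficacy blocks
  for (key in names(p$efficacy)) {
    e <- p$efficacy[[key]]
    nm <- paste0("efficacy.", key)
    chk_prob(e$suppression_rate_y1, paste0(nm, ".suppression_rate_y1"))
    chk_prob(e$suppression_ci, paste0(nm, ".suppression_ci"))
    chk(e$suppression_ci[1] <= e$suppression_rate_y1 &&
          e$suppression_rate_y1 <= e$suppression_ci[2],
        paste0(nm, ": CI must bracket the point estimate"))
    chk_prob(e$late_failure_m12_23, paste0(nm, ".late_failure_m12_23"))
    chk_prob(e$late_failure_m24plus, paste0(nm, ".late_failure_m24plus"))
    chk_nonneg(c(e$cd4_gain_y1, e$cd4_gain_y2, e$cd4_gain_later),
               paste0(nm, ".cd4_gain_*"))
  }

  # treatment algorithm
  tr <- p$treatment
  chk_prob(tr$ae_discontinuation_monthly, "treatment.ae_discontinuation_monthly")
  for (arm in c("dtg", "ral")) {
    chk_prob(tr$resistance_prob_on_failure[[arm]],
             paste0("treatment.resistance_prob_on_failure.", arm))
    for (st in c("no_resistance", "ini_resistance")) {
      seqn <- tr$lines[[arm]][[st]]
      chk(length(seqn) >= 1, paste0("treatment.lines.", arm, ".", st, " empty"))
      for (key in seqn) {
        chk(key %in% names(tr$definitions),
            paste0("line key '", key, "' in treatment.lines.", arm, ".", st,
                   " has no entry in treatment.definitions"))
      }
    }
  }
  for (key in names(tr$definitions)) {
    d <- tr$definitions[[key]]
    chk(d$efficacy %in% names(p$efficacy),
        paste0("treatment.definitions.", key, ": unknown efficacy block '",
               d$efficacy, "'"))
    for (comp in d$art_components) {
      chk(comp %in% names(p$costs$art_monthly),
          paste0("treatment.definitions.", key, ": ART cost component '",
                 comp, "' missing from costs.art_monthly"))
    }
  }

  # costs
  chk_nonneg(unlist(p$costs$art_monthly), "costs.art_monthly")
  chk(setequal(names(p$costs$routine_monthly), CD4_STRATA6),
      "costs.routine_monthly must cover exactly the six CD4 strata")
  for (s in CD4_STRATA6) {
    r <- p$costs$routine_monthly[[s]]
    chk(setequal(names(r), c("no_history", "history")),
        paste0("costs.routine_monthly.", s,
               " must have no_history and history entries"))
    chk_nonneg(unlist(r), paste0("costs.routine_monthly.", s))
  }
  chk(setequal(names(p$costs$oi_event), OI_TYPES),
      "costs.oi_event must cover the five OI types")
  chk_nonneg(unlist(p$costs$oi_event), "costs.oi_event")
  chk(setequal(names(p$costs$death),
               c("no_history", "history_gt30d", "history_le30d")),
      "costs.death must have no_history, history_gt30d, history_le30d")
  chk_nonneg(unlist(p$costs$death), "costs.death")
  chk_nonneg(p$costs$switch_cost, "costs.switch_cost")
  chk_nonneg(p$costs$tests_monthly, "costs.tests_monthly")

  # utilities
  u4 <- unlist(p$utilities$by_cd4[CD4_STRATA4])
  chk(length(u4) == 4L && all(!is.na(u4)), "utilities.by_cd4 must cover the four strata")
  chk_prob(u4, "utilities.by_cd4")
  chk(all(diff(u4) >= 0), "utilities.by_cd4 must be non-decreasing in CD4")
  uoi <- unlist(p$utilities$by_oi[OI_TYPES])
  chk(length(uoi) == 5L && all(!is.na(uoi)), "utilities.by_oi must cover the five OI types")
  chk_prob(uoi, "utilities.by_oi")

  # disease dynamics
  dd <- p$disease
  chk(dd$oi_duration_months >= 1, "disease.oi_duration_months must be >= 1")
  chk(dd$cd4_cap > 0, "disease.cd4_cap must be > 0")
  chk_nonneg(dd$terminal_decline_monthly, "disease.terminal_decline_monthly")
  chk_nonneg(dd$terminal_decline_macs_monthly, "disease.terminal_decline_macs_monthly")
  chk(dd$terminal_scenario %in% c("base", "macs_decline", "no_decline"),
      "disease.terminal_scenario must be base, macs_decline or no_decline")
  chk(dd$oi_history_multiplier >= 1, "disease.oi_history_multiplier must be >= 1")
  chk(setequal(names(dd$oi_hazard_monthly), CD4_STRATA6),
      "disease.oi_hazard_monthly must cover the six CD4 strata")
  for (s in CD4_STRATA6) {
    h <- dd$oi_hazard_monthly[[s]]
    chk(setequal(names(h), OI_TYPES),
        paste0("disease.oi_hazard_monthly.", s, " must cover the five OI types"))
    chk_prob(unlist(h), paste0("disease.oi_hazard_monthly.", s))
  }

  # mortality
  mo <- p$mortality
  chk(mo$acute_oi_multiplier >= 1, "mortality.acute_oi_multiplier must be >= 1")
  chk(setequal(names(mo$hiv_excess_annual), CD4_STRATA6),
      "mortality.hiv_excess_annual must cover the six CD4 strata")
  chk_prob(unlist(mo$hiv_excess_annual), "mortality.hiv_excess_annual")
  lt <- mo$life_table
  chk(length(lt$age_start) == length(lt$qx_male) &&
        length(lt$age_start) == length(lt$qx_female),
      "mortality.life_table columns must have equal length")
  chk(all(diff(lt$age_start) > 0), "mortality.life_table.age_start must increase")
  chk_prob(lt$qx_male, "mortality.life_table.qx_male")
  chk_prob(lt$qx_female, "mortality.life_table.qx_female")

  invisible(params)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters> ", x$meta$name, "\n", sep = "")
  cat("  arms: dtg, ral | discount ",
      100 * x$discount$rate_early, "% / ",
      100 * x$discount$rate_late, "% after year ",
      x$discount$switch_year, "\n", sep = "")
  cat("  horizon: ",
      if (is.na(x$horizon$months)) paste0("lifetime (age cap ", x$horizon$max_age_years, ")")
      else paste0(x$horizon$months, " months"),
      " | n_patients: ", x$simulation$n_patients, "\n", sep = "")
  cat("  fingerprint: ", parameter_fingerprint(x), "\n", sep = "")
  invisible(x)
}

#' Parameter fingerprint
#'
#' Stable hash of a parameter bundle, recorded in results objects so arm
#' comparisons can verify both arms were run under identical parameters.
#'
#' @param params A `cea_parameters` object.
#' @return A character scalar (hash).
#' @export
parameter_fingerprint <- function(params) {
  rlang::hash(unclass(params))
}

# Discounting ---------------------------------------------------------------

#' Tiered discount factor
#'
#' Present-value factor for an accrual at the start of month `month_index`
#' (month 0 = model entry, factor 1). Annual rate `rate_early` applies up
#' to `switch_year`; beyond it the factor continues from its boundary
#' value using `rate_late` (piecewise-continuous compounding, no jump).
#' Fractional-year exponents on the annual rates keep the factor exact at
#' year boundaries.
#'
#' @param month_index Integer vector of month indices (>= 0).
#' @param settings Discount settings list (`rate_early`, `rate_late`,
#'   `switch_year`), e.g. `params$discount`.
#' @return Numeric vector of factors in (0, 1].
#' @examples
#' p <- default_parameters()
#' discount_factor(c(0, 12, 372), p$discount)
#' @export
discount_factor <- function(month_index, settings) {
  if (any(month_index < 0)) abort("month_index must be >= 0")
  ms <- settings$switch_year * 12
  early <- (1 + settings$rate_early)^(-pmin(month_index, ms) / 12)
  late <- (1 + settings$rate_late)^(-pmax(month_index - ms, 0) / 12)
  early * late
}
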