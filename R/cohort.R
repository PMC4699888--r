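# Synthetic baseline cohort: treatment-experienced, INI-naive adults
# entering the model at virological failure.

# Truncated sampling by rejection, preserving the parent distribution's
# shape near the bounds. A degenerate [min, max] interval short-circuits;
# after `cap` rounds any stragglers are clamped (practically unreachable
# for sane profiles).
rtrunc <- function(n, draw, min, max, cap = 100L) {
  if (min == max) return(rep(min, n))
  x <- draw(n)
  bad <- which(x < min | x > max)
  i <- 0L
  while (length(bad) > 0L && i < cap) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] < min | x[bad] > max]
    i <- i + 1L
  }
  pmin(pmax(x, min), max)
}

#' Sample a baseline cohort
#'
#' Draws `n` patients from the baseline profile in `params$cohort`: age
#' (truncated normal), sex, CD4 count (truncated lognormal), entry
#' suppression flag and prior-OI history. One extra uniform draw per
#' patient (`u_line1`) is reserved for the first-line week-48 response so
#' that the same patient responds identically wherever the compared arms'
#' response rates coincide (common-random-numbers pairing). Identical
#' `(n, params, seed)` reproduce the cohort exactly, and the cohort is
#' shared byte-identically across arms.
#'
#' @param n Number of patients (>= 1).
#' @param params A `cea_parameters` object (profile read from
#'   `params$cohort`).
#' @param seed Integer seed.
#' @return A tibble with one row per patient: `id`, `age_years`, `sex`
#'   (`"M"`/`"F"`), `cd4`, `suppressed`, `oi_history`, `u_line1`.
#' @examples
#' cohort <- sample_cohort(5, default_parameters(), seed = 1)
#' @export
sample_cohort <- function(n, params = default_parameters(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("n must be a positive count")
  }
  n <- as.integer(n)
  pr <- params$cohort
  set.seed(seed)
  age <- rtrunc(n, function(k) rnorm(k, pr$age_mean, pr$age_sd),
                pr$age_min, pr$age_max)
  sex <- ifelse(runif(n) < pr$proportion_male, "M", "F")
  cd4 <- rtrunc(n, function(k) rlnorm(k, pr$cd4_meanlog, pr$cd4_sdlog),
                pr$cd4_min, pr$cd4_max)
  suppressed <- runif(n) < pr$proportion_suppressed
  oi_history <- runif(n) < pr$oi_history_proportion
  u_line1 <- runif(n)
  tibble::tibble(
    id = seq_len(n),
    age_years = age,
    sex = sex,
    cd4 = cd4,
    suppressed = suppressed,
    oi_history = oi_history,
    u_line1 = u_line1
  )
}

#' Export / import a cohort
#'
#' Round-trippable delimited representation (one row per patient) so an
#' identical baseline cohort can be replayed across runs and machines.
#'
#' @param cohort A cohort tibble from [sample_cohort()].
#' @param path File path (CSV).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_integer(),
    age_years = readr::col_double(),
    sex = readr::col_character(),
    cd4 = readr::col_double(),
    suppressed = readr::col_logical(),
    oi_history = readr::col_logical(),
    u_line1 = readr::col_double()
  ))
}
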