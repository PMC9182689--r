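#' Impute right-censored survival times by conditional empirical residuals
#'
#' Each censored time t is replaced by t + mean(s - t | s > t), the mean
#' residual life under the empirical distribution of observed deaths s.
#' Observed deaths pass through unchanged. A censored time exceeding
#' every observed death has no qualifying deaths; it is left unchanged
#' (zero residual) and flagged in the `fallback` attribute.
#'
#' @param months survival times in months.
#' @param dead logical; TRUE for observed deaths, FALSE for
#'   alive-at-cutoff (censored).
#' @return numeric vector of imputed survival times, with attribute
#'   `fallback`: indices of censored records beyond all observed deaths.
#' @examples
#' impute_censored(c(10, 20, 30, 15), c(TRUE, TRUE, TRUE, FALSE))
#' @export
impute_censored <- function(months, dead) {
  stopifnot(length(months) == length(dead), all(months >= 0))
  dead <- as.logical(dead)
  deaths <- sort(months[dead])
  out <- months
  fallback <- integer(0)
  cens_idx <- which(!dead)
  if (length(cens_idx) && length(deaths)) {
    # for each censored t, residual = mean(deaths > t) - t
    cs <- cumsum(deaths)
    total <- cs[length(deaths)]
    for (i in cens_idx) {
      t <- months[i]
      nle <- findInterval(t, deaths)  # deaths <= t
      ngt <- length(deaths) - nle
      if (ngt == 0) {
        fallback <- c(fallback, i)
      } else {
        sum_gt <- total - if (nle > 0) cs[nle] else 0
        out[i] <- t + (sum_gt / ngt - t)
      }
    }
  } else if (length(cens_idx)) {
    fallback <- cens_idx
  }
  if (length(fallback))
    warning(sprintf(
      "%d censored record(s) exceed every observed death; left unimputed",
      length(fallback)))
  attr(out, "fallback") <- fallback
  out
}

#' Conditional residual life expectancy lookup
#'
#' Life tables are stratified into age bands up to 64, 65-74, and 75 and
#' over, per ancestry and sex. The lookup is piecewise constant in age;
#' a discontinuity at the band boundaries (notably age 65) is expected
#' and propagates as a slight artificial upward bump in modeled survival.
#'
#' @param life_table data.frame with columns ancestry, sex, age_band
#'   (one of "<=64", "65-74", "75+"), expectancy_years.
#' @param ancestry,sex labels.
#' @param age age in years.
#' @return residual life expectancy, years.
#' @export
conditional_life_expectancy <- function(life_table, ancestry, sex, age) {
  band <- if (age <= 64) "<=64" else if (age <= 74) "65-74" else "75+"
  row <- life_table[life_table$ancestry == ancestry &
                    life_table$sex == sex &
                    life_table$age_band == band, , drop = FALSE]
  if (nrow(row) == 0)
    stop(sprintf("life table has no entry for %s/%s/%s", ancestry, sex, band))
  row$expectancy_years[1]
}

#' Default estimation configuration
#'
#' @param mean_diag_to_treatment tunable mean months between diagnosis
#'   and treatment start (not reliably recorded in registries).
#' @param mean_early_sojourn months from disease initiation to the next
#'   transition; default 180 (a 15-year window of pre-symptomatic
#'   progression, as estimated for pancreatic-type disease).
#' @param death_frac,screen_frac,progress_frac early-disease routing
#'   fractions r10, r12, r13 (scenario assumptions, not estimable from
#'   diagnosis-anchored registries).
#' @param min_subgroup minimum records per subgroup; smaller subgroups
#'   are excluded.
#' @param window diagnosis-year study window.
#' @return a named list.
#' @export
estimation_config <- function(mean_diag_to_treatment = 1,
                              mean_early_sojourn = 180,
                              death_frac = 0.1, screen_frac = 0.3,
                              progress_frac = 0.6,
                              min_subgroup = 100,
                              window = c(2000, 2016)) {
  list(mean_diag_to_treatment = mean_diag_to_treatment,
       mean_early_sojourn = mean_early_sojourn,
       death_frac = death_frac, screen_frac = screen_frac,
       progress_frac = progress_frac, min_subgroup = min_subgroup,
       window = window)
}

# midpoint age of a "lo-hi" band label
age_band_midpoint <- function(band) {
  parts <- as.numeric(strsplit(band, "-", fixed = TRUE)[[1]])
  mean(parts)
}

#' Estimate subgroup disease parameters from a registry table
#'
#' Empirical estimators, registry-anchored: eta1 is the mean yearly
#' diagnosis count over the study window; the treated fraction f is the
#' unweighted mean of per-year treated fractions; mean treated survival
#' is the mean of (imputed survival - months to treatment) among treated
#' patients, after right-censoring imputation over the whole subgroup;
#' mean late-stage survival combines the treated and untreated paths,
#' 1/mu3 = f * (w + treated survival) + (1 - f) * untreated survival,
#' with w the configured diagnosis-to-treatment mean. L comes from the
#' life table at the age-band midpoint. Incidence underestimation from
#' deaths before diagnosis is not corrected; a warning is emitted for
#' bands at 75 and over, where the approximation is weakest.
#'
#' @param registry data.frame in registry format (see [read_registry()]).
#' @param key a [subgroup_key()].
#' @param life_table life table data.frame (see
#'   [conditional_life_expectancy()]).
#' @param config list from [estimation_config()].
#' @return a [subgroup_params()] with extra fields `n_records` and
#'   `mean_treated_survival`, `mean_untreated_survival`.
#' @export
estimate_subgroup_params <- function(registry, key, life_table,
                                     config = estimation_config()) {
  sub <- registry[registry$cancer_type == key[["cancer_type"]] &
                  registry$sex == key[["sex"]] &
                  registry$ancestry == key[["ancestry"]] &
                  registry$age_band == key[["age_band"]] &
                  registry$diagnosis_year >= config$window[1] &
                  registry$diagnosis_year <= config$window[2], , drop = FALSE]
  n <- nrow(sub)
  if (n < config$min_subgroup)
    stop(sprintf("excluded: insufficient sample (%d < %d) for %s",
                 n, config$min_subgroup, format(key)),
         call. = FALSE)
  mid <- age_band_midpoint(key[["age_band"]])
  if (mid >= 75)
    warning("75+ band: incidence may be underestimated by deaths before diagnosis")

  years <- config$window[1]:config$window[2]
  counts <- vapply(years, function(y) sum(sub$diagnosis_year == y), numeric(1))
  eta1 <- mean(counts)

  per_year_f <- vapply(years, function(y) {
    yr <- sub[sub$diagnosis_year == y, , drop = FALSE]
    if (nrow(yr) == 0) NA_real_ else mean(yr$treated)
  }, numeric(1))
  f <- mean(per_year_f, na.rm = TRUE)

  # impute within treatment strata: treated and untreated survival laws
  # differ sharply, so the conditional empirical residual is taken among
  # comparable patients
  treated <- which(sub$treated)
  untreated <- which(!sub$treated)
  imputed <- sub$survival_months
  for (idx in list(treated, untreated)) {
    if (length(idx))
      imputed[idx] <- suppressWarnings(
        impute_censored(sub$survival_months[idx],
                        sub$vital_status[idx] == "dead"))
  }
  mean_treated <- if (length(treated))
    mean(pmax(imputed[treated] - sub$months_to_treatment[treated], 0))
  else NA_real_
  mean_untreated <- if (length(untreated)) mean(imputed[untreated])
  else NA_real_

  w <- config$mean_diag_to_treatment
  late <- f * (w + ifelse(is.na(mean_treated), 0, mean_treated)) +
    (1 - f) * ifelse(is.na(mean_untreated), 0, mean_untreated)

  L <- conditional_life_expectancy(life_table, key[["ancestry"]],
                                   key[["sex"]], mid)
  out <- subgroup_params(diagnosis_rate = eta1,
                         mean_early_sojourn = config$mean_early_sojourn,
                         death_frac = config$death_frac,
                         screen_frac = config$screen_frac,
                         progress_frac = config$progress_frac,
                         mean_late_survival = late,
                         cond_life_expectancy = L,
                         treated_fraction = f,
                         mean_diag_to_treatment = w,
                         key = key)
  out$n_records <- n
  out$mean_treated_survival <- mean_treated
  out$mean_untreated_survival <- mean_untreated
  out
}
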