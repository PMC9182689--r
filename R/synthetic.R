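#' Specification for a synthetic registry
#'
#' Describes the ground truth from which SEER-like registry tables are
#' generated: per-subgroup Poisson yearly diagnosis arrivals, Bernoulli
#' treatment routing, arbitrary survival distributions, and
#' administrative right-censoring at a study cutoff.
#'
#' Default distributions emulate a poor-prognosis cancer: treated
#' survival lognormal with mean 13.5 months and cv ~ 0.95; untreated
#' survival exponential with mean 3 months; time to treatment uniform on
#' (0, 2) months.
#'
#' @param subgroups data.frame with columns cancer_type, sex, ancestry,
#'   age_band, eta1 (cases/year), treated_fraction.
#' @param treated_survival,untreated_survival,months_to_treatment
#'   [service_spec()] objects (months).
#' @param window diagnosis-year range, default 2000-2016.
#' @param cutoff_year decimal year of administrative censoring; default
#'   the end of the window (patients alive then are censored).
#' @param age_band_weights optional named weights over 5-year bands for
#'   drawing age at diagnosis; default uniform over the listed bands.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(subgroups,
                       treated_survival = svc_lognormal_mean(13.5, 0.95),
                       untreated_survival = svc_exponential(3),
                       months_to_treatment = svc_uniform(0, 2),
                       window = c(2000, 2016),
                       cutoff_year = NULL) {
  stopifnot(is.data.frame(subgroups),
            all(c("cancer_type", "sex", "ancestry", "age_band", "eta1",
                  "treated_fraction") %in% names(subgroups)),
            all(subgroups$eta1 > 0),
            all(subgroups$treated_fraction >= 0 &
                subgroups$treated_fraction <= 1),
            window[2] >= window[1])
  if (is.null(cutoff_year)) cutoff_year <- window[2] + 1  # end of last year
  structure(list(subgroups = subgroups,
                 treated_survival = treated_survival,
                 untreated_survival = untreated_survival,
                 months_to_treatment = months_to_treatment,
                 window = window, cutoff_year = cutoff_year),
            class = "synth_spec")
}

#' Generate a synthetic registry with known ground truth
#'
#' Per subgroup and calendar year, the diagnosis count is
#' Poisson(eta1); each case receives a treated flag ~ Bernoulli(f), a
#' survival time from the matching distribution (treated: time to
#' treatment plus post-treatment survival; untreated: untreated
#' survival), and is right-censored if the death date exceeds the
#' cutoff. Fully reproducible given `seed`.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @return a registry data.frame (see [read_registry()] for the schema)
#'   with attribute `truth` echoing the generating parameters.
#' @export
generate_registry <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  years <- spec$window[1]:spec$window[2]
  rows <- list()
  for (g in seq_len(nrow(spec$subgroups))) {
    sg <- spec$subgroups[g, ]
    band_lo <- as.numeric(strsplit(sg$age_band, "-", fixed = TRUE)[[1]][1])
    for (y in years) {
      n <- stats::rpois(1, sg$eta1)
      if (n == 0) next
      diag_time <- y + stats::runif(n)          # decimal year of diagnosis
      treated <- stats::runif(n) < sg$treated_fraction
      m2t <- rep(NA_real_, n)
      surv <- numeric(n)
      nt <- sum(treated)
      if (nt > 0) {
        m2t[treated] <- service_draw(spec$months_to_treatment, nt)
        surv[treated] <- m2t[treated] +
          service_draw(spec$treated_survival, nt)
      }
      if (nt < n)
        surv[!treated] <- service_draw(spec$untreated_survival, n - nt)
      death_time <- diag_time + surv / 12
      censored <- death_time > spec$cutoff_year
      obs_surv <- ifelse(censored,
                         pmax((spec$cutoff_year - diag_time) * 12, 0), surv)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = NA_integer_,
        cancer_type = sg$cancer_type, sex = sg$sex,
        ancestry = sg$ancestry, age_band = sg$age_band,
        age_at_diagnosis = band_lo + floor(stats::runif(n, 0, 5)),
        diagnosis_year = y, treated = treated,
        months_to_treatment = ifelse(censored & treated &
                                       m2t > obs_surv, NA, m2t),
        survival_months = obs_surv,
        vital_status = ifelse(censored, "alive", "dead"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # drop treated cases censored before treatment started: their flag is
  # unobservable at cutoff, mirroring registry semantics
  drop <- out$treated & is.na(out$months_to_treatment)
  out$treated[drop] <- FALSE
  out$survival_months <- round(out$survival_months, 3)
  out$months_to_treatment <- round(out$months_to_treatment, 3)
  out$patient_id <- seq_len(nrow(out))
  attr(out, "truth") <- list(
    subgroups = spec$subgroups,
    mean_treated_survival = spec$treated_survival$mean,
    mean_untreated_survival = spec$untreated_survival$mean,
    mean_months_to_treatment = spec$months_to_treatment$mean,
    window = spec$window, cutoff_year = spec$cutoff_year, seed = seed)
  out
}

#' Generate a complete life table
#'
#' A full ancestry x sex x age-band (<=64, 65-74, 75+) table of residual
#' life expectancies; a synthetic stand-in for national life tables.
#'
#' @param ancestries,sexes label vectors.
#' @param expectancies named numeric vector of expectancy (years) per
#'   band, default c("<=64" = 30, "65-74" = 17, "75+" = 10).
#' @return data.frame with columns ancestry, sex, age_band,
#'   expectancy_years.
#' @export
generate_life_table <- function(ancestries = c("Caucasian",
                                               "African American",
                                               "Asian/Pacific Islander",
                                               "Hispanic"),
                                sexes = c("Female", "Male"),
                                expectancies = c("<=64" = 30,
                                                 "65-74" = 17,
                                                 "75+" = 10)) {
  if (!all(c("<=64", "65-74", "75+") %in% names(expectancies)))
    stop("expectancies must cover bands <=64, 65-74, 75+")
  if (any(expectancies <= 0)) stop("expectancies must be positive")
  out <- expand.grid(ancestry = ancestries, sex = sexes,
                     age_band = names(expectancies),
                     stringsAsFactors = FALSE)
  out$expectancy_years <- unname(expectancies[out$age_band])
  rownames(out) <- NULL
  attr(out, "out.attrs") <- NULL
  out
}

#' Generate a population-size table
#'
#' @param subgroups data.frame with subgroup key columns and a
#'   `population` column of screenable counts (positive integers).
#' @return validated data.frame.
#' @export
generate_population_table <- function(subgroups) {
  stopifnot(is.data.frame(subgroups), "population" %in% names(subgroups),
            all(subgroups$population > 0),
            all(subgroups$population == floor(subgroups$population)))
  subgroups
}
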