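registry_columns <- c("patient_id", "cancer_type", "sex", "ancestry",
                      "age_band", "age_at_diagnosis", "diagnosis_year",
                      "treated", "months_to_treatment", "survival_months",
                      "vital_status")

#' Read / write a registry CSV
#'
#' UTF-8 comma-separated with header; one row per cancer case with
#' columns patient_id, cancer_type, sex, ancestry, age_band,
#' age_at_diagnosis (years), diagnosis_year, treated (logical),
#' months_to_treatment (missing when untreated), survival_months,
#' vital_status ("dead" or "alive"). Malformed rows (negative survival,
#' treatment time on untreated cases) are rejected with their line
#' numbers.
#'
#' @param path CSV path.
#' @return `read_registry`: the validated data.frame, row order
#'   preserved.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty registry file: ", path)
  missing_cols <- setdiff(registry_columns, names(df))
  if (length(missing_cols))
    stop("registry is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$treated <- as.logical(df$treated)
  bad <- which(df$survival_months < 0 |
               (!df$treated & !is.na(df$months_to_treatment)) |
               !(df$vital_status %in% c("dead", "alive")))
  if (length(bad))
    stop("malformed registry row(s) at line(s): ",
         paste(utils::head(bad + 1L, 20), collapse = ", "))
  df
}

#' @rdname read_registry
#' @param registry a registry data.frame.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry[, registry_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a life table CSV
#'
#' Columns ancestry, sex, age_band (one of "<=64", "65-74", "75+"),
#' expectancy_years.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ancestry", "sex", "age_band", "expectancy_years")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("life table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(df$expectancy_years <= 0))
    stop("life expectancies must be positive")
  df
}

#' Read a population-size table CSV
#'
#' Columns cancer_type, sex, ancestry, age_band, population.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_population_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"population" %in% names(df))
    stop("population table is missing column: population")
  generate_population_table(df)
}

#' Evaluate a screening scenario over every subgroup in a registry
#'
#' Fits subgroup parameters, builds the screening and no-screening
#' networks, and reports the modeled benefit per cancer patient (years),
#' per positive case detected (years), and per screen (days), with
#' exclusion flags for undersized subgroups. Deterministic given the
#' inputs; rows are ordered by the chosen score, descending.
#'
#' @param registry registry data.frame ([read_registry()]).
#' @param life_table life table data.frame ([read_life_table()]).
#' @param population population table ([read_population_table()]).
#' @param scenario a [screening_scenario()].
#' @param config an [estimation_config()].
#' @param order_by score used for the report ordering: "per_screen" or
#'   "per_patient".
#' @return data.frame with one row per subgroup.
#' @export
run_evaluate <- function(registry, life_table, population, scenario,
                         config = estimation_config(),
                         order_by = c("per_screen", "per_patient")) {
  order_by <- match.arg(order_by)
  keys <- unique(registry[, c("cancer_type", "sex", "ancestry", "age_band")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- do.call(subgroup_key, as.list(keys[i, ]))
    base <- data.frame(cancer_type = k[["cancer_type"]], sex = k[["sex"]],
                       ancestry = k[["ancestry"]], age_band = k[["age_band"]],
                       stringsAsFactors = FALSE)
    params <- tryCatch(
      suppressWarnings(
        estimate_subgroup_params(registry, k, life_table, config)),
      error = function(e) e)
    if (inherits(params, "error")) {
      base$n_records <- NA_integer_
      base$excluded <- TRUE
      base$gain_years <- NA_real_
      base$gain_per_positive_years <- NA_real_
      base$gain_per_screen_days <- NA_real_
      return(base)
    }
    pop_row <- population[population$cancer_type == k[["cancer_type"]] &
                          population$sex == k[["sex"]] &
                          population$ancestry == k[["ancestry"]] &
                          population$age_band == k[["age_band"]], , drop = FALSE]
    gain <- lifetime_gain(params, scenario)
    base$n_records <- params$n_records
    base$excluded <- FALSE
    base$gain_years <- gain
    base$gain_per_positive_years <- lifetime_gain(params, scenario,
                                                  per_positive = TRUE)
    base$gain_per_screen_days <- if (nrow(pop_row))
      per_screen_benefit(gain, params, pop_row$population[1],
                         scenario$screens_per_person_year)
    else NA_real_
    base
  })
  out <- do.call(rbind, rows)
  score <- if (order_by == "per_screen") out$gain_per_screen_days
           else out$gain_years
  out <- out[order(-ifelse(is.na(score), -Inf, score)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a registry the way published registry overview tables do
#'
#' Per cancer type: case counts, composition by sex / age band /
#' ancestry (counts and percentages), and survival mean, SD, median and
#' range. A pooled "Overall" stratum is appended.
#'
#' @param registry a registry data.frame.
#' @return list of data.frames: `totals`, `by_sex`, `by_age`,
#'   `by_ancestry`, `survival`.
#' @export
summarise_registry <- function(registry) {
  types <- sort(unique(registry$cancer_type))
  strata <- c(types, "Overall")
  pick <- function(tt) if (tt == "Overall") registry
                       else registry[registry$cancer_type == tt, , drop = FALSE]
  totals <- data.frame(cancer_type = strata,
                       n = vapply(strata, function(tt) nrow(pick(tt)),
                                  numeric(1)))
  comp <- function(var) {
    levels <- sort(unique(registry[[var]]))
    do.call(rbind, lapply(strata, function(tt) {
      sub <- pick(tt)
      n <- vapply(levels, function(l) sum(sub[[var]] == l), numeric(1))
      data.frame(cancer_type = tt, level = levels, n = n,
                 pct = 100 * n / nrow(sub), stringsAsFactors = FALSE)
    }))
  }
  survival <- do.call(rbind, lapply(strata, function(tt) {
    s <- pick(tt)$survival_months
    data.frame(cancer_type = tt, mean = mean(s), sd = stats::sd(s),
               median = stats::median(s), min = min(s), max = max(s))
  }))
  rownames(survival) <- NULL
  list(totals = totals, by_sex = comp("sex"), by_age = comp("age_band"),
       by_ancestry = comp("ancestry"), survival = survival)
}
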