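#' Published SEER summary counts (2000-2016)
#'
#' Loads the bundled long-format transcription of a published SEER
#' overview of six cancer types without population screening programs
#' (esophagus, kidney, liver, mesothelioma, ovary, pancreas; diagnosis
#' years 2000-2016): case counts by sex, 5-year age band and ancestry,
#' plus survival summary statistics (months). Used for incidence-scale
#' inputs and arithmetic cross-checks.
#'
#' @param path CSV path; default the bundled copy.
#' @return data.frame with columns cancer_type, category
#'   (total/sex/age/ancestry/survival), level, value.
#' @export
read_registry_summary <- function(path = system.file(
    "extdata", "registry_summary_counts.csv", package = "screenq")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cancer_type", "category", "level", "value") %in%
                names(df)))
  df
}

#' Derived arithmetic of a registry summary table
#'
#' Recomputes, from the per-type counts alone, the quantities such
#' overview tables print: the pooled total, pooled strata counts
#' (summing types), within-type percentages, the pooled mean survival
#' (case-weighted mean of per-type means), and per-type mean yearly
#' incidence over the study window.
#'
#' @param summary data.frame from [read_registry_summary()].
#' @param years number of diagnosis years covered, default 17
#'   (2000-2016).
#' @return list with `total_cases`, `per_type_n`, `pooled_strata`
#'   (sex/age/ancestry counts summed over types), `pct` (within-type
#'   percentages by category/level), `pooled_mean_survival` (months),
#'   and `yearly_incidence` (cases/year per type).
#' @export
summary_arithmetic <- function(summary, years = 17) {
  types <- setdiff(unique(summary$cancer_type), "Overall")
  n_of <- function(tt) summary$value[summary$cancer_type == tt &
                                     summary$category == "total"]
  per_type_n <- vapply(types, n_of, numeric(1))
  total <- sum(per_type_n)

  strata <- summary[summary$cancer_type != "Overall" &
                    summary$category %in% c("sex", "age", "ancestry"), ]
  pooled <- stats::aggregate(value ~ category + level, strata, sum)

  pct <- summary[summary$category %in% c("sex", "age", "ancestry"), ]
  pct$pct <- 100 * pct$value / vapply(pct$cancer_type, function(tt) {
    if (tt == "Overall") total else n_of(tt)
  }, numeric(1))

  means <- vapply(types, function(tt) {
    summary$value[summary$cancer_type == tt &
                  summary$category == "survival" &
                  summary$level == "mean"]
  }, numeric(1))
  pooled_mean <- sum(per_type_n * means) / total

  list(total_cases = total,
       per_type_n = per_type_n,
       pooled_strata = pooled,
       pct = pct,
       pooled_mean_survival = pooled_mean,
       yearly_incidence = per_type_n / years)
}
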