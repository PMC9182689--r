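#' Disease parameters for one population subgroup
#'
#' Parameters of the three-state disease model for one subgroup (cancer
#' type x sex x ancestry x 5-year age band): undetected early disease,
#' early-treated disease, late-stage (symptomatic) disease.
#'
#' @param diagnosis_rate eta1, new cases per year.
#' @param mean_early_sojourn 1/mu1, months from disease initiation to the
#'   next transition (death, early detection, or symptomatic progression).
#' @param death_frac,screen_frac,progress_frac r10, r12, r13: routing
#'   probabilities out of the early-disease state; must sum to 1.
#' @param mean_late_survival 1/mu3, months survived after symptomatic
#'   (late) presentation.
#' @param treated_fraction f, fraction of diagnosed patients treated.
#' @param mean_diag_to_treatment months between diagnosis and treatment
#'   start (a tunable parameter; not reliably recorded in registries).
#' @param cond_life_expectancy L, residual life expectancy in years
#'   conditional on having reached the subgroup's age.
#' @param key optional subgroup key (see [subgroup_key()]).
#' @return object of class `subgroup_params`.
#' @export
subgroup_params <- function(diagnosis_rate, mean_early_sojourn,
                            death_frac, screen_frac, progress_frac,
                            mean_late_survival, cond_life_expectancy,
                            treated_fraction = NA_real_,
                            mean_diag_to_treatment = NA_real_,
                            key = NULL) {
  if (abs(death_frac + screen_frac + progress_frac - 1) > 1e-12)
    stop("death_frac + screen_frac + progress_frac must equal 1")
  stopifnot(diagnosis_rate > 0, mean_early_sojourn > 0,
            mean_late_survival > 0, cond_life_expectancy > 0,
            death_frac >= 0, screen_frac >= 0, progress_frac >= 0)
  if (!is.na(treated_fraction))
    stopifnot(treated_fraction >= 0, treated_fraction <= 1)
  structure(list(diagnosis_rate = diagnosis_rate,
                 mean_early_sojourn = mean_early_sojourn,
                 death_frac = death_frac, screen_frac = screen_frac,
                 progress_frac = progress_frac,
                 mean_late_survival = mean_late_survival,
                 cond_life_expectancy = cond_life_expectancy,
                 treated_fraction = treated_fraction,
                 mean_diag_to_treatment = mean_diag_to_treatment,
                 key = key),
            class = "subgroup_params")
}

#' Subgroup key
#'
#' @param cancer_type,sex,ancestry labels.
#' @param age_band 5-year band label, e.g. "50-54".
#' @return object of class `subgroup_key` (a named character vector).
#' @export
subgroup_key <- function(cancer_type, sex, ancestry, age_band) {
  structure(c(cancer_type = cancer_type, sex = sex, ancestry = ancestry,
              age_band = age_band), class = "subgroup_key")
}

#' @export
format.subgroup_key <- function(x, ...) paste(unclass(x), collapse = "/")

#' Screening scenario
#'
#' The knobs of a hypothetical screening program.
#'
#' @param detection d in [0,1], probability an early-disease episode is
#'   detected by the screen.
#' @param effectiveness e in [0,1], fraction of the subgroup's
#'   conditional residual life expectancy attained on average by
#'   early-detected patients.
#' @param qaly_factor quality-of-life weight in [0,1] for
#'   treatment-associated morbidity (1 = no reduction).
#' @param mortality_prob p in [0,1], probability of treatment-induced
#'   premature death among the early-treated.
#' @param mortality_survival months survived under treatment-induced
#'   death; default a point mass at one month.
#' @param false_positive_rate per-screen probability of a false positive
#'   in a healthy individual.
#' @param confirmatory_specificity specificity of the confirmatory test
#'   applied after a positive screen; only the (1 - specificity) fraction
#'   of false positives proceeds to unnecessary treatment.
#' @param fp_survival_reduction fraction of conditional life expectancy
#'   lost by a treated false positive, in [0,1].
#' @param screens_per_person_year screening frequency in the eligible
#'   population.
#' @return object of class `screening_scenario`.
#' @export
screening_scenario <- function(detection, effectiveness, qaly_factor = 1,
                               mortality_prob = 0, mortality_survival = 1,
                               false_positive_rate = 0,
                               confirmatory_specificity = 1,
                               fp_survival_reduction = 0,
                               screens_per_person_year = 1) {
  probs <- c(detection = detection, effectiveness = effectiveness,
             qaly_factor = qaly_factor, mortality_prob = mortality_prob,
             false_positive_rate = false_positive_rate,
             confirmatory_specificity = confirmatory_specificity,
             fp_survival_reduction = fp_survival_reduction)
  if (any(probs < 0 | probs > 1))
    stop("scenario probabilities must lie in [0,1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  stopifnot(mortality_survival > 0, screens_per_person_year > 0)
  structure(as.list(c(probs, mortality_survival = mortality_survival,
                      screens_per_person_year = screens_per_person_year)),
            class = "screening_scenario")
}

# early-treatment service: e * L years, as a mortality mixture when p > 0
early_treatment_service <- function(params, scenario) {
  eL <- scenario$effectiveness * params$cond_life_expectancy * 12  # months
  if (eL <= 0)
    stop("degenerate early-treatment survival: effectiveness * L is zero")
  base <- svc_exponential(eL)
  apply_mortality(base, scenario$mortality_prob,
                  svc_deterministic(scenario$mortality_survival))
}

#' Build the three-queue screening network for a subgroup
#'
#' Queue 1: undetected early disease (mean 1/mu1). On leaving, a fraction
#' r10 dies, r12*d is detected early and enters early treatment (queue 2,
#' mean e*L, with the treatment-mortality mixture applied), and the rest
#' -- r13 plus the undetected screenable mass r12*(1-d) -- progresses to
#' late-stage disease (queue 3, mean 1/mu3). Exogenous arrivals (eta1, 0, 0).
#'
#' @param params a [subgroup_params()].
#' @param scenario a [screening_scenario()].
#' @return a [queue_network()].
#' @export
build_screening_network <- function(params, scenario) {
  d <- scenario$detection
  r12d <- params$screen_frac * d
  if (r12d > 0 && scenario$effectiveness * params$cond_life_expectancy <= 0)
    stop("degenerate early-treatment survival")
  R <- matrix(0, 3, 3)
  R[1, 2] <- r12d
  R[1, 3] <- params$progress_frac + params$screen_frac * (1 - d)
  # zero detection collapses exactly to the no-screening counterfactual
  svc2 <- if (r12d > 0) early_treatment_service(params, scenario)
          else svc_exponential(params$mean_late_survival)
  queue_network(
    routing = R,
    exogenous_rates = c(params$diagnosis_rate / 12, 0, 0),
    services = list(svc_exponential(params$mean_early_sojourn),
                    svc2,
                    svc_exponential(params$mean_late_survival)),
    labels = c("early_undetected", "early_treated", "late_stage"))
}

#' Build the no-screening counterfactual network
#'
#' Identical to [build_screening_network()] with the screened mass
#' reassigned to symptomatic progression: routing row 1 becomes
#' (0, 0, r13 + r12), so the early-treatment queue has zero inflow.
#'
#' @inheritParams build_screening_network
#' @return a [queue_network()].
#' @export
build_no_screening_network <- function(params) {
  R <- matrix(0, 3, 3)
  R[1, 3] <- params$progress_frac + params$screen_frac
  queue_network(
    routing = R,
    exogenous_rates = c(params$diagnosis_rate / 12, 0, 0),
    services = list(svc_exponential(params$mean_early_sojourn),
                    svc_exponential(params$mean_late_survival),
                    svc_exponential(params$mean_late_survival)),
    labels = c("early_undetected", "early_treated", "late_stage"))
}

#' Two-queue diagnosis/treatment network
#'
#' The validation model: queue 1 holds diagnosed patients awaiting the
#' next event; a fraction r12 proceeds to a treatment queue (e.g.
#' surgery), the rest exits. Used to test the product-form predictions
#' against registry-style data.
#'
#' @param eta1 diagnosis rate, per year.
#' @param r12 routing probability into the treatment queue.
#' @param service1,service2 [service_spec()]s for the two queues (months).
#' @return a [queue_network()].
#' @export
build_two_queue_network <- function(eta1, r12, service1, service2) {
  stopifnot(r12 >= 0, r12 <= 1)
  queue_network(matrix(c(0, r12, 0, 0), 2, 2, byrow = TRUE),
                c(eta1 / 12, 0), list(service1, service2),
                labels = c("awaiting", "treated"))
}

#' Expected residual-lifetime gain from screening
#'
#' Difference in expected network sojourn (Little's law) between the
#' screening network and its no-screening counterfactual, per cancer
#' patient, in years. With `per_positive = TRUE` the gain is reported per
#' early-detected case, i.e. divided by the routing probability r12*d
#' into the early-treatment queue.
#'
#' @inheritParams build_screening_network
#' @param per_positive report gain per positive case detected instead of
#'   per cancer patient.
#' @return gain in years.
#' @export
lifetime_gain <- function(params, scenario, per_positive = FALSE) {
  with_s <- expected_sojourn(build_screening_network(params, scenario))
  without <- expected_sojourn(build_no_screening_network(params))
  gain <- (with_s - without) / 12
  if (per_positive) {
    p2 <- params$screen_frac * scenario$detection
    gain <- if (p2 > 0) gain / p2 else 0
  }
  gain
}

#' Per-screen benefit
#'
#' Converts a per-patient gain into expected extra life per screen
#' administered. The per-screen detection yield is the standing pool of
#' undetected early disease, rho1 = eta1 * (1/mu1), divided by the
#' screenable population, so
#' benefit = gain_years * 365 * rho1 / population_size, in days.
#'
#' @param gain_years per-cancer-patient lifetime gain, years.
#' @param params a [subgroup_params()].
#' @param population_size screenable individuals in the subgroup.
#' @param screens_per_person_year screening frequency; the standing-pool
#'   yield is per screening instant and does not vary with it (kept for
#'   interface completeness).
#' @return benefit in days per screen.
#' @export
per_screen_benefit <- function(gain_years, params, population_size,
                               screens_per_person_year = 1) {
  if (population_size <= 0) stop("population_size must be positive")
  rho1 <- (params$diagnosis_rate / 12) * params$mean_early_sojourn
  gain_years * 365 * rho1 / population_size
}

#' Quality-adjust a survival period for treatment morbidity
#'
#' The affected portion of the sojourn is multiplied by the QALY factor
#' q; the remainder is unweighted (temporary side effects reweight only
#' the period when they occur).
#'
#' @param sojourn_years unadjusted survival, years.
#' @param qaly_factor q in [0,1].
#' @param affected_fraction fraction of the period experiencing side
#'   effects, in [0,1]; default the whole period.
#' @return quality-adjusted years.
#' @export
apply_morbidity <- function(sojourn_years, qaly_factor,
                            affected_fraction = 1) {
  if (qaly_factor < 0 || qaly_factor > 1)
    stop("qaly_factor must lie in [0,1]")
  if (affected_fraction < 0 || affected_fraction > 1)
    stop("affected_fraction must lie in [0,1]")
  sojourn_years * (affected_fraction * qaly_factor + (1 - affected_fraction))
}

#' Mix treatment-associated mortality into a service distribution
#'
#' With probability p the service time is a short "premature death"
#' distribution (default a point mass at one month); with probability
#' 1 - p it is the original distribution.
#'
#' @param service a [service_spec()].
#' @param p treatment-induced mortality probability in [0,1].
#' @param early_death [service_spec()] for the premature-death time;
#'   default point mass at 1 month.
#' @return a [service_spec()] (the original object when p = 0).
#' @export
apply_mortality <- function(service, p, early_death = svc_deterministic(1)) {
  if (p < 0 || p > 1) stop("p must lie in [0,1]")
  if (p == 0) return(service)
  if (p == 1) return(early_death)
  svc_mixture(list(early_death, service), c(p, 1 - p))
}

#' Net screening benefit accounting for imperfect specificity
#'
#' Extends the screening evaluation with a false-positive queue fed by
#' the healthy population: each screen of a healthy person yields a false
#' positive with probability `false_positive_rate`, of which a fraction
#' (1 - confirmatory_specificity) survives the confirmatory test and is
#' unnecessarily treated, losing `fp_survival_reduction * L` years.
#' Net benefit (years per cohort-year) = true-positive gains
#' (eta1 * per-patient gain) minus false-positive losses; negative when
#' overtreatment of the healthy outweighs early detection.
#'
#' @inheritParams build_screening_network
#' @param healthy_population screenable healthy individuals.
#' @return net years per cohort-year (may be negative).
#' @export
net_benefit_with_specificity <- function(params, scenario,
                                         healthy_population) {
  if (healthy_population < 0) stop("healthy_population must be non-negative")
  gain <- lifetime_gain(params, scenario)
  tp_years <- params$diagnosis_rate * gain
  fp_rate <- healthy_population * scenario$screens_per_person_year *
    scenario$false_positive_rate * (1 - scenario$confirmatory_specificity)
  fp_years <- fp_rate * scenario$fp_survival_reduction *
    params$cond_life_expectancy
  tp_years - fp_years
}
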