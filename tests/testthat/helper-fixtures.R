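# Shared fixtures, built in code.

# two-queue diagnosis/treatment validation network: eta1 = 120/yr,
# r12 = 0.4, service means 6 and 12 months => rho = (60, 48)
fig_two_queue <- function(svc1 = svc_exponential(6),
                          svc2 = svc_exponential(12)) {
  build_two_queue_network(120, 0.4, svc1, svc2)
}

# three-state screening subgroup: 2-year early sojourn, late survival
# 12 months, conditional life expectancy 80/3 years so that
# 75% effectiveness gives exactly 20 years of early-treated survival
example_params <- function() {
  subgroup_params(diagnosis_rate = 100, mean_early_sojourn = 24,
                  death_frac = 0.1, screen_frac = 0.3, progress_frac = 0.6,
                  mean_late_survival = 12, cond_life_expectancy = 80 / 3)
}

example_scenario <- function(detection = 1, effectiveness = 0.75, ...) {
  screening_scenario(detection = detection, effectiveness = effectiveness,
                     ...)
}

# random valid routing matrix: row sums strictly below 1
random_routing <- function(J, rng_scale = 0.8) {
  R <- matrix(stats::runif(J * J), J, J)
  R <- R / rowSums(R) * stats::runif(J, 0.1, rng_scale)
  R
}

random_network <- function(J) {
  queue_network(random_routing(J), stats::runif(J, 0.5, 5),
                lapply(stats::runif(J, 1, 20), svc_exponential))
}

# single-subgroup synthetic registry spec at the documented truth
default_synth_subgroups <- function() {
  data.frame(cancer_type = "Pancreas", sex = "Female",
             ancestry = "Caucasian", age_band = "60-64",
             eta1 = 200, treated_fraction = 0.4,
             stringsAsFactors = FALSE)
}

default_key <- function() {
  subgroup_key("Pancreas", "Female", "Caucasian", "60-64")
}

default_life_table <- function() generate_life_table()

# exhaustive-search oracle over all feasible integer allocations,
# honouring the worthwhileness threshold (score must strictly exceed T)
brute_force_allocation <- function(scores, budget, threshold) {
  eligible <- scores$score > threshold
  caps <- ifelse(eligible, scores$size, 0)
  grid <- do.call(expand.grid, lapply(caps, function(k) 0:k))
  feasible <- rowSums(grid) <= budget
  benefits <- as.matrix(grid[feasible, , drop = FALSE]) %*% scores$score
  max(benefits)
}
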