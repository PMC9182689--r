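test_that("censoring imputation follows the conditional empirical rule", {
  # no censoring: identity
  x <- impute_censored(c(5, 9, 30), c(TRUE, TRUE, TRUE))
  expect_equal(as.numeric(x), c(5, 9, 30))
  # deaths at 10/20/30, censored at 15 -> 15 + mean(20-15, 30-15) = 25
  x <- impute_censored(c(10, 20, 30, 15), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(as.numeric(x), c(10, 20, 30, 25))
  # censoring at 0: conditioning is vacuous, impute the mean of deaths
  x <- impute_censored(c(12, 24, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.numeric(x)[3:4], c(18, 18))
})

test_that("imputation never decreases a censored time; tail censoring flagged", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 60
    months <- round(rexp(n, 1 / 12), 2)
    dead <- runif(n) < 0.7
    out <- suppressWarnings(impute_censored(months, dead))
    expect_true(all(out >= months - 1e-12))
    expect_equal(out[dead], months[dead])
  }
  # censored beyond every observed death: left unchanged, flagged
  expect_warning(
    out <- impute_censored(c(10, 20, 99), c(TRUE, TRUE, FALSE)),
    "exceed")
  expect_equal(as.numeric(out), c(10, 20, 99))
  expect_equal(attr(out, "fallback"), 3L)
})

test_that("life-expectancy lookup is piecewise constant with a bump at 65", {
  lt <- generate_life_table(expectancies = c("<=64" = 20, "65-74" = 22,
                                             "75+" = 8))
  l64 <- conditional_life_expectancy(lt, "Caucasian", "Female", 64)
  l65 <- conditional_life_expectancy(lt, "Caucasian", "Female", 65)
  expect_equal(l64, 20)
  expect_equal(l65, 22)
  expect_gt(l65, l64)  # the discretisation bump across the boundary
  # constant within a band
  expect_equal(conditional_life_expectancy(lt, "Hispanic", "Male", 30),
               conditional_life_expectancy(lt, "Hispanic", "Male", 60))
  # a flat table has no bump anywhere
  flat <- generate_life_table(expectancies = c("<=64" = 15, "65-74" = 15,
                                               "75+" = 15))
  expect_equal(conditional_life_expectancy(flat, "Caucasian", "Male", 64),
               conditional_life_expectancy(flat, "Caucasian", "Male", 75))
  expect_error(conditional_life_expectancy(lt, "Unknown", "Female", 50),
               "no entry")
})

test_that("subgroup estimates recover synthetic truth within 5%", {
  reg <- generate_registry(synth_spec(default_synth_subgroups()), seed = 1)
  est <- estimate_subgroup_params(reg, default_key(), default_life_table())
  expect_lt(abs(est$diagnosis_rate - 200) / 200, 0.05)
  expect_lt(abs(est$treated_fraction - 0.4) / 0.4, 0.05)
  expect_lt(abs(est$mean_treated_survival - 13.5) / 13.5, 0.05)
  expect_equal(est$n_records, nrow(reg))
  expect_equal(est$cond_life_expectancy, 30)  # <=64 band of the default table
})

test_that("an all-treated registry estimates f = 1 exactly", {
  sg <- default_synth_subgroups()
  sg$treated_fraction <- 1
  # cutoff far beyond the window: no censoring, so the flag is exact
  reg <- generate_registry(synth_spec(sg, cutoff_year = 2100), seed = 3)
  est <- estimate_subgroup_params(reg, default_key(), default_life_table())
  expect_equal(est$treated_fraction, 1)
})

test_that("undersized subgroups are excluded with a structured error", {
  sg <- default_synth_subgroups()
  sg$eta1 <- 3  # ~51 records over 17 years
  reg <- generate_registry(synth_spec(sg), seed = 2)
  expect_lt(nrow(reg), 100)
  expect_error(
    estimate_subgroup_params(reg, default_key(), default_life_table()),
    "excluded: insufficient sample")
})

test_that("estimation is deterministic and invariant to record order", {
  reg <- generate_registry(synth_spec(default_synth_subgroups()), seed = 8)
  a <- estimate_subgroup_params(reg, default_key(), default_life_table())
  b <- estimate_subgroup_params(reg, default_key(), default_life_table())
  set.seed(123)
  shuffled <- reg[sample(nrow(reg)), ]
  c <- estimate_subgroup_params(shuffled, default_key(), default_life_table())
  expect_equal(a$diagnosis_rate, b$diagnosis_rate)
  expect_equal(a$diagnosis_rate, c$diagnosis_rate)
  expect_equal(a$mean_late_survival, c$mean_late_survival)
  expect_equal(a$treated_fraction, c$treated_fraction)
})

test_that("75+ subgroups carry the incidence-approximation warning", {
  sg <- default_synth_subgroups()
  sg$age_band <- "75-79"
  reg <- generate_registry(synth_spec(sg), seed = 4)
  key <- subgroup_key("Pancreas", "Female", "Caucasian", "75-79")
  expect_warning(
    estimate_subgroup_params(reg, key, default_life_table()),
    "75\\+")
})
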