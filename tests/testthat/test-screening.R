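test_that("zero detection collapses to the no-screening counterfactual", {
  p <- example_params()
  a <- build_screening_network(p, example_scenario(detection = 0))
  b <- build_no_screening_network(p)
  expect_equal(a$routing, b$routing)
  expect_equal(a$exogenous_rates, b$exogenous_rates)
  expect_equal(solve_traffic(a)$rho, solve_traffic(b)$rho)
  expect_equal(expected_sojourn(a), expected_sojourn(b))
  # nothing to screen: r12 = 0 makes the two constructions identical too
  p0 <- subgroup_params(100, 24, 0.1, 0, 0.9, 12, 80 / 3)
  expect_equal(solve_traffic(build_screening_network(p0, example_scenario()))$rho,
               solve_traffic(build_no_screening_network(p0))$rho)
})

test_that("full detection routes the screened fraction to early treatment", {
  p <- example_params()
  net <- build_screening_network(p, example_scenario(detection = 1))
  expect_equal(net$routing[1, ], c(0, 0.3, 0.6))
  expect_equal(exit_probabilities(net$routing)[1], 0.1)
  # hand-solved traffic: lambda = eta1 * (1, r12 d, r13 + r12(1-d))
  ts <- solve_traffic(net)
  expect_equal(ts$lambda * 12, c(100, 30, 60), tolerance = 1e-9)
  expect_identical(validate_network(net), character(0))
})

test_that("no-screening network has an empty early-treatment queue", {
  p <- example_params()
  net <- build_no_screening_network(p)
  expect_equal(solve_traffic(net)$rho[2], 0)
  expect_equal(expected_sojourn(net), 24 + 0.9 * 12, tolerance = 1e-12)
})

test_that("lifetime gain matches the closed form r12 d (eL - 1/mu3)", {
  p <- example_params()
  expect_equal(lifetime_gain(p, example_scenario(detection = 1)),
               0.3 * (20 - 1), tolerance = 1e-9)
  expect_equal(lifetime_gain(p, example_scenario(detection = 0)), 0)
  # early-treated survival equal to the late path: no gain
  even <- screening_scenario(detection = 1, effectiveness = 1 / (80 / 3))
  expect_equal(lifetime_gain(p, even), 0, tolerance = 1e-9)
  # per positive case detected: divide by the routing probability r12 d
  expect_equal(lifetime_gain(p, example_scenario(detection = 0.5),
                             per_positive = TRUE),
               (20 - 1), tolerance = 1e-9)
})

test_that("gain is monotone in detection and effectiveness, linear in e", {
  p <- example_params()
  ds <- seq(0, 1, length.out = 5)
  es <- seq(0.2, 1, length.out = 5)
  g <- outer(ds, es, Vectorize(function(d, e) {
    lifetime_gain(p, screening_scenario(detection = d, effectiveness = e))
  }))
  expect_true(all(diff(g) >= -1e-12))        # along d
  expect_true(all(t(diff(t(g))) >= -1e-12))  # along e
  # exact linearity in e at fixed d
  for (i in seq_along(ds)[-1]) {
    fit <- lm(g[i, ] ~ es)
    expect_lt(max(abs(residuals(fit))), 1e-9)
  }
})

test_that("per-screen benefit scales with the standing pool over population", {
  p <- example_params()  # rho1 = (100/12) * 24 = 200 undetected cases
  expect_equal(per_screen_benefit(10, p, 1e6),
               10 * 365 * 200 / 1e6, tolerance = 1e-12)
  expect_equal(per_screen_benefit(0, p, 1e4), 0)
  expect_equal(per_screen_benefit(10, p, 2e6),
               per_screen_benefit(10, p, 1e6) / 2)
  expect_error(per_screen_benefit(10, p, 0), "population")
})

test_that("per-screen and per-patient rankings can disagree", {
  # subgroup A: large per-patient gain, tiny standing pool in a huge
  # population; subgroup B: modest gain, high prevalence pool
  pA <- subgroup_params(10, 24, 0.1, 0.3, 0.6, 12, 80 / 3)
  pB <- subgroup_params(500, 24, 0.1, 0.3, 0.6, 12, 40 / 3)
  sc <- example_scenario()
  gA <- lifetime_gain(pA, sc); gB <- lifetime_gain(pB, sc)
  expect_gt(gA, gB)  # per patient: A wins
  bA <- per_screen_benefit(gA, pA, 1e6)
  bB <- per_screen_benefit(gB, pB, 1e6)
  expect_gt(bB, bA)  # per screen: B wins
})

test_that("morbidity reweights only the affected portion of the sojourn", {
  expect_equal(apply_morbidity(10, 1), 10)
  expect_equal(apply_morbidity(10, 0, affected_fraction = 1), 0)
  expect_equal(apply_morbidity(10, 0.8, affected_fraction = 0.2), 9.6)
  expect_error(apply_morbidity(10, 1.2))
  expect_error(apply_morbidity(10, 0.5, affected_fraction = 2))
})

test_that("treatment mortality mixes a point mass at one month", {
  base <- svc_exponential(120)
  expect_identical(apply_mortality(base, 0), base)
  expect_equal(apply_mortality(base, 1)$mean, 1)
  mixed <- apply_mortality(base, 0.1)
  expect_equal(mixed$mean, 0.1 * 1 + 0.9 * 120, tolerance = 1e-12)
  expect_identical(mixed$family, "mixture")
  # mortality lowers the modeled gain monotonically
  p <- example_params()
  gains <- vapply(c(0, 0.2, 0.5), function(mp) {
    lifetime_gain(p, example_scenario(mortality_prob = mp))
  }, numeric(1))
  expect_true(all(diff(gains) < 0))
})

test_that("specificity extension nets out false-positive losses", {
  p <- example_params()
  sc_clean <- example_scenario(false_positive_rate = 0,
                               confirmatory_specificity = 0.9,
                               fp_survival_reduction = 0.5)
  expect_equal(net_benefit_with_specificity(p, sc_clean, 1e6),
               p$diagnosis_rate * lifetime_gain(p, sc_clean))
  sc_harmless <- example_scenario(false_positive_rate = 0.05,
                                  confirmatory_specificity = 0.9,
                                  fp_survival_reduction = 0)
  expect_equal(net_benefit_with_specificity(p, sc_harmless, 1e6),
               p$diagnosis_rate * lifetime_gain(p, sc_harmless))
  # agent-level bookkeeping oracle on a concrete harmful instance
  sc_fp <- example_scenario(false_positive_rate = 0.01,
                            confirmatory_specificity = 0.5,
                            fp_survival_reduction = 0.3)
  healthy <- 1e6
  fp_count <- healthy * 1 * 0.01 * (1 - 0.5)
  oracle <- p$diagnosis_rate * lifetime_gain(p, sc_fp) -
    fp_count * 0.3 * p$cond_life_expectancy
  got <- net_benefit_with_specificity(p, sc_fp, healthy)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(got, 0)  # overtreatment outweighs the benefit here
  expect_error(net_benefit_with_specificity(p, sc_fp, -1))
})

test_that("constructed networks always validate with positive means", {
  set.seed(5)
  for (rep in 1:15) {
    p <- subgroup_params(runif(1, 10, 500), runif(1, 6, 60),
                         0.1, 0.3, 0.6, runif(1, 3, 36),
                         runif(1, 5, 40))
    sc <- screening_scenario(detection = runif(1), effectiveness = runif(1, .1, 1))
    for (net in list(build_screening_network(p, sc),
                     build_no_screening_network(p))) {
      expect_identical(validate_network(net), character(0))
      expect_true(all(vapply(net$services, function(s) s$mean, numeric(1)) > 0))
    }
  }
})
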