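test_that("traffic equations reproduce the closed form of the two-queue model", {
  ts <- solve_traffic(fig_two_queue())
  # lambda = (eta1, r12 * eta1) in per-month units
  expect_equal(ts$lambda, c(10, 4), tolerance = 1e-12)
  expect_equal(ts$rho, c(60, 48), tolerance = 1e-12)

  single <- queue_network(matrix(0, 1, 1), 5, list(svc_exponential(3)))
  ts1 <- solve_traffic(single)
  expect_equal(ts1$lambda, 5)
  expect_equal(ts1$rho, 15)
})

test_that("direct solve agrees with fixed-point iteration on random networks", {
  set.seed(21)
  for (rep in 1:20) {
    net <- random_network(sample(2:6, 1))
    lam <- solve_traffic(net)$lambda
    # independent brute-force fixed point
    fp <- net$exogenous_rates
    for (k in 1:5000) fp <- net$exogenous_rates + drop(fp %*% net$routing)
    expect_equal(lam, fp, tolerance = 1e-8)
    resid <- lam - net$exogenous_rates - drop(lam %*% net$routing)
    expect_lt(sqrt(sum(resid^2)), 1e-9 * max(1, sqrt(sum(lam^2))))
  }
})

test_that("joint pmf matches term-by-term factorial evaluation", {
  model <- stationary_model(c(2, 3))
  # independent oracle: direct factorial form
  oracle <- function(rho, n) prod(exp(-rho) * rho^n / factorial(n))
  for (counts in list(c(0, 0), c(1, 2), c(5, 0), c(3, 7))) {
    expect_equal(joint_pmf(model, counts), oracle(c(2, 3), counts),
                 tolerance = 1e-12)
  }
  expect_equal(joint_pmf(stationary_model(c(0, 0)), c(0, 0)), 1)
  expect_equal(joint_pmf(stationary_model(1), 0), exp(-1))
  expect_error(joint_pmf(model, c(-1, 2)))
  expect_error(joint_pmf(model, c(1, 2, 3)))
})

test_that("marginal tails match an independent partial-sum evaluation", {
  oracle_tail <- function(rho, x) {
    1 - exp(-rho) * sum(rho^(0:floor(x)) / factorial(0:floor(x)))
  }
  for (rho in c(0.5, 1, 2.5, 10)) {
    model <- stationary_model(rho)
    for (x in c(0, 1, 4, 20, 3.7)) {
      expect_lt(abs(marginal_tail(model, 1, x) - oracle_tail(rho, x)),
                1e-12)
      # complement identity
      expect_equal(marginal_tail(model, 1, x) +
                     sum(marginal_pmf(model, 1, 0:floor(x))), 1,
                   tolerance = 1e-12)
    }
  }
  expect_equal(marginal_tail(stationary_model(1), 1, 0), 1 - exp(-1))
  expect_error(marginal_tail(stationary_model(1), 1, -1))
})

test_that("zero-load queues have a degenerate marginal, not an error", {
  model <- stationary_model(c(0, 2))
  expect_equal(marginal_pmf(model, 1, 0), 1)
  expect_equal(marginal_tail(model, 1, 0), 0)
  expect_equal(joint_pmf(model, c(0, 2)), dpois(2, 2))
})

test_that("expected sojourn follows Little's law", {
  single <- queue_network(matrix(0, 1, 1), 7, list(svc_exponential(3)))
  expect_equal(expected_sojourn(single), 3)

  # screening network with 2 yr early sojourn, then 30% to 20 yr of early
  # treatment and 60% to 1 yr late survival: 2 + 0.3*20 + 0.6*1 = 8.6 yr
  net <- build_screening_network(example_params(), example_scenario())
  expect_equal(expected_sojourn(net) / 12, 8.6, tolerance = 1e-9)

  # doubling all exogenous rates leaves the mean sojourn unchanged
  doubled <- queue_network(net$routing, 2 * net$exogenous_rates,
                           net$services)
  expect_equal(expected_sojourn(doubled), expected_sojourn(net),
               tolerance = 1e-12)

  no_arrive <- list(routing = matrix(0, 1, 1), exogenous_rates = 0,
                    services = list(svc_exponential(1)))
  expect_error(expected_sojourn(no_arrive), "no arrivals")
})

test_that("sojourn equals brute-force path enumeration on a small network", {
  # enumerate all exit paths of the 3-queue screening topology
  p <- example_params()
  sc <- example_scenario(detection = 0.8)
  net <- build_screening_network(p, sc)
  means <- vapply(net$services, function(s) s$mean, numeric(1))
  R <- net$routing
  r0 <- exit_probabilities(R)
  # feedforward: paths are 1->exit, 1->2->exit, 1->3->exit
  e_sojourn <- means[1] +
    R[1, 2] * (means[2] * r0[2]) +
    R[1, 3] * (means[3] * r0[3])
  expect_equal(expected_sojourn(net), e_sojourn, tolerance = 1e-12)
})

test_that("stationary results are insensitive to the service family", {
  fams <- list(svc_exponential(6), svc_lognormal_mean(6, 1.3),
               svc_deterministic(6), svc_uniform(0, 12))
  ref <- solve_traffic(fig_two_queue(fams[[1]], svc_exponential(12)))
  for (f in fams[-1]) {
    alt <- solve_traffic(fig_two_queue(f, svc_deterministic(12)))
    expect_equal(alt$lambda, ref$lambda)
    expect_equal(alt$rho, ref$rho)
  }
})

test_that("stationary summary table carries loads and sojourns", {
  s <- stationary_summary(fig_two_queue())
  expect_equal(s$rho, c(60, 48))
  expect_equal(attr(s, "sojourn_months"), 10.8)
  expect_equal(attr(s, "sojourn_years"), 0.9)
})
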