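# Kolmogorov-Smirnov distance between a sample of counts and Poisson(rate).
# Support is truncated where the reference CDF is within 1e-12 of 1;
# beyond that point both CDFs agree to the comparison tolerance.
ks_stat_poisson <- function(counts, rate) {
  upper <- max(counts, stats::qpois(1 - 1e-12, rate))
  support <- 0:upper
  emp_cdf <- cumsum(tabulate(counts + 1L, nbins = upper + 1L)) / length(counts)
  theo_cdf <- stats::ppois(support, rate)
  max(abs(emp_cdf - theo_cdf))
}

#' Are yearly arrival counts Poisson?
#'
#' Tests the Markovian-arrivals assumption: under a homogeneous Poisson
#' arrival process, the number of arrivals in disjoint year-long windows
#' is Poisson with mean rate x 1 year. The statistic is the KS distance
#' between the empirical distribution of yearly counts and the Poisson
#' reference. Because the reference is discrete and (by default) its
#' rate is estimated from the same counts, the p-value is computed
#' against a simulated null that re-estimates the rate in each
#' replicate; `simulate_null = FALSE` falls back to the asymptotic KS
#' distribution (conservative here).
#'
#' @param yearly_counts integer vector of arrival counts, one per year
#'   (at least 2).
#' @param rate Poisson rate per year; if NULL, estimated as the mean
#'   count.
#' @param n_null number of null replicates.
#' @param simulate_null logical.
#' @return list with `statistic`, `p_value`, `rate`, `n_years`.
#' @export
ks_poisson_counts <- function(yearly_counts, rate = NULL, n_null = 2000,
                              simulate_null = TRUE) {
  yearly_counts <- as.numeric(yearly_counts)
  if (length(yearly_counts) < 2) stop("need at least 2 years of counts")
  if (any(yearly_counts < 0)) stop("counts must be non-negative")
  estimated <- is.null(rate)
  if (estimated) rate <- mean(yearly_counts)
  if (rate <= 0) stop("rate must be positive")
  d <- ks_stat_poisson(yearly_counts, rate)
  n <- length(yearly_counts)
  if (simulate_null) {
    null_d <- vapply(seq_len(n_null), function(b) {
      x <- stats::rpois(n, rate)
      r <- if (estimated) mean(x) else rate
      if (r <= 0) r <- .Machine$double.eps
      ks_stat_poisson(x, r)
    }, numeric(1))
    p <- (1 + sum(null_d >= d - 1e-12)) / (n_null + 1)
  } else {
    p <- stats::ks.test(yearly_counts, "ppois", rate)$p.value
  }
  list(statistic = d, p_value = p, rate = rate, n_years = n)
}

#' Does an empirical queue-length distribution match Poisson(rho)?
#'
#' Compares the empirical stationary distribution of a queue length with
#' the product-form prediction Poisson(rho). Accepts either a raw
#' integer sample or one queue's entry from [empirical_stationary()].
#' P-values come from a simulated null (n samples from Poisson(rho) per
#' replicate) because the reference law is discrete.
#'
#' @param x integer sample of queue lengths, or a list with elements
#'   `counts`/`n` as produced by [empirical_stationary()].
#' @param rho predicted Poisson mean (>= 0).
#' @param n_null number of null replicates.
#' @return list with `statistic`, `p_value`, `rho`, `n`.
#' @export
ks_queue_length <- function(x, rho, n_null = 2000) {
  if (is.list(x)) x <- x$counts
  x <- as.numeric(x)
  if (!length(x)) stop("empty sample")
  if (rho < 0) stop("rho must be non-negative")
  if (rho == 0) {
    d <- if (all(x == 0)) 0 else max(abs(stats::ecdf(x)(0:max(x)) - 1))
    return(list(statistic = d, p_value = if (d == 0) 1 else
                  1 / (n_null + 1), rho = rho, n = length(x)))
  }
  d <- ks_stat_poisson(x, rho)
  n <- length(x)
  null_d <- vapply(seq_len(n_null), function(b) {
    ks_stat_poisson(stats::rpois(n, rho), rho)
  }, numeric(1))
  p <- (1 + sum(null_d >= d - 1e-12)) / (n_null + 1)
  list(statistic = d, p_value = p, rho = rho, n = n)
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the number of tests and capped at 1.
#'
#' @param p_values numeric vector in [0,1].
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0,1]")
  pmin(1, p_values * length(p_values))
}

#' Assemble a goodness-of-fit report
#'
#' One row per test with the statistic, raw p, Bonferroni-adjusted p
#' (adjusted across all rows in the report), and the decision at the
#' adjusted 5% level.
#'
#' @param tests named list of results from [ks_poisson_counts()] /
#'   [ks_queue_length()].
#' @param family character vector of test family labels
#'   ("arrival-Poissonness" or "queue-length"), recycled.
#' @param alpha significance level applied to adjusted p-values.
#' @return data.frame of class `gof_report`.
#' @export
gof_report <- function(tests, family = "queue-length", alpha = 0.05) {
  raw <- vapply(tests, function(t) t$p_value, numeric(1))
  adj <- bonferroni(raw)
  out <- data.frame(
    test = if (is.null(names(tests))) seq_along(tests) else names(tests),
    family = rep_len(family, length(tests)),
    statistic = vapply(tests, function(t) t$statistic, numeric(1)),
    p_raw = raw, p_adjusted = adj, reject = adj < alpha,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gof_report", "data.frame")
  out
}
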