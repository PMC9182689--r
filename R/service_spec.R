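#' Service-time specification for an infinite-server queue
#'
#' A `service_spec` describes the waiting-time distribution of one queue:
#' the time an agent spends in the corresponding disease state before its
#' next transition. Stationary results depend on the distribution only
#' through its mean (the insensitivity property), but the discrete-event
#' simulator draws from the full distribution. All times are in months.
#'
#' Supported families: `exponential` (param `mean`), `lognormal`
#' (`meanlog`, `sdlog`), `deterministic` (`value`), `uniform`
#' (`min`, `max`), `empirical` (`samples`, a vector of observed
#' durations), and `mixture` (`components`, a list of service_spec,
#' and `weights`).
#'
#' @param family distribution family name.
#' @param ... family-specific parameters (see Details).
#' @return an object of class `service_spec` with elements `family`,
#'   `params`, and `mean` (months).
#' @examples
#' svc_exponential(6)
#' svc_lognormal(meanlog = 1, sdlog = 1.3)
#' @export
service_spec <- function(family = c("exponential", "lognormal", "deterministic",
                                    "uniform", "empirical", "mixture"), ...) {
  family <- match.arg(family)
  params <- list(...)
  m <- switch(family,
    exponential = {
      stopifnot(is.numeric(params$mean), params$mean > 0)
      params$mean
    },
    lognormal = {
      stopifnot(is.numeric(params$meanlog), is.numeric(params$sdlog),
                params$sdlog >= 0)
      exp(params$meanlog + params$sdlog^2 / 2)
    },
    deterministic = {
      stopifnot(is.numeric(params$value), params$value > 0)
      params$value
    },
    uniform = {
      stopifnot(params$min >= 0, params$max >= params$min)
      (params$min + params$max) / 2
    },
    empirical = {
      s <- params$samples
      stopifnot(is.numeric(s), length(s) > 0, all(s >= 0))
      mean(s)
    },
    mixture = {
      comps <- params$components
      w <- params$weights
      stopifnot(length(comps) == length(w), all(w >= 0),
                abs(sum(w) - 1) < 1e-9)
      stopifnot(all(vapply(comps, inherits, logical(1), "service_spec")))
      sum(w * vapply(comps, function(c) c$mean, numeric(1)))
    })
  if (!is.finite(m) || m <= 0)
    stop("service mean must be finite and strictly positive")
  structure(list(family = family, params = params, mean = m),
            class = "service_spec")
}

#' @rdname service_spec
#' @param mean mean service time in months.
#' @export
svc_exponential <- function(mean) service_spec("exponential", mean = mean)

#' @rdname service_spec
#' @param meanlog,sdlog log-scale parameters.
#' @export
svc_lognormal <- function(meanlog, sdlog) {
  service_spec("lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' Lognormal service specification from its mean and coefficient of variation
#'
#' Convenience parameterisation: given the target mean (months) and cv,
#' solves for `meanlog` and `sdlog`.
#'
#' @param mean target mean, months.
#' @param cv coefficient of variation (sd/mean), > 0.
#' @return a `service_spec`.
#' @export
svc_lognormal_mean <- function(mean, cv) {
  stopifnot(mean > 0, cv > 0)
  sdlog <- sqrt(log(1 + cv^2))
  svc_lognormal(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' @rdname service_spec
#' @param value the fixed duration, months.
#' @export
svc_deterministic <- function(value) service_spec("deterministic", value = value)

#' @rdname service_spec
#' @param min,max uniform support bounds, months.
#' @export
svc_uniform <- function(min, max) service_spec("uniform", min = min, max = max)

#' @rdname service_spec
#' @param samples observed durations, months; the sample mean is used as 1/mu.
#' @export
svc_empirical <- function(samples) service_spec("empirical", samples = samples)

#' @rdname service_spec
#' @param components list of `service_spec` objects.
#' @param weights mixing weights, summing to 1.
#' @export
svc_mixture <- function(components, weights) {
  service_spec("mixture", components = components, weights = weights)
}

#' Draw service times from a specification
#'
#' Uses the current R random stream; callers control reproducibility with
#' `set.seed()`.
#'
#' @param spec a `service_spec`.
#' @param n number of draws.
#' @return numeric vector of n non-negative durations (months).
#' @export
service_draw <- function(spec, n) {
  stopifnot(inherits(spec, "service_spec"), n >= 0)
  if (n == 0) return(numeric(0))
  p <- spec$params
  switch(spec$family,
    exponential   = stats::rexp(n, rate = 1 / p$mean),
    lognormal     = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    deterministic = rep.int(p$value, n),
    uniform       = stats::runif(n, p$min, p$max),
    empirical     = sample(p$samples, n, replace = TRUE),
    mixture = {
      k <- sample.int(length(p$components), n, replace = TRUE,
                      prob = p$weights)
      out <- numeric(n)
      for (i in seq_along(p$components)) {
        idx <- which(k == i)
        if (length(idx)) out[idx] <- service_draw(p$components[[i]], length(idx))
      }
      out
    })
}

#' @export
print.service_spec <- function(x, ...) {
  cat(sprintf("<service_spec> %s, mean %.4g months\n", x$family, x$mean))
  invisible(x)
}
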