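#' Solve the traffic equations of an open queue network
#'
#' The aggregate arrival rate into each queue superposes exogenous and
#' internally rerouted arrivals: lambda = eta + lambda R (row vectors),
#' i.e. lambda = eta (I - R)^{-1}. Loads are rho_j = lambda_j / mu_j
#' (arrival rate times mean service).
#'
#' Solved by direct factorisation with a fixed-point fallback
#' (lambda <- eta + lambda R) if the factorisation is numerically
#' unreliable; residual tolerance 1e-9 relative.
#'
#' @param net a [queue_network()].
#' @return object of class `traffic_solution`: list with `lambda`
#'   (per month), `rho`, `labels`.
#' @examples
#' net <- queue_network(matrix(c(0, .4, 0, 0), 2, 2, byrow = TRUE),
#'                      c(10, 0), list(svc_exponential(6), svc_exponential(12)))
#' solve_traffic(net)
#' @export
solve_traffic <- function(net) {
  viol <- validate_network(net)
  if (length(viol))
    stop("invalid network: ", paste(viol, collapse = "; "))
  R <- net$routing
  eta <- net$exogenous_rates
  J <- nrow(R)
  lambda <- tryCatch(drop(eta %*% solve(diag(J) - R)),
                     error = function(e) NULL)
  if (is.null(lambda))
    stop("no stationary traffic solution: (I - R) is singular")
  resid <- sqrt(sum((lambda - eta - drop(lambda %*% R))^2))
  if (resid > 1e-9 * max(1, sqrt(sum(lambda^2)))) {
    # fixed-point fallback; converges because spectral radius of R < 1
    lambda <- eta
    for (k in seq_len(10000)) {
      nxt <- eta + drop(lambda %*% R)
      if (max(abs(nxt - lambda)) <= 1e-12 * max(1, max(abs(nxt)))) break
      lambda <- nxt
    }
    lambda <- nxt
  }
  lambda <- pmax(lambda, 0)
  means <- vapply(net$services, function(s) s$mean, numeric(1))
  structure(list(lambda = lambda, rho = lambda * means, labels = net$labels),
            class = "traffic_solution")
}

#' @export
print.traffic_solution <- function(x, ...) {
  cat("<traffic_solution>\n")
  print(data.frame(queue = x$labels, lambda_per_month = x$lambda,
                   rho = x$rho), row.names = FALSE)
  invisible(x)
}

#' Product-form stationary distribution of the network
#'
#' At equilibrium each infinite-server queue behaves as an independent
#' M/G/infinity queue: the joint stationary law is a product of
#' independent Poisson(rho_j) marginals, depending on the service
#' distributions only through their means (insensitivity).
#'
#' @param x a [queue_network()], a `traffic_solution`, or a numeric
#'   vector of loads rho.
#' @return object of class `stationary_model` with element `rho`.
#' @export
stationary_model <- function(x) {
  rho <- if (inherits(x, "queue_network")) solve_traffic(x)$rho
         else if (inherits(x, "traffic_solution")) x$rho
         else as.numeric(x)
  stopifnot(all(is.finite(rho)), all(rho >= 0))
  structure(list(rho = rho), class = "stationary_model")
}

#' @export
print.stationary_model <- function(x, ...) {
  cat("<stationary_model> independent Poisson marginals, rho =",
      paste(signif(x$rho, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Joint stationary probability mass
#'
#' P(N* = n) = prod_j exp(-rho_j) rho_j^{n_j} / n_j!, computed in log
#' space. A queue with rho_j = 0 contributes a degenerate mass at 0.
#'
#' @param model a `stationary_model`.
#' @param counts vector of non-negative integers, one per queue.
#' @return probability in [0,1].
#' @export
joint_pmf <- function(model, counts) {
  stopifnot(inherits(model, "stationary_model"))
  counts <- as.numeric(counts)
  if (length(counts) != length(model$rho))
    stop("counts length must equal the number of queues")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  exp(sum(stats::dpois(counts, model$rho, log = TRUE)))
}

#' Marginal stationary pmf of one queue
#'
#' @param model a `stationary_model`.
#' @param j queue index (1-based).
#' @param k vector of non-negative integers.
#' @return P(N_j* = k).
#' @export
marginal_pmf <- function(model, j, k) {
  stopifnot(inherits(model, "stationary_model"), j >= 1,
            j <= length(model$rho))
  stats::dpois(k, model$rho[j])
}

#' Exact marginal tail probability
#'
#' P(N_j* > x) = 1 - exp(-rho_j) sum_{k=0}^{floor(x)} rho_j^k / k!,
#' the exceedance probability of the stationary queue length -- e.g. the
#' chance of seeing more simultaneous cases than any planning threshold.
#' Computed via the exact partial sum in log space.
#'
#' @param model a `stationary_model`.
#' @param j queue index (1-based).
#' @param x non-negative threshold (need not be an integer).
#' @return probability in [0,1].
#' @export
marginal_tail <- function(model, j, x) {
  stopifnot(inherits(model, "stationary_model"), j >= 1,
            j <= length(model$rho))
  if (any(x < 0)) stop("threshold x must be non-negative")
  rho <- model$rho[j]
  vapply(x, function(xi) {
    ks <- 0:floor(xi)
    # log-space partial sum: log(sum exp(k log rho - rho - log k!))
    if (rho == 0) return(0)
    lt <- stats::dpois(ks, rho, log = TRUE)
    m <- max(lt)
    1 - exp(m + log(sum(exp(lt - m))))
  }, numeric(1))
}

#' Expected sojourn time via Little's law
#'
#' E(W*) = E(N*) / eta = (1/eta) sum_j rho_j, where eta is the total
#' exogenous arrival rate. Interpreted as expected residual lifetime when
#' exiting the network corresponds to death.
#'
#' @param net a [queue_network()].
#' @return mean time in network, months.
#' @export
expected_sojourn <- function(net) {
  eta <- sum(net$exogenous_rates)
  if (eta <= 0) stop("no arrivals: total exogenous rate is zero")
  sum(solve_traffic(net)$rho) / eta
}

#' Flat summary table of a network's stationary analysis
#'
#' @param net a [queue_network()].
#' @return data.frame with per-queue lambda, rho, mean service, plus
#'   attributes `sojourn_months` and `sojourn_years`.
#' @export
stationary_summary <- function(net) {
  ts <- solve_traffic(net)
  means <- vapply(net$services, function(s) s$mean, numeric(1))
  out <- data.frame(queue = net$labels, lambda_per_month = ts$lambda,
                    mean_service_months = means, rho = ts$rho)
  attr(out, "sojourn_months") <- expected_sojourn(net)
  attr(out, "sojourn_years") <- expected_sojourn(net) / 12
  out
}
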