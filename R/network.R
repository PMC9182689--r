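#' Open networks of infinite-server queues
#'
#' A `queue_network` couples a routing matrix R (r_ij = probability of
#' moving to queue j on leaving queue i; residual mass exits), a vector of
#' exogenous Poisson arrival rates eta (per month), and one
#' [service_spec()] per queue. Row-vector convention throughout: the
#' traffic equations read lambda = eta + lambda R.
#'
#' @param routing J x J numeric matrix of routing probabilities.
#' @param exogenous_rates length-J vector of non-negative arrival rates
#'   (per month).
#' @param services list of J [service_spec()] objects.
#' @param labels optional queue names.
#' @return an object of class `queue_network`.
#' @examples
#' net <- queue_network(
#'   routing = matrix(c(0, 0.4, 0, 0), 2, 2, byrow = TRUE),
#'   exogenous_rates = c(10, 0),
#'   services = list(svc_exponential(6), svc_exponential(12)))
#' validate_network(net)
#' @export
queue_network <- function(routing, exogenous_rates, services, labels = NULL) {
  routing <- as.matrix(routing)
  J <- nrow(routing)
  if (is.null(labels)) labels <- paste0("queue", seq_len(J))
  net <- structure(list(routing = routing,
                        exogenous_rates = as.numeric(exogenous_rates),
                        services = services, labels = labels),
                   class = "queue_network")
  viol <- validate_network(net)
  if (length(viol))
    stop("invalid queue network:\n  ", paste(viol, collapse = "\n  "))
  net
}

#' Structural validation of a queue network
#'
#' Checks every invariant and returns a character vector naming each
#' violation (with the offending queue index); an empty vector means the
#' network is valid. Validation never raises.
#'
#' @param net a list with elements routing, exogenous_rates, services.
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_network <- function(net) {
  viol <- character(0)
  R <- net$routing
  if (!is.matrix(R) || nrow(R) != ncol(R))
    return("routing matrix is not square")
  J <- nrow(R)
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1))
    viol <- c(viol, "routing entries must be probabilities in [0,1]")
  rs <- rowSums(R)
  bad <- which(rs > 1 + 1e-12)
  for (i in bad) viol <- c(viol, sprintf("row sum > 1 for queue %d", i))
  if (length(net$exogenous_rates) != J)
    viol <- c(viol, "exogenous_rates length differs from J")
  else {
    if (any(!is.finite(net$exogenous_rates) | net$exogenous_rates < 0))
      viol <- c(viol, "exogenous rates must be finite and non-negative")
    if (!any(net$exogenous_rates > 0))
      viol <- c(viol, "at least one exogenous rate must be positive")
  }
  if (length(net$services) != J)
    viol <- c(viol, "services length differs from J")
  else if (!all(vapply(net$services, inherits, logical(1), "service_spec")))
    viol <- c(viol, "services must all be service_spec objects")
  # every customer must eventually exit: (I - R) invertible with
  # non-negative inverse (equivalently spectral radius of R < 1)
  if (!length(viol) || all(rs <= 1 + 1e-12)) {
    IR <- diag(J) - R
    inv <- tryCatch(solve(IR), error = function(e) NULL)
    if (is.null(inv) ||
        max(abs(IR %*% inv - diag(J))) > 1e-10 ||
        any(inv < -1e-10)) {
      viol <- c(viol, "no exit path / (I - R) singular")
    }
  }
  viol
}

#' Exit probabilities of a routing matrix
#'
#' r_i0 = 1 - sum_j r_ij, the probability of leaving the network on
#' service completion at queue i. Together with the row of R this forms a
#' full stochastic routing kernel.
#'
#' @param routing J x J routing matrix.
#' @return numeric vector of exit probabilities in [0,1].
#' @export
exit_probabilities <- function(routing) {
  routing <- as.matrix(routing)
  rs <- rowSums(routing)
  bad <- which(rs > 1 + 1e-12 | apply(routing, 1, function(r) any(r < 0)))
  if (length(bad))
    stop(sprintf("invalid routing row(s): %s", paste(bad, collapse = ", ")))
  pmin(pmax(1 - rs, 0), 1)
}

#' @export
print.queue_network <- function(x, ...) {
  J <- nrow(x$routing)
  cat(sprintf("<queue_network> %d infinite-server queue(s)\n", J))
  means <- vapply(x$services, function(s) s$mean, numeric(1))
  df <- data.frame(queue = x$labels, eta = x$exogenous_rates,
                   mean_service_months = means,
                   exit_prob = exit_probabilities(x$routing))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read / write a queue network description file
#'
#' YAML key/value description with fields `labels`, `exogenous_rates`
#' (per month), `routing` (list of `[from, to, probability]` triples,
#' 1-based queue indices), and `services` (list of family + params).
#'
#' @param path file path.
#' @return `read_network`: a `queue_network`.
#' @export
read_network <- function(path) {
  cfg <- yaml::read_yaml(path)
  J <- length(cfg$services)
  R <- matrix(0, J, J)
  for (tr in cfg$routing) {
    R[tr[[1]], tr[[2]]] <- as.numeric(tr[[3]])
  }
  services <- lapply(cfg$services, build_service_from_list)
  queue_network(R, as.numeric(cfg$exogenous_rates), services,
                labels = cfg$labels)
}

build_service_from_list <- function(s) {
  p <- s$params
  if (identical(s$family, "mixture")) {
    p$components <- lapply(p$components, build_service_from_list)
    p$weights <- as.numeric(unlist(p$weights))
  }
  if (identical(s$family, "empirical"))
    p$samples <- as.numeric(unlist(p$samples))
  do.call(service_spec, c(list(family = s$family), p))
}

#' @rdname read_network
#' @param net a `queue_network`.
#' @export
write_network <- function(net, path) {
  idx <- which(net$routing > 0, arr.ind = TRUE)
  routing <- lapply(seq_len(nrow(idx)), function(k) {
    list(idx[k, 1], idx[k, 2], net$routing[idx[k, 1], idx[k, 2]])
  })
  services <- lapply(net$services, function(s) {
    list(family = s$family, params = s$params)
  })
  yaml::write_yaml(list(labels = net$labels,
                        exogenous_rates = net$exogenous_rates,
                        routing = routing, services = services), path)
  invisible(path)
}
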