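#' Discrete-event simulation of an infinite-server queue network
#'
#' Agent-path simulation: because all servers are infinite, agents never
#' interact, so each agent's full visit path and per-visit durations can
#' be drawn independently and superposed. Exogenous arrivals are
#' homogeneous Poisson at rates eta; on leaving queue i an agent moves to
#' queue j with probability r_ij or exits with probability r_i0.
#'
#' Reproducibility: one seeded stream, with draws made in a fixed order
#' (arrival counts, arrival times, then per-hop service and routing
#' batches), so identical seed and configuration give bit-identical
#' event logs.
#'
#' @param net a [queue_network()].
#' @param horizon simulated time span, months; arrivals occur on
#'   [0, horizon).
#' @param seed integer seed.
#' @return object of class `sim_result`: list with `visits` (vectors
#'   agent, queue, entry, exit), `arrival_time` and `sojourn` per agent,
#'   `horizon`, `seed`, and `net`.
#' @export
simulate_network <- function(net, horizon, seed = 1L) {
  viol <- validate_network(net)
  if (length(viol)) stop("invalid network: ", paste(viol, collapse = "; "))
  stopifnot(horizon > 0)
  means <- vapply(net$services, function(s) s$mean, numeric(1))
  if (horizon < 5 * max(means))
    warning("horizon shorter than the default burn-in (5 x largest mean service)")
  set.seed(seed)
  J <- nrow(net$routing)
  # exit-inclusive routing kernel, cumulative by row
  kern <- cbind(net$routing, exit_probabilities(net$routing))
  cum_kern <- t(apply(kern, 1, cumsum))

  n_arr <- stats::rpois(J, net$exogenous_rates * horizon)
  agent_q0 <- rep.int(seq_len(J), n_arr)
  n_agents <- sum(n_arr)
  arrival <- stats::runif(n_agents, 0, horizon)

  v_agent <- list(); v_queue <- list(); v_entry <- list(); v_exit <- list()
  active <- seq_len(n_agents)
  cur_q <- agent_q0
  cur_t <- arrival
  hop <- 0L
  while (length(active)) {
    hop <- hop + 1L
    if (hop > 10000L) stop("routing did not terminate (no exit path?)")
    dur <- numeric(length(active))
    for (q in unique(cur_q)) {
      idx <- which(cur_q == q)
      dur[idx] <- service_draw(net$services[[q]], length(idx))
    }
    leave <- cur_t + dur
    v_agent[[hop]] <- active
    v_queue[[hop]] <- cur_q
    v_entry[[hop]] <- cur_t
    v_exit[[hop]] <- leave
    u <- stats::runif(length(active))
    nxt <- integer(length(active))
    for (q in unique(cur_q)) {
      idx <- which(cur_q == q)
      nxt[idx] <- findInterval(u[idx], cum_kern[q, ], left.open = TRUE) + 1L
    }
    stay <- which(nxt <= J)
    active <- active[stay]
    cur_q <- nxt[stay]
    cur_t <- leave[stay]
  }
  visits <- list(agent = unlist(v_agent), queue = unlist(v_queue),
                 entry = unlist(v_entry), exit = unlist(v_exit))
  exit_time <- numeric(n_agents)
  # last exit per agent: visits are appended hop by hop, so later hops
  # overwrite earlier ones
  exit_time[visits$agent] <- visits$exit
  structure(list(visits = visits, arrival_time = arrival,
                 sojourn = exit_time - arrival, horizon = horizon,
                 seed = seed, J = J, labels = net$labels,
                 mean_services = means),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d agents, %d visits, horizon %.4g months, seed %d\n",
              length(x$sojourn), length(x$visits$agent), x$horizon, x$seed))
  invisible(x)
}

#' Empirical stationary distribution from queue-length samples
#'
#' Samples each queue's length at epochs burn_in, burn_in + spacing, ...
#' up to the horizon and tabulates the empirical pmf. Defaults follow
#' the decorrelation heuristics: burn-in 5x and spacing 1x the largest
#' mean service time.
#'
#' @param sim a `sim_result`.
#' @param burn_in months discarded at the start.
#' @param spacing months between samples.
#' @return object of class `empirical_stationary`: per-queue list with
#'   `counts` (integer samples), `pmf` (named numeric, sums to 1), and
#'   `n`.
#' @export
empirical_stationary <- function(sim,
                                 burn_in = 5 * max(sim$mean_services),
                                 spacing = max(sim$mean_services)) {
  stopifnot(inherits(sim, "sim_result"))
  if (sim$horizon - burn_in < 10 * spacing)
    stop("too few samples: horizon - burn_in must be at least 10 spacings")
  epochs <- seq(burn_in, sim$horizon, by = spacing)
  out <- vector("list", sim$J)
  for (q in seq_len(sim$J)) {
    in_q <- sim$visits$queue == q
    ent <- sort(sim$visits$entry[in_q])
    ext <- sort(sim$visits$exit[in_q])
    counts <- findInterval(epochs, ent) - findInterval(epochs, ext)
    pmf <- tabulate(counts + 1L, nbins = max(counts) + 1L) / length(counts)
    names(pmf) <- 0:max(counts)
    out[[q]] <- list(counts = counts, pmf = pmf, n = length(counts))
  }
  names(out) <- sim$labels
  structure(out, class = "empirical_stationary")
}

#' Total-variation distance between an empirical pmf and Poisson(rho)
#'
#' @param pmf named numeric pmf over counts (names = values).
#' @param rho Poisson mean.
#' @return TV distance in [0,1].
#' @export
tv_distance_poisson <- function(pmf, rho) {
  vals <- as.integer(names(pmf))
  upper <- max(vals, ceiling(10 * rho + 50))
  support <- 0:upper
  emp <- numeric(length(support))
  emp[vals + 1L] <- pmf
  theo <- stats::dpois(support, rho)
  (sum(abs(emp - theo)) + (1 - sum(theo))) / 2
}
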