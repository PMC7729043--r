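#' Metropolis acceptance rule
#'
#' A proposed change with stress difference `delta_h` is always accepted
#' when it does not increase stress (`delta_h <= 0`), and otherwise
#' accepted with probability `exp(-delta_h / temperature)`. Consumes one
#' uniform draw from R's RNG only when `delta_h > 0`.
#'
#' @param delta_h stress difference of the proposed change.
#' @param temperature social temperature, `> 0`.
#' @return `TRUE` if the change is accepted.
#' @export
metropolis_accept <- function(delta_h, temperature) {
  if (temperature <= 0) stop("`temperature` must be positive")
  if (delta_h <= 0) return(TRUE)
  runif(1) < exp(-delta_h / temperature)
}

#' One sweep of opinion updates
#'
#' Performs `round(rate * N)` single-opinion Metropolis attempts, each
#' on a uniformly random agent, leaving all links untouched. With
#' `rate * N < 1` a single attempt is made with that probability.
#'
#' @param net a fully signed [signed_network()].
#' @param params a [model_params()] object.
#' @return a list with the updated `net`, the number of `attempts` and
#'   of `accepted` flips.
#' @export
opinion_sweep <- function(net, params = model_params()) {
  params <- as_params(params)
  validate_network(net)
  nn <- params$rate * net$n_agents
  if (nn < 1) {
    if (runif(1) >= nn) {
      return(list(net = net, attempts = 0L, accepted = 0L))
    }
    nn <- 1
  }
  res <- cpp_opinion_sweep(net$n_agents, net$edges, net$signs,
                           net$opinions, params$g, params$temperature,
                           params$h, nn / net$n_agents)
  net$opinions <- res$opinions
  list(net = net, attempts = res$attempts, accepted = res$accepted)
}

#' One link update
#'
#' With probability `1 - p_rewire` a uniformly random existing link is
#' proposed for a sign flip; with probability `p_rewire` a compound
#' rewiring move is proposed instead (delete a uniformly random link,
#' create one between a uniformly random currently-unlinked pair, its
#' sign set by `rewiring_mode`). Either proposal is accepted by the
#' Metropolis rule on its exact stress difference; the link count is
#' conserved in all cases.
#'
#' @inheritParams opinion_sweep
#' @return a list with the updated `net`, the `move` type
#'   (`"flip"`/`"rewire"`) and whether it was `accepted`.
#' @export
link_update <- function(net, params = model_params()) {
  params <- as_params(params)
  validate_network(net)
  if (nrow(net$edges) == 0L) stop("network has no links")
  res <- cpp_link_update(net$n_agents, net$edges, net$signs, net$opinions,
                         params$g, params$temperature, params$h,
                         params$p_rewire,
                         params$rewiring_mode == "homophilious")
  net$edges <- res$edges
  net$signs <- res$signs
  list(net = net, move = res$move, accepted = res$accepted)
}

#' One coevolution time step
#'
#' A time step is one [opinion_sweep()] followed by one [link_update()]
#' (order reversed under `fast_links`, the regime where links update
#' before opinions). Agent count and link count are invariant.
#'
#' @inheritParams opinion_sweep
#' @param fast_links perform the link update before the opinion attempts.
#' @return a list with the updated `net`, the current `stress`, and the
#'   acceptance counts of the sub-moves.
#' @export
coevolve_step <- function(net, params = model_params(), fast_links = FALSE) {
  params <- as_params(params)
  validate_network(net)
  res <- cpp_step(net$n_agents, net$edges, net$signs, net$opinions,
                  params$g, params$temperature, params$h, params$rate,
                  params$p_rewire,
                  params$rewiring_mode == "homophilious", fast_links)
  net$edges <- res$edges
  net$signs <- res$signs
  net$opinions <- res$opinions
  list(net = net, stress = res$stress,
       accepted_opinions = res$accepted_opinions,
       link_accepted = res$link_accepted)
}

#' Run the coevolution to stationarity
#'
#' Iterates time steps until a windowed stationarity criterion fires or
#' `max_steps` is reached. The criterion partitions the step axis into
#' consecutive non-overlapping windows of `window` steps and declares
#' convergence at the first window whose mean stress differs from the
#' previous window's by less than `tol`, with a guard against slow
#' monotone drift (the mean must also lie within `2 * tol` of the
#' window before that). After convergence the run continues for one
#' further window over which the stationary observables are averaged;
#' censored runs (no convergence within `max_steps`) average over the
#' trailing window instead and report `tau = NA`.
#'
#' The convergence time `tau` is reported in units of `k N` time steps
#' (`k N` equals twice the link count), the natural scale on which the
#' whole network updates once.
#'
#' @inheritParams coevolve_step
#' @param max_steps maximum number of time steps; default `50 * k * N`.
#' @param window width of the stationarity window in steps; default
#'   `max(10, round(k * N / 10))`.
#' @param tol tolerance on the difference of consecutive window means
#'   of the stress.
#' @param record_every record the observables every this many steps.
#' @param check_convergence disable to run for exactly `max_steps`
#'   steps (used e.g. by fixed-schedule sweeps).
#' @param record_states for tiny systems (`N + E <= 30`), also return
#'   the integer-coded microstate after every step (used by exactness
#'   checks against the Boltzmann distribution).
#' @return an object of class `trajectory`: a list with `records` (data
#'   frame of `t`, `H`, `f`, `e_f`, `m`, `neg_frac`), `tau`,
#'   `converged`, `t_conv`, `net` (final state), `stationary` (named
#'   list of window-averaged `H`, `f`, `e_f`, `m`, `neg_frac`) and
#'   acceptance counters.
#' @export
run_to_stationarity <- function(net, params = model_params(),
                                max_steps = NULL, window = NULL,
                                tol = 0.5, record_every = NULL,
                                fast_links = FALSE,
                                check_convergence = TRUE,
                                record_states = FALSE) {
  params <- as_params(params)
  validate_network(net)
  kN <- 2L * nrow(net$edges)
  if (is.null(max_steps)) max_steps <- 50L * kN
  if (is.null(window)) window <- max(10L, round(kN / 10))
  if (is.null(record_every)) record_every <- max(1L, window %/% 10L)
  if (max_steps < 1) stop("`max_steps` must be at least 1")
  res <- cpp_run(net$n_agents, net$edges, net$signs, net$opinions,
                 params$g, params$temperature, params$h, params$rate,
                 params$p_rewire,
                 params$rewiring_mode == "homophilious",
                 as.integer(max_steps), as.integer(record_every),
                 as.integer(window), tol, fast_links, check_convergence,
                 record_states)
  net$edges <- res$edges
  net$signs <- res$signs
  net$opinions <- res$opinions
  out <- list(
    records = as.data.frame(res$records),
    tau = res$tau,
    converged = res$converged,
    t_conv = res$t_conv,
    t_final = res$t_final,
    net = net,
    stress = res$stress,
    stationary = list(H = res$stationary_H, f = res$stationary_f,
                      e_f = res$stationary_e_f, m = res$stationary_m,
                      neg_frac = res$stationary_neg_frac),
    accepted_opinions = res$accepted_opinions,
    accepted_links = res$accepted_links,
    window = window, tol = tol, kN = kN,
    params = params)
  if (record_states) out$state_codes <- res$state_codes
  structure(out, class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d steps recorded up to t = %d\n",
              nrow(x$records), as.integer(x$t_final)))
  if (isTRUE(x$converged)) {
    cat(sprintf("  converged at t = %d (tau = %.3f kN)\n",
                as.integer(x$t_conv), x$tau))
  } else {
    cat("  not converged (censored at max_steps)\n")
  }
  st <- x$stationary
  cat(sprintf("  stationary: H = %.2f, f = %s, e_f = %.3f, m = %.3f\n",
              st$H, ifelse(is.na(st$f), "NA", sprintf("%.3f", st$f)),
              st$e_f, st$m))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$records$t, x$records$H, type = "l", xlab = "t",
                 ylab = "H", ...)
  if (isTRUE(x$converged))
    graphics::abline(v = x$t_conv, lty = 2, col = "grey40")
  graphics::plot(x$records$t, x$records$f, type = "l", xlab = "t",
                 ylab = "f", ylim = c(-1, 1), ...)
  invisible(x)
}
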