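#' Four-agent worked example
#'
#' The complete graph on four agents with one hostile link and aligned
#' opinions: two of its four triangles are balanced and two unbalanced,
#' and its stress (`H = -4` at `g = 1`) sits well above the topology's
#' ground state `H = -10`. Running the dynamics at low temperature
#' relaxes it to a fully balanced state.
#'
#' @return a list with `name`, the `net` (a valid `signed_network`) and
#'   default `params` (`g = 1`, `T = 0.5`).
#' @export
fixture_k4 <- function() {
  net <- complete_network(4)
  # hostile link between agents 1 and 2; all opinions up
  net$signs <- ifelse(net$edges[, 1L] == 1L & net$edges[, 2L] == 2L,
                      -1L, 1L)
  net$opinions <- rep(1L, 4L)
  validate_network(net)
  list(name = "k4_one_hostile_link", net = net,
       params = model_params(g = 1, temperature = 0.5))
}

build_topology <- function(n_agents, k, epsilon) {
  if (epsilon > 0) small_world(n_agents, k, epsilon)
  else ring_lattice(n_agents, k)
}

run_one <- function(n_agents, k, epsilon, params, p_plus, p_up,
                    max_steps, window, tol, fast_links = FALSE,
                    check_convergence = TRUE) {
  net <- build_topology(n_agents, k, epsilon)
  net <- randomize_state(net, p_plus = p_plus, p_up = p_up)
  run_to_stationarity(net, params, max_steps = max_steps,
                      window = window, tol = tol,
                      fast_links = fast_links,
                      check_convergence = check_convergence)
}

#' Phase-diagram scan over connectivity and temperature
#'
#' For every grid cell `(k, T)` the driver builds the topology, draws a
#' random initial configuration, runs the coevolution to stationarity
#' and records the window-averaged order parameters, repeated over
#' `realizations` independent runs. The stationary balance index `f`
#' separates a fragmented phase (`f` near 1, high connectivity / low
#' temperature) from a coherent one (`f` near 0).
#'
#' @param k_values vector of mean degrees (even, `< n_agents`).
#' @param t_values vector of social temperatures.
#' @param n_agents number of agents.
#' @param params base [model_params()]; its `temperature` is replaced
#'   cell by cell.
#' @param epsilon small-world rewiring probability of the topology.
#' @param realizations independent runs per cell.
#' @param p_plus,p_up initial sign/opinion probabilities.
#' @param max_steps,window,tol stationarity controls (defaults as in
#'   [run_to_stationarity()], per cell).
#' @param seed integer seed for the whole scan (bit-reproducible).
#' @param keep_nets also return the final states (lists of
#'   `signed_network`, one per realization, per cell).
#' @return a data frame of class `scan_result` with one row per cell:
#'   `k`, `temperature`, `mean_f`, `se_f`, `mean_e_f`, `mean_m`,
#'   `mean_neg_frac`, `n_converged`, `realizations`; invalid cells
#'   (odd `k` or `k >= N`) carry `NA`s.
#' @export
phase_diagram_scan <- function(k_values, t_values, n_agents = 400,
                               params = model_params(), epsilon = 0,
                               realizations = 50, p_plus = 0.5,
                               p_up = 0.5, max_steps = NULL,
                               window = NULL, tol = 0.5, seed = NULL,
                               keep_nets = FALSE) {
  params <- as_params(params)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(k = k_values, temperature = t_values,
                      KEEP.OUT.ATTRS = FALSE)
  nets <- if (keep_nets) vector("list", nrow(grid)) else NULL
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    k <- grid$k[cell]
    tt <- grid$temperature[cell]
    if (k %% 2 != 0 || k >= n_agents) {
      warning(sprintf("cell (k=%g, T=%g) not constructible; skipped",
                      k, tt))
      return(data.frame(k = k, temperature = tt, mean_f = NA_real_,
                        se_f = NA_real_, mean_e_f = NA_real_,
                        mean_m = NA_real_, mean_neg_frac = NA_real_,
                        n_converged = NA_integer_, realizations = 0L))
    }
    pars <- params
    pars$temperature <- tt
    f <- ef <- m <- ng <- numeric(realizations)
    conv <- logical(realizations)
    finals <- if (keep_nets) vector("list", realizations) else NULL
    for (r in seq_len(realizations)) {
      traj <- run_one(n_agents, k, epsilon, pars, p_plus, p_up,
                      max_steps, window, tol)
      f[r] <- traj$stationary$f
      ef[r] <- traj$stationary$e_f
      m[r] <- traj$stationary$m
      ng[r] <- traj$stationary$neg_frac
      conv[r] <- traj$converged
      if (keep_nets) finals[[r]] <- traj$net
    }
    if (keep_nets) nets[[cell]] <<- finals
    data.frame(k = k, temperature = tt,
               mean_f = mean(f, na.rm = TRUE),
               se_f = sd(f, na.rm = TRUE) / sqrt(sum(!is.na(f))),
               mean_e_f = mean(ef), mean_m = mean(m),
               mean_neg_frac = mean(ng),
               n_converged = sum(conv), realizations = realizations)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", "data.frame")
  if (keep_nets) attr(out, "final_nets") <- nets
  out
}

#' Hysteresis sweep in temperature
#'
#' Sweeps the temperature upward along `t_values` and then back down,
#' carrying the final state of each temperature into the next as the
#' initial state. At each temperature the chain runs for a fixed
#' `steps_per_temp` schedule (default `5 k N` steps) and the balance
#' index is averaged over the trailing window. Separation of the two
#' branches (`f_up` above `f_down` in an interval) is the signature of
#' a first-order, discontinuous transition; it is pronounced at high
#' connectivity.
#'
#' @param t_values ascending temperature grid (the descending branch
#'   revisits it in reverse).
#' @param n_agents,params,epsilon,realizations,p_plus,p_up,seed as in
#'   [phase_diagram_scan()].
#' @param k mean degree.
#' @param steps_per_temp steps run at each temperature before
#'   measuring; default `5 k N`.
#' @param window trailing measurement window; default `k N / 10`.
#' @return a data frame of class `hysteresis_result` with one row per
#'   temperature: `temperature`, `f_up`, `se_up`, `f_down`, `se_down`.
#' @export
hysteresis_sweep <- function(t_values, k = 30, n_agents = 50,
                             params = model_params(), epsilon = 0,
                             realizations = 10, p_plus = 0.5,
                             p_up = 0.5, steps_per_temp = NULL,
                             window = NULL, seed = NULL) {
  params <- as_params(params)
  if (!is.null(seed)) set.seed(seed)
  t_values <- sort(t_values)
  kN <- k * n_agents
  if (is.null(steps_per_temp)) steps_per_temp <- 5L * kN
  if (is.null(window)) window <- max(10L, round(kN / 10))
  nt <- length(t_values)
  f_up <- matrix(NA_real_, realizations, nt)
  f_down <- matrix(NA_real_, realizations, nt)
  for (r in seq_len(realizations)) {
    net <- build_topology(n_agents, k, epsilon)
    net <- randomize_state(net, p_plus = p_plus, p_up = p_up)
    for (ti in seq_len(nt)) {
      pars <- params
      pars$temperature <- t_values[ti]
      traj <- run_to_stationarity(net, pars, max_steps = steps_per_temp,
                                  window = window,
                                  check_convergence = FALSE)
      net <- traj$net
      f_up[r, ti] <- traj$stationary$f
    }
    for (ti in rev(seq_len(nt))) {
      pars <- params
      pars$temperature <- t_values[ti]
      traj <- run_to_stationarity(net, pars, max_steps = steps_per_temp,
                                  window = window,
                                  check_convergence = FALSE)
      net <- traj$net
      f_down[r, ti] <- traj$stationary$f
    }
  }
  se <- function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  out <- data.frame(
    temperature = t_values,
    f_up = colMeans(f_up, na.rm = TRUE),
    se_up = apply(f_up, 2, se),
    f_down = colMeans(f_down, na.rm = TRUE),
    se_down = apply(f_down, 2, se))
  class(out) <- c("hysteresis_result", "data.frame")
  out
}

#' External-field scan
#'
#' Scans the exogenous pro-social field `h` against the temperature and
#' reports the stationary opinion alignment `m` and the fraction of
#' hostile links. Beyond a critical field, hostility is largely
#' eliminated and global consensus (`m` near 1) becomes the attractor.
#'
#' @param h_values field strengths.
#' @param t_values social temperatures.
#' @inheritParams phase_diagram_scan
#' @param k mean degree.
#' @return a data frame of class `scan_result` with one row per
#'   `(h, T)` cell: `h`, `temperature`, `mean_m`, `se_m`,
#'   `mean_neg_frac`, `mean_f`, `n_converged`, `realizations`.
#' @export
external_field_scan <- function(h_values, t_values, k = 10,
                                n_agents = 200, params = model_params(),
                                epsilon = 0, realizations = 20,
                                p_plus = 0.5, p_up = 0.5,
                                max_steps = NULL, window = NULL,
                                tol = 0.5, seed = NULL) {
  params <- as_params(params)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(h = h_values, temperature = t_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(cell) {
    pars <- params
    pars$h <- grid$h[cell]
    pars$temperature <- grid$temperature[cell]
    m <- ng <- f <- numeric(realizations)
    conv <- logical(realizations)
    for (r in seq_len(realizations)) {
      traj <- run_one(n_agents, k, epsilon, pars, p_plus, p_up,
                      max_steps, window, tol)
      m[r] <- traj$stationary$m
      ng[r] <- traj$stationary$neg_frac
      f[r] <- traj$stationary$f
      conv[r] <- traj$converged
    }
    data.frame(h = pars$h, temperature = pars$temperature,
               mean_m = mean(m),
               se_m = sd(m) / sqrt(realizations),
               mean_neg_frac = mean(ng),
               mean_f = mean(f, na.rm = TRUE),
               n_converged = sum(conv), realizations = realizations)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Convergence-time distribution
#'
#' Runs independent realizations from random initial conditions and
#' collects the convergence time `tau` of each (in `k N` time-step
#' units, as detected by the windowed stationarity criterion of
#' [run_to_stationarity()]). Runs that hit `max_steps` without
#' converging are reported as censored and excluded from the moments,
#' with a warning.
#'
#' @inheritParams phase_diagram_scan
#' @param k mean degree.
#' @return a list of class `tau_result` with `tau` (per-run values,
#'   `NA` when censored), `mean_tau`, `var_tau`, `n_censored` and the
#'   run settings.
#' @export
convergence_time_experiment <- function(realizations = 100, n_agents = 200,
                                        k = 10, params = model_params(),
                                        epsilon = 0, p_plus = 0.5,
                                        p_up = 0.5, max_steps = NULL,
                                        window = NULL, tol = 0.5,
                                        seed = NULL) {
  if (realizations < 2) stop("`realizations` must be at least 2")
  params <- as_params(params)
  if (!is.null(seed)) set.seed(seed)
  tau <- rep(NA_real_, realizations)
  for (r in seq_len(realizations)) {
    traj <- run_one(n_agents, k, epsilon, params, p_plus, p_up,
                    max_steps, window, tol)
    tau[r] <- traj$tau
  }
  n_cens <- sum(is.na(tau))
  if (n_cens > 0)
    warning(sprintf("%d of %d runs censored at max_steps", n_cens,
                    realizations))
  structure(list(tau = tau,
                 mean_tau = mean(tau, na.rm = TRUE),
                 var_tau = var(tau, na.rm = TRUE),
                 n_censored = n_cens,
                 realizations = realizations,
                 n_agents = n_agents, k = k, params = params),
            class = "tau_result")
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf(
    "<tau_result> %d runs (N=%d, k=%d, T=%g): mean tau = %.3f kN, var = %.3f (%d censored)\n",
    x$realizations, x$n_agents, x$k, x$params$temperature,
    x$mean_tau, x$var_tau, x$n_censored))
  invisible(x)
}
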