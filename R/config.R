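#' Run configuration files
#'
#' A single simulation run is fully described by a flat YAML (or JSON)
#' key-value file with keys
#' `N, k, epsilon, g, T, h, n, p, rewiring_mode, p_plus, p_up,
#' max_steps, record_every, window, tol, seed`; unknown keys error,
#' missing keys take the documented defaults.
#'
#' @param path path to a YAML/JSON config file.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads bare `N:`/`T:`-style keys as booleans; restore them
  names(cfg)[names(cfg) == "FALSE"] <- "N"
  names(cfg)[names(cfg) == "TRUE"] <- "T"
  defaults <- list(N = 100L, k = 8L, epsilon = 0, g = 1, T = 1, h = 0,
                   n = 1, p = 0, rewiring_mode = "random_sign",
                   p_plus = 0.5, p_up = 0.5, max_steps = NULL,
                   record_every = NULL, window = NULL, tol = 0.5,
                   seed = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Run a single simulation from a configuration
#'
#' Builds the topology, draws the initial configuration, runs the
#' coevolution to stationarity and (optionally) writes the trajectory
#' CSV (`t,H,f,e_f,m,neg_frac`), the final state as edge-list and
#' opinion CSVs, and a JSON metadata sidecar carrying the full
#' configuration, package version and seed for provenance.
#'
#' @param config a `run_config` list (see [read_run_config()]).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param prefix file-name prefix for outputs.
#' @return the [run_to_stationarity()] trajectory, invisibly when
#'   writing.
#' @export
run_simulation <- function(config, out_dir = NULL, prefix = "run") {
  if (!inherits(config, "run_config")) {
    class(config) <- "run_config"
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  params <- model_params(g = config$g, temperature = config$T,
                         h = config$h, rate = config$n,
                         p_rewire = config$p,
                         rewiring_mode = config$rewiring_mode)
  net <- build_topology(config$N, config$k, config$epsilon)
  net <- randomize_state(net, p_plus = config$p_plus, p_up = config$p_up)
  traj <- run_to_stationarity(net, params, max_steps = config$max_steps,
                              window = config$window, tol = config$tol,
                              record_every = config$record_every)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(traj$records,
              file.path(out_dir, paste0(prefix, "_trajectory.csv")),
              row.names = FALSE, quote = FALSE)
    write_edge_list(traj$net,
                    file.path(out_dir, paste0(prefix, "_edges.csv")))
    write_opinions(traj$net,
                   file.path(out_dir, paste0(prefix, "_opinions.csv")))
    sidecar <- list(
      config = unclass(config),
      package = "socialbalance",
      version = as.character(utils::packageVersion("socialbalance")),
      converged = traj$converged,
      tau = traj$tau,
      stationary = traj$stationary)
    jsonlite::write_json(sidecar,
                         file.path(out_dir, paste0(prefix, "_meta.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    return(invisible(traj))
  }
  traj
}
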