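#' Model parameters
#'
#' Bundles the Hamiltonian and dynamics parameters:
#' \describe{
#'   \item{g}{strength of the triadic balance term relative to the
#'     homophily term (non-negative; `g = 1` throughout the reference
#'     experiments).}
#'   \item{temperature}{social temperature `T > 0` of the Metropolis
#'     acceptance rule; higher `T` means more stress-increasing changes
#'     are accepted.}
#'   \item{h}{exogenous pro-social field (non-negative); adds
#'     `(h/2) * sum(1 - J_ij)` to the stress, penalizing hostile links.}
#'   \item{rate}{relative opinion/link update rate `n`: each time step
#'     performs `round(n * N)` opinion attempts followed by one link
#'     attempt. Fractional `n * N < 1` performs a single opinion attempt
#'     with probability `n * N` (fast-link regime).}
#'   \item{p_rewire}{probability that a link update proposes a rewiring
#'     move (break a random link, create one elsewhere) instead of a
#'     sign flip.}
#'   \item{rewiring_mode}{sign rule for newly created links:
#'     `"random_sign"` draws +1/-1 equiprobably, `"homophilious"` sets
#'     +1 between like-minded agents and -1 otherwise.}
#' }
#'
#' @param g balance-term strength, `g >= 0`.
#' @param temperature social temperature, `> 0`.
#' @param h external pro-social field, `>= 0`.
#' @param rate relative opinion update rate `n`, `> 0`.
#' @param p_rewire rewiring probability in \[0, 1\].
#' @param rewiring_mode `"random_sign"` or `"homophilious"`.
#' @return an object of class `model_params`.
#' @export
model_params <- function(g = 1, temperature = 1, h = 0, rate = 1,
                         p_rewire = 0,
                         rewiring_mode = c("random_sign", "homophilious")) {
  rewiring_mode <- match.arg(rewiring_mode)
  if (g < 0) stop("`g` must be non-negative")
  if (temperature <= 0) stop("`temperature` must be positive")
  if (h < 0) stop("`h` must be non-negative")
  if (rate <= 0) stop("`rate` must be positive")
  if (p_rewire < 0 || p_rewire > 1) stop("`p_rewire` must be in [0, 1]")
  structure(list(g = g, temperature = temperature, h = h, rate = rate,
                 p_rewire = p_rewire, rewiring_mode = rewiring_mode),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> g=%g T=%g h=%g n=%g p_rewire=%g mode=%s\n",
    x$g, x$temperature, x$h, x$rate, x$p_rewire, x$rewiring_mode))
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "model_params")) return(params)
  do.call(model_params, as.list(params))
}

#' Social stress (Hamiltonian) of a configuration
#'
#' Evaluates
#' `H = - sum_(i,j) J_ij s_i s_j - g sum_(i,j,k) J_ij J_jk J_ki
#'      + (h/2) sum_(i,j) (1 - J_ij)`,
#' where the pair sums visit each linked pair once and the triangle sum
#' each closed triangle once. Lower `H` means less social tension: the
#' first term rewards agreement between friends, the second rewards
#' Heider-balanced triads, the third penalizes hostile links.
#'
#' @param net a fully signed [signed_network()].
#' @param params a [model_params()] object (only `g` and `h` are used).
#' @return the scalar stress `H`.
#' @examples
#' k4 <- randomize_state(complete_network(4), p_plus = 1, p_up = 1)
#' total_stress(k4, model_params(g = 1))  # -10, the K4 ground state
#' @export
total_stress <- function(net, params = model_params()) {
  params <- as_params(params)
  validate_network(net)
  cpp_total_stress(net$n_agents, net$edges, net$signs, net$opinions,
                   params$g, params$h)
}

#' Ground-state stress of a topology
#'
#' For `g, h >= 0` the all-positive, all-aligned configuration
#' simultaneously minimizes every edge term, every triangle term and the
#' field term, so the exact global minimum of `H` on a fixed topology is
#' `-(E + g * n_triangles)` with `E` the link count. This value
#' normalizes the relative stress [relative_stress()].
#'
#' @param net a `signed_network` (signs may be unset; only the topology
#'   matters).
#' @param params a [model_params()] object.
#' @return the scalar ground-state stress.
#' @export
ground_state_stress <- function(net, params = model_params()) {
  params <- as_params(params)
  m <- nrow(net$edges)
  if (m == 0L) stop("network has no links")
  cen <- cpp_triangle_census(net$n_agents, net$edges,
                             rep(1L, m))
  -(m + params$g * sum(cen))
}

#' Stress change of a single opinion flip
#'
#' Incremental evaluation of `delta H` for flipping agent `i`'s opinion,
#' using only the links incident to `i` (the triangle and field terms do
#' not involve opinions). Equals the difference of full [total_stress()]
#' evaluations exactly.
#'
#' @inheritParams total_stress
#' @param i agent index (1-based).
#' @return the scalar stress change.
#' @export
delta_stress_opinion_flip <- function(net, params = model_params(), i) {
  params <- as_params(params)
  validate_network(net)
  cpp_delta_opinion(net$n_agents, net$edges, net$signs, net$opinions,
                    params$g, params$h, as.integer(i))
}

#' Stress change of a single link-sign flip
#'
#' Incremental `delta H` for flipping `J_ij`, using the opinions of the
#' endpoints, the signs of links to common neighbours (the triangles
#' through the link), and the field term. Equals the difference of full
#' [total_stress()] evaluations exactly. Errors if `(i, j)` is unlinked.
#'
#' @inheritParams total_stress
#' @param i,j endpoints of an existing link (1-based).
#' @return the scalar stress change.
#' @export
delta_stress_link_flip <- function(net, params = model_params(), i, j) {
  params <- as_params(params)
  validate_network(net)
  cpp_delta_link(net$n_agents, net$edges, net$signs, net$opinions,
                 params$g, params$h, as.integer(i), as.integer(j))
}

#' Exhaustive enumeration of all configurations on a small topology
#'
#' Evaluates `H` for every one of the `2^N * 2^E` assignments of
#' opinions and link signs of a fixed topology, and reports the global
#' minimum together with all minimizing configurations and their
#' triangle census. Feasible for `N + E <= 20` (the complete four-agent
#' graph has `2^10 = 1024` configurations); used as the brute-force
#' oracle behind ground-state and observable checks.
#'
#' @inheritParams ground_state_stress
#' @return a list with `min_stress`, `n_minima`, and a data frame
#'   `minima` holding one row per minimizing configuration with columns
#'   `n_plus`, `n_minus` (balanced/unbalanced triangles) plus the
#'   encoded configuration.
#' @export
exhaustive_minimum <- function(net, params = model_params()) {
  params <- as_params(params)
  n <- net$n_agents
  m <- nrow(net$edges)
  if (n + m > 20L) stop("exhaustive enumeration limited to N + E <= 20")
  sgrid <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  jgrid <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), m)))
  best <- Inf
  rows <- list()
  for (a in seq_len(nrow(jgrid))) {
    signs <- jgrid[a, ]
    for (b in seq_len(nrow(sgrid))) {
      H <- cpp_total_stress(n, net$edges, signs, sgrid[b, ],
                            params$g, params$h)
      if (H < best - 1e-9) {
        best <- H
        rows <- list(list(signs = signs, opinions = sgrid[b, ]))
      } else if (abs(H - best) <= 1e-9) {
        rows[[length(rows) + 1L]] <- list(signs = signs,
                                          opinions = sgrid[b, ])
      }
    }
  }
  census <- t(vapply(rows, function(r)
    cpp_triangle_census(n, net$edges, r$signs), numeric(2)))
  minima <- data.frame(
    n_plus = census[, 1L], n_minus = census[, 2L],
    signs = vapply(rows, function(r) paste(r$signs, collapse = ","), ""),
    opinions = vapply(rows, function(r) paste(r$opinions, collapse = ","),
                      ""))
  list(min_stress = best, n_minima = length(rows), minima = minima)
}
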