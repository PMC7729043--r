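#' Construct a signed opinion network
#'
#' The microstate of the model: `n` agents holding binary opinions
#' `s_i` in \{-1, +1\}, connected by undirected links with signs
#' `J_ij` in \{-1, +1\} (friendly / hostile). Unlinked pairs carry
#' `J_ij = 0` implicitly and are simply absent from the edge list.
#' Freshly built topologies may leave signs and opinions unset (`NA`)
#' until [randomize_state()] or explicit assignment fills them in.
#'
#' @param edges two-column integer matrix of undirected links, one row per
#'   linked pair, 1-based agent indices. Each pair must appear exactly once.
#' @param n_agents number of agents `N`; defaults to the largest index seen.
#' @param signs integer vector of link signs (`-1`/`+1`), parallel to the
#'   rows of `edges`, or `NA` for an unsigned topology.
#' @param opinions integer vector of length `n_agents` with entries
#'   `-1`/`+1`, or `NA` for unset opinions.
#' @return an object of class `signed_network` with fields `n_agents`,
#'   `edges`, `signs`, `opinions`.
#' @examples
#' net <- signed_network(rbind(c(1, 2), c(2, 3), c(1, 3)),
#'                       signs = c(1, 1, -1), opinions = c(1, 1, -1))
#' triangle_census(net)
#' @export
signed_network <- function(edges, n_agents = NULL, signs = NA,
                           opinions = NA) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), ncol = 2L)
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  if (is.null(n_agents)) n_agents <- max(edges, 0L)
  n_agents <- as.integer(n_agents)
  if (n_agents < 1L) stop("`n_agents` must be positive")
  if (length(signs) == 1L && is.na(signs)) {
    signs <- rep(NA_integer_, nrow(edges))
  }
  if (length(opinions) == 1L && is.na(opinions)) {
    opinions <- rep(NA_integer_, n_agents)
  }
  net <- structure(
    list(n_agents = n_agents, edges = edges,
         signs = as.integer(signs), opinions = as.integer(opinions)),
    class = "signed_network")
  validate_network(net, signed = FALSE)
  net
}

#' Validate the structural invariants of a signed network
#'
#' Checks that there are no self-links, that every linked pair is stored
#' exactly once, that indices are in range, and (when `signed = TRUE`)
#' that every link sign is exactly -1 or +1 and every opinion is -1 or +1.
#'
#' @param net a [signed_network()] object.
#' @param signed require signs and opinions to be fully assigned.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net, signed = TRUE) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > net$n_agents))
      stop("edge endpoint out of range")
    if (any(e[, 1L] == e[, 2L])) stop("self-links are not allowed")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) stop("duplicate links present")
  }
  if (length(net$signs) != nrow(e))
    stop("`signs` must be parallel to the edge rows")
  if (length(net$opinions) != net$n_agents)
    stop("`opinions` must have one entry per agent")
  if (signed) {
    if (anyNA(net$signs) || !all(net$signs %in% c(-1L, 1L)))
      stop("all link signs must be -1 or +1")
    if (anyNA(net$opinions) || !all(net$opinions %in% c(-1L, 1L)))
      stop("all opinions must be -1 or +1")
  }
  invisible(net)
}

#' @export
print.signed_network <- function(x, ...) {
  m <- nrow(x$edges)
  cat(sprintf("<signed_network> %d agents, %d links (mean degree %.2f)\n",
              x$n_agents, m, 2 * m / x$n_agents))
  if (!anyNA(x$signs) && m > 0)
    cat(sprintf("  negative links: %d (%.1f%%)\n", sum(x$signs < 0),
                100 * mean(x$signs < 0)))
  if (!anyNA(x$opinions))
    cat(sprintf("  opinion alignment m = %.3f\n", opinion_alignment(x)))
  invisible(x)
}

#' Regular ring lattice topology
#'
#' Every agent sits on a ring and is linked to its `k/2` nearest
#' neighbours on each side, so all `N` agents have degree exactly `k`
#' and the lattice has `N k / 2` links. Signs and opinions are left
#' unset; see [randomize_state()].
#'
#' @param n_agents number of agents `N`.
#' @param k target degree; must be even and smaller than `N`.
#' @return an unsigned `signed_network` topology.
#' @examples
#' ring_lattice(10, 4)
#' @export
ring_lattice <- function(n_agents, k) {
  n_agents <- as.integer(n_agents)
  k <- as.integer(k)
  if (k %% 2L != 0L) stop("`k` must be even for a ring lattice")
  if (k >= n_agents) stop("`k` must be smaller than `n_agents`")
  if (k < 2L) stop("`k` must be at least 2")
  half <- k %/% 2L
  i <- rep(seq_len(n_agents), each = half)
  off <- rep(seq_len(half), times = n_agents)
  j <- ((i - 1L + off) %% n_agents) + 1L
  signed_network(cbind(i, j), n_agents = n_agents)
}

#' Small-world topology by connectivity-preserving rewiring
#'
#' Starting from [ring_lattice()], each link independently with
#' probability `epsilon` has one uniformly chosen endpoint detached and
#' reattached to a uniformly chosen non-adjacent agent. Proposals that
#' would create a self-link, a duplicate link, or disconnect the graph
#' are rejected and resampled (up to `max_tries` attempts per link,
#' after which the link is left in place), so the result is always a
#' connected graph with exactly `N k / 2` links and mean degree `k`.
#' `epsilon = 0` returns the untouched lattice; `epsilon = 1`
#' approaches a random graph.
#'
#' @inheritParams ring_lattice
#' @param epsilon rewiring probability in \[0, 1\].
#' @param seed optional integer seed for reproducibility.
#' @param max_tries rejection-resampling budget per rewired link.
#' @return an unsigned `signed_network` topology.
#' @export
small_world <- function(n_agents, k, epsilon, seed = NULL, max_tries = 100) {
  if (epsilon < 0 || epsilon > 1) stop("`epsilon` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  net <- ring_lattice(n_agents, k)
  if (epsilon == 0) return(net)
  e <- net$edges
  m <- nrow(e)
  adj <- igraph::graph_from_edgelist(e, directed = FALSE)
  rewire_flags <- runif(m) < epsilon
  for (idx in which(rewire_flags)) {
    for (try in seq_len(max_tries)) {
      keep_side <- if (runif(1) < 0.5) 1L else 2L
      kept <- e[idx, keep_side]
      cand <- sample.int(n_agents, 1L)
      if (cand == kept) next
      if (igraph::are_adjacent(adj, kept, cand)) next
      old <- e[idx, ]
      g2 <- igraph::delete_edges(adj, igraph::get_edge_ids(adj, old))
      g2 <- igraph::add_edges(g2, c(kept, cand))
      if (!igraph::is_connected(g2)) next
      adj <- g2
      e[idx, ] <- c(kept, cand)
      break
    }
  }
  signed_network(e, n_agents = n_agents)
}

#' Complete graph topology
#'
#' All `N (N - 1) / 2` pairs linked; used for small worked examples and
#' exhaustive ground-state enumeration.
#'
#' @inheritParams ring_lattice
#' @return an unsigned `signed_network` topology.
#' @export
complete_network <- function(n_agents) {
  pairs <- t(utils::combn(n_agents, 2L))
  signed_network(pairs, n_agents = n_agents)
}

#' Draw random link signs and opinions
#'
#' Assigns each link sign independently (+1 with probability `p_plus`)
#' and each opinion independently (+1 with probability `p_up`), leaving
#' the topology untouched. The defaults give the equiprobable random
#' initial configuration used by the dynamics.
#'
#' @param net a `signed_network` (topology with or without signs).
#' @param p_plus probability of a friendly (+1) link.
#' @param p_up probability of a +1 opinion.
#' @param seed optional integer seed.
#' @return the network with signs and opinions assigned.
#' @export
randomize_state <- function(net, p_plus = 0.5, p_up = 0.5, seed = NULL) {
  stopifnot(inherits(net, "signed_network"))
  if (p_plus < 0 || p_plus > 1 || p_up < 0 || p_up > 1)
    stop("`p_plus` and `p_up` must be probabilities")
  if (!is.null(seed)) set.seed(seed)
  net$signs <- ifelse(runif(nrow(net$edges)) < p_plus, 1L, -1L)
  net$opinions <- ifelse(runif(net$n_agents) < p_up, 1L, -1L)
  validate_network(net)
}

#' Convert to an igraph object
#'
#' Edge attribute `sign` and vertex attribute `opinion` are attached
#' when assigned.
#'
#' @param net a `signed_network`.
#' @return an igraph graph object.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, net$n_agents - igraph::vcount(g)))
  if (!anyNA(net$signs)) igraph::E(g)$sign <- net$signs
  if (!anyNA(net$opinions)) igraph::V(g)$opinion <- net$opinions
  g
}

#' Read and write signed edge lists and opinions
#'
#' Plain-text CSV interchange: edge lists have columns
#' `source,target,sign` with 0-based agent ids and one undirected link
#' per row; opinion files have columns `node,opinion`. [write_graphml()]
#' exports the network with a `sign` edge attribute and an `opinion`
#' node attribute for use in other tools.
#'
#' @param net a `signed_network`.
#' @param path file path.
#' @param n_agents optional agent count when reading (defaults to the
#'   largest id seen plus one).
#' @return the written path (writers, invisibly) or a `signed_network` /
#'   opinion vector (readers).
#' @name network-io
NULL

#' @rdname network-io
#' @export
write_edge_list <- function(net, path) {
  validate_network(net, signed = !anyNA(net$signs))
  df <- data.frame(source = net$edges[, 1L] - 1L,
                   target = net$edges[, 2L] - 1L,
                   sign = net$signs)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
read_edge_list <- function(path, n_agents = NULL) {
  df <- read.csv(path)
  if (!all(c("source", "target", "sign") %in% names(df)))
    stop("edge list must have columns source, target, sign")
  if (is.null(n_agents)) n_agents <- max(df$source, df$target) + 1L
  signed_network(cbind(df$source + 1L, df$target + 1L),
                 n_agents = n_agents, signs = df$sign)
}

#' @rdname network-io
#' @export
write_opinions <- function(net, path) {
  df <- data.frame(node = seq_len(net$n_agents) - 1L,
                   opinion = net$opinions)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
read_opinions <- function(path, net = NULL) {
  df <- read.csv(path)
  if (!all(c("node", "opinion") %in% names(df)))
    stop("opinion file must have columns node, opinion")
  op <- integer(max(df$node) + 1L)
  op[df$node + 1L] <- as.integer(df$opinion)
  if (!is.null(net)) {
    if (length(op) < net$n_agents) op <- c(op, rep(NA_integer_,
                                                   net$n_agents - length(op)))
    net$opinions <- op
    return(validate_network(net))
  }
  op
}

#' @rdname network-io
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
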