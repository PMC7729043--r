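# Shared fixtures and independent oracles, built in code.

# pure-R stress oracle: direct evaluation of the three Hamiltonian sums by
# triple enumeration; deliberately independent of the package's C++ path
stress_oracle <- function(net, g = 1, h = 0) {
  e <- net$edges
  J <- as.numeric(net$signs)
  s <- as.numeric(net$opinions)
  sign_of <- function(a, b) {
    idx <- which((e[, 1] == a & e[, 2] == b) | (e[, 1] == b & e[, 2] == a))
    if (length(idx)) J[idx] else 0
  }
  H <- -sum(J * s[e[, 1]] * s[e[, 2]]) + (h / 2) * sum(1 - J)
  if (net$n_agents >= 3) {
    trips <- utils::combn(net$n_agents, 3)
    for (cidx in seq_len(ncol(trips))) {
      tr <- trips[, cidx]
      H <- H - g * sign_of(tr[1], tr[2]) * sign_of(tr[2], tr[3]) *
        sign_of(tr[1], tr[3])
    }
  }
  H
}

# connected random signed graph with random opinions
random_signed_net <- function(n, p_edge = 0.6) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::ecount(g) >= 1 && igraph::is_connected(g)) break
  }
  signed_network(igraph::as_edgelist(g), n,
                 signs = sample(c(-1L, 1L), igraph::ecount(g),
                                replace = TRUE),
                 opinions = sample(c(-1L, 1L), n, replace = TRUE))
}

# clusterable signed graph: random labels, all-positive within groups,
# all-negative between
clusterable_net <- function(n, p_edge = 0.7, n_groups = 2) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::ecount(g) >= 3) break
  }
  lab <- sample(seq_len(n_groups), n, replace = TRUE)
  e <- igraph::as_edgelist(g)
  signs <- ifelse(lab[e[, 1]] == lab[e[, 2]], 1L, -1L)
  net <- signed_network(e, n, signs = signs,
                        opinions = ifelse(lab == 1L, 1L, -1L))
  attr(net, "labels") <- lab
  net
}

two_agent_net <- function(sign = 1L, opinions = c(1L, 1L)) {
  signed_network(rbind(c(1L, 2L)), n_agents = 2,
                 signs = sign, opinions = opinions)
}
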