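#' Triangle census of a signed network
#'
#' Enumerates each closed triangle once and classifies it by the sign
#' product of its three links: balanced (`J_ij J_jk J_ki = +1`) or
#' unbalanced (`-1`).
#'
#' @param net a `signed_network` with assigned link signs.
#' @return a list with integer counts `n_plus` (balanced) and `n_minus`
#'   (unbalanced); their sum is the triangle count of the topology.
#' @export
triangle_census <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (anyNA(net$signs)) stop("link signs must be assigned")
  cen <- cpp_triangle_census(net$n_agents, net$edges, net$signs)
  list(n_plus = as.integer(cen[["n_plus"]]),
       n_minus = as.integer(cen[["n_minus"]]))
}

#' Balance index f
#'
#' `f = (n_plus - n_minus) / (n_plus + n_minus)`, the excess fraction of
#' balanced over unbalanced triangles, in \[-1, 1\]. `f = 1` means every
#' triangle is balanced; `f` near 0 means balanced and unbalanced triads
#' are equally common. On a triangle-free topology the index is
#' undefined and `NA` is returned (with a warning), so such graphs are
#' not misread as maximally frustrated.
#'
#' @param census a [triangle_census()] result, or a `signed_network`
#'   (the census is computed on the fly).
#' @return the scalar balance index, or `NA` if there are no triangles.
#' @export
balance_f <- function(census) {
  if (inherits(census, "signed_network")) census <- triangle_census(census)
  tot <- census$n_plus + census$n_minus
  if (tot == 0L) {
    warning("triangle-free network: balance index undefined")
    return(NA_real_)
  }
  (census$n_plus - census$n_minus) / tot
}

#' Relative stress e_f
#'
#' The ratio of the current stress `H` to the absolute value of the
#' ground-state stress of the same topology. By construction
#' `e_f >= -1`, with equality exactly when no social tension remains
#' (the configuration attains the ground state).
#'
#' @inheritParams total_stress
#' @return the scalar relative stress.
#' @export
relative_stress <- function(net, params = model_params()) {
  params <- as_params(params)
  gs <- ground_state_stress(net, params)
  total_stress(net, params) / abs(gs)
}

#' Opinion alignment m
#'
#' `m = |sum_i s_i| / N`, the absolute mean opinion of the society, in
#' \[0, 1\]. `m = 1` means full consensus; low `m` means diverse
#' opinions.
#'
#' @param net a `signed_network` with assigned opinions.
#' @return the scalar alignment.
#' @export
opinion_alignment <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (anyNA(net$opinions)) stop("opinions must be assigned")
  abs(sum(net$opinions)) / net$n_agents
}

#' Positive clusters
#'
#' Connected components of the subgraph restricted to positive links.
#' Agents without positive links form singleton components, so the
#' sizes always sum to `N`. A component spanning all of society
#' indicates a cohesive phase in which cooperation percolates.
#'
#' @param net a `signed_network` with assigned link signs.
#' @return a list with `membership` (component id per agent) and
#'   `sizes` (component sizes, descending).
#' @export
positive_clusters <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (anyNA(net$signs)) stop("link signs must be assigned")
  pos <- net$edges[net$signs > 0L, , drop = FALSE]
  g <- igraph::graph_from_edgelist(pos, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, net$n_agents - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(membership = as.integer(comp$membership),
       sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' Frustration of a partition
#'
#' Counts positive links between clusters plus negative links within
#' clusters: the objective of the signed blockmodel, whose minimum over
#' all partitions is the line index of balance.
#'
#' @param net a `signed_network` with assigned link signs.
#' @param labels integer cluster label per agent.
#' @return the integer frustration count.
#' @export
partition_frustration <- function(net, labels) {
  same <- labels[net$edges[, 1L]] == labels[net$edges[, 2L]]
  sum((net$signs > 0L & !same) | (net$signs < 0L & same))
}

#' Frustration-minimizing signed partition
#'
#' Heuristically minimizes the frustration objective over partitions
#' with a free number of clusters, by greedy node-move local search:
#' each pass moves single agents to the neighbouring (or a fresh)
#' cluster that most reduces frustration, iterated to a local optimum,
#' and the best result of `restarts` initializations (one singleton
#' start plus random label starts) is kept. With `exhaustive = TRUE`
#' (feasible for `N <= 10`) all set partitions are enumerated instead
#' and the exact minimum is returned.
#'
#' @param net a `signed_network` with assigned link signs.
#' @param restarts number of local-search restarts.
#' @param exhaustive use exact enumeration over all set partitions.
#' @return an object of class `partition`: list with `labels`
#'   (consecutive cluster ids per agent), `frustration`, `n_clusters`
#'   and `method`.
#' @export
signed_partition <- function(net, restarts = 20, exhaustive = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  if (anyNA(net$signs)) stop("link signs must be assigned")
  if (exhaustive) {
    if (net$n_agents > 10L)
      stop("exhaustive partition search limited to N <= 10")
    best <- NULL
    best_cost <- Inf
    enumerate_partitions(net$n_agents, function(labels) {
      cost <- partition_frustration(net, labels)
      if (cost < best_cost) {
        best_cost <<- cost
        best <<- labels
      }
    })
    labels <- match(best, unique(best))
    res <- list(labels = labels, frustration = best_cost)
    method <- "exhaustive"
  } else {
    res <- cpp_signed_partition(net$n_agents, net$edges, net$signs,
                                as.integer(restarts))
    method <- "greedy"
  }
  structure(list(labels = as.integer(res$labels),
                 frustration = as.integer(res$frustration),
                 n_clusters = length(unique(res$labels)),
                 method = method),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d clusters, frustration %d (%s)\n",
              x$n_clusters, x$frustration, x$method))
  invisible(x)
}

# visit every set partition of n elements as restricted-growth labels
enumerate_partitions <- function(n, visit) {
  labels <- integer(n)
  recurse <- function(i, maxl) {
    if (i > n) {
      visit(labels)
      return(invisible(NULL))
    }
    for (l in seq_len(maxl + 1L)) {
      labels[i] <<- l
      recurse(i + 1L, max(maxl, l))
    }
  }
  labels[1L] <- 1L
  recurse(2L, 1L)
  if (n == 1L) visit(labels)
  invisible(NULL)
}

#' Line index of balance
#'
#' The minimum number of links whose removal (equivalently, sign
#' change) makes the network balanced; equals the minimal frustration
#' over all partitions. Given a heuristic [signed_partition()], the
#' returned frustration is an upper bound on the line index; it is
#' exact when the partition was computed exhaustively.
#'
#' @param partition a [signed_partition()] result.
#' @return the integer frustration of the partition.
#' @export
line_index <- function(partition) {
  stopifnot(inherits(partition, "partition"))
  partition$frustration
}

#' Echo chambers
#'
#' Among the clusters of the frustration-minimizing partition, those
#' whose members all hold the same opinion are echo chambers: groups of
#' mutually friendly, like-minded agents. Mixed-opinion clusters
#' contribute none; singleton clusters count as echo chambers of
#' size 1.
#'
#' @param net a fully signed `signed_network`.
#' @param partition a [signed_partition()] of `net` (computed with
#'   default settings when omitted).
#' @param largest_only return only the largest echo-chamber size.
#' @return a list with `echo_sizes` (sizes of all echo chambers,
#'   descending), `cluster_sizes` (all partition cluster sizes,
#'   descending) and `echo_clusters` (the cluster ids that are echo
#'   chambers).
#' @export
echo_chambers <- function(net, partition = NULL, largest_only = FALSE) {
  validate_network(net)
  if (is.null(partition)) partition <- signed_partition(net)
  lab <- partition$labels
  sizes <- tabulate(lab)
  uniform <- vapply(seq_along(sizes), function(cl) {
    ops <- net$opinions[lab == cl]
    length(ops) > 0L && all(ops == ops[1L])
  }, logical(1))
  echo <- sort(sizes[uniform], decreasing = TRUE)
  if (largest_only) echo <- utils::head(echo, 1L)
  list(echo_sizes = as.integer(echo),
       cluster_sizes = sort(as.integer(sizes[sizes > 0L]),
                            decreasing = TRUE),
       echo_clusters = which(uniform))
}

#' Long-format cluster-size report
#'
#' Convenience tabulation of positive-cluster and echo-chamber size
#' distributions, in the long CSV-friendly format
#' `(kind, size, count)`.
#'
#' @inheritParams echo_chambers
#' @return a data frame with columns `kind` (`"positive"`/`"echo"`),
#'   `size` and `count`.
#' @export
cluster_size_report <- function(net, partition = NULL) {
  pos <- positive_clusters(net)$sizes
  ec <- echo_chambers(net, partition)$echo_sizes
  tab <- function(x, kind) {
    if (length(x) == 0L)
      return(data.frame(kind = character(), size = integer(),
                        count = integer()))
    t <- table(x)
    data.frame(kind = kind, size = as.integer(names(t)),
               count = as.integer(t))
  }
  rbind(tab(pos, "positive"), tab(ec, "echo"))
}
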