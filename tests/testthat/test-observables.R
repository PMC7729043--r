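test_that("triangle census classifies balanced and unbalanced triads", {
  k4 <- randomize_state(complete_network(4), 1, 1)
  expect_equal(triangle_census(k4), list(n_plus = 4L, n_minus = 0L))
  c3 <- complete_network(3)
  c3$signs <- rep(-1L, 3)
  c3$opinions <- rep(1L, 3)
  expect_equal(triangle_census(c3), list(n_plus = 0L, n_minus = 1L))
  r <- randomize_state(ring_lattice(10, 4), 0.5, 0.5, seed = 1)
  cen <- triangle_census(r)
  expect_equal(cen$n_plus + cen$n_minus, 10L)

  # census against direct triple enumeration on random graphs
  set.seed(21)
  for (rep in 1:15) {
    net <- random_signed_net(sample(5:9, 1))
    cen <- triangle_census(net)
    # oracle: -g * sum of products with g=1, no edge/field contribution
    tri_term <- stress_oracle(net, g = 1, h = 0) -
      stress_oracle(net, g = 0, h = 0)
    expect_equal(cen$n_plus - cen$n_minus, -tri_term)
  }
})

test_that("balance index f follows its definition and flags triangle-free graphs", {
  expect_equal(balance_f(list(n_plus = 4L, n_minus = 0L)), 1)
  expect_equal(balance_f(list(n_plus = 2L, n_minus = 2L)), 0)
  expect_equal(balance_f(list(n_plus = 7L, n_minus = 3L)), 0.4)
  fx <- fixture_k4()
  expect_equal(balance_f(fx$net), 0)  # worked example starts at f = 0
  ring <- randomize_state(ring_lattice(12, 2), seed = 2)
  expect_warning(f <- balance_f(ring), "triangle-free")
  expect_true(is.na(f))
})

test_that("relative stress is -1 exactly at the ground state and never below", {
  p <- model_params(g = 1)
  k4 <- randomize_state(complete_network(4), 1, 1)
  expect_identical(relative_stress(k4, p), -1)
  r10 <- randomize_state(ring_lattice(10, 4), 1, 1)
  expect_identical(relative_stress(r10, p), -1)
  set.seed(22)
  for (rep in 1:30) {
    net <- randomize_state(ring_lattice(sample(6:20, 1), 4))
    ef <- relative_stress(net, p)
    expect_gte(ef, -1)
  }
})

test_that("opinion alignment m averages opinions on [0, 1]", {
  net <- randomize_state(complete_network(4), 1, 1)
  expect_equal(opinion_alignment(net), 1)
  net$opinions <- c(1L, 1L, -1L, -1L)
  expect_equal(opinion_alignment(net), 0)
  net$opinions <- c(1L, 1L, 1L, -1L)
  expect_equal(opinion_alignment(net), 0.5)
})

test_that("positive clusters are the components of the positive subgraph", {
  path4 <- signed_network(rbind(c(1, 2), c(2, 3), c(3, 4)), 4,
                          signs = c(1L, -1L, 1L),
                          opinions = rep(1L, 4))
  expect_equal(positive_clusters(path4)$sizes, c(2L, 2L))
  allneg <- complete_network(4)
  allneg$signs <- rep(-1L, 6)
  allneg$opinions <- rep(1L, 4)
  expect_equal(positive_clusters(allneg)$sizes, rep(1L, 4))
  allpos <- randomize_state(complete_network(4), 1, 1)
  expect_equal(positive_clusters(allpos)$sizes, 4L)
  set.seed(23)
  for (rep in 1:10) {
    net <- random_signed_net(sample(5:12, 1))
    expect_equal(sum(positive_clusters(net)$sizes), net$n_agents)
  }
})

test_that("signed partition recovers exact minima on small graphs", {
  # two hostile factions: frustration 0, factions recovered
  k4 <- complete_network(4)
  within <- (k4$edges[, 1] <= 2) == (k4$edges[, 2] <= 2)
  k4$signs <- ifelse(within, 1L, -1L)
  k4$opinions <- c(1L, 1L, -1L, -1L)
  set.seed(24)
  p <- signed_partition(k4)
  expect_equal(p$frustration, 0L)
  expect_equal(p$labels[1], p$labels[2])
  expect_equal(p$labels[3], p$labels[4])
  expect_false(p$labels[1] == p$labels[3])

  # all-negative 3-cycle: three singletons, frustration 0
  c3 <- complete_network(3)
  c3$signs <- rep(-1L, 3)
  c3$opinions <- rep(1L, 3)
  expect_equal(signed_partition(c3)$frustration, 0L)
  expect_equal(signed_partition(c3, exhaustive = TRUE)$frustration, 0L)

  # (+, +, -) 3-cycle is frustrated: line index 1
  c3$signs <- c(1L, 1L, -1L)
  expect_equal(line_index(signed_partition(c3, exhaustive = TRUE)), 1L)
  expect_equal(line_index(signed_partition(c3)), 1L)
})

test_that("heuristic partition never beats the exhaustive optimum", {
  set.seed(25)
  worse <- 0L
  for (rep in 1:60) {
    net <- random_signed_net(sample(4:8, 1))
    fh <- signed_partition(net, restarts = 10)$frustration
    fe <- signed_partition(net, exhaustive = TRUE)$frustration
    expect_gte(fh, fe)
    if (fh > fe) worse <- worse + 1L
  }
  expect_lte(worse, 6)  # equality on at least 90%
})

test_that("partition frustration is consistent with the returned labels", {
  set.seed(26)
  for (rep in 1:15) {
    net <- random_signed_net(sample(5:10, 1))
    p <- signed_partition(net)
    expect_equal(partition_frustration(net, p$labels), p$frustration)
  }
})

test_that("clusterable networks are fully balanced with zero line index", {
  set.seed(27)
  for (rep in 1:20) {
    net <- clusterable_net(sample(6:10, 1))
    cen <- triangle_census(net)
    if (cen$n_plus + cen$n_minus > 0) {
      expect_equal(cen$n_minus, 0L)
      expect_equal(balance_f(net), 1)
    }
    expect_equal(signed_partition(net)$frustration, 0L)
  }
})

test_that("echo chambers are the like-minded clusters of the partition", {
  k4 <- complete_network(4)
  within <- (k4$edges[, 1] <= 2) == (k4$edges[, 2] <= 2)
  k4$signs <- ifelse(within, 1L, -1L)
  k4$opinions <- c(1L, 1L, -1L, -1L)
  set.seed(28)
  ec <- echo_chambers(k4)
  expect_equal(ec$echo_sizes, c(2L, 2L))

  # a mixed-opinion cluster contributes no echo chamber
  k4$opinions <- c(1L, -1L, -1L, -1L)
  ec <- echo_chambers(k4)
  expect_equal(ec$echo_sizes, 2L)
  expect_equal(ec$cluster_sizes, c(2L, 2L))

  # fully balanced aligned society: one echo chamber of size N
  allpos <- randomize_state(complete_network(5), 1, 1)
  ec <- echo_chambers(allpos)
  expect_equal(ec$echo_sizes, 5L)

  # echo sizes bounded by cluster sizes, largest_only picks the maximum
  set.seed(29)
  for (rep in 1:10) {
    net <- random_signed_net(8)
    part <- signed_partition(net)
    ec <- echo_chambers(net, part)
    if (length(ec$echo_sizes) > 0) {
      expect_lte(max(ec$echo_sizes), max(ec$cluster_sizes))
      expect_equal(echo_chambers(net, part, largest_only = TRUE)$echo_sizes,
                   max(ec$echo_sizes))
    }
    expect_lte(sum(ec$echo_sizes), net$n_agents)
  }
})

test_that("cluster size report tabulates both kinds in long format", {
  set.seed(30)
  net <- random_signed_net(10)
  rep_df <- cluster_size_report(net)
  expect_true(all(c("kind", "size", "count") %in% names(rep_df)))
  pos <- rep_df[rep_df$kind == "positive", ]
  expect_equal(sum(pos$size * pos$count), 10)
})
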