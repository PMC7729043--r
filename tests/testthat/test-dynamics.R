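test_that("the Metropolis rule accepts downhill moves surely and uphill ones at the Boltzmann rate", {
  expect_true(metropolis_accept(-4, 0.01))
  expect_true(metropolis_accept(0, 1))  # H1 <= H0 accepted deterministically
  expect_error(metropolis_accept(1, 0), "positive")
  set.seed(1)
  draws <- replicate(1e5, metropolis_accept(2, 1))
  p_hat <- mean(draws)
  p_exact <- exp(-2)
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})

test_that("an opinion sweep makes round(n N) attempts and touches no links", {
  set.seed(2)
  net <- randomize_state(ring_lattice(50, 4))
  res <- opinion_sweep(net, model_params(rate = 1, temperature = 1))
  expect_equal(res$attempts, 50)
  expect_equal(res$net$signs, net$signs)
  expect_equal(res$net$edges, net$edges)
  res2 <- opinion_sweep(net, model_params(rate = 2, temperature = 1))
  expect_equal(res2$attempts, 100)
  # isolated agents always flip (delta H = 0)
  iso <- signed_network(rbind(c(1L, 2L)), n_agents = 10, signs = 1L,
                        opinions = rep(1L, 10))
  resi <- opinion_sweep(iso, model_params(temperature = 1))
  expect_gte(resi$accepted, resi$attempts - 4)  # only agents 1,2 can reject
})

test_that("link updates conserve the link count in both flip and rewiring branches", {
  set.seed(3)
  net <- randomize_state(ring_lattice(40, 4))
  for (p_rw in c(0, 1)) {
    pars <- model_params(temperature = 5, p_rewire = p_rw)
    cur <- net
    for (r in 1:50) {
      res <- link_update(cur, pars)
      cur <- res$net
      expect_equal(nrow(cur$edges), nrow(net$edges))
      expect_true(res$move == if (p_rw == 0) "flip" else "rewire")
    }
    validate_network(cur)
  }
  # pure sign-flip dynamics leaves the topology untouched
  set.seed(4)
  cur <- net
  for (r in 1:30) cur <- link_update(cur, model_params(temperature = 2))$net
  expect_equal(cur$edges, net$edges)
})

test_that("homophilious rewiring signs new links by opinion agreement", {
  set.seed(5)
  # all opinions equal: every accepted rewiring must create a +1 link
  net <- randomize_state(ring_lattice(30, 4), p_plus = 0.5, p_up = 1)
  pars <- model_params(temperature = 100, p_rewire = 1,
                       rewiring_mode = "homophilious")
  cur <- net
  for (r in 1:60) cur <- link_update(cur, pars)$net
  created <- !(paste(cur$edges[, 1], cur$edges[, 2]) %in%
                 paste(net$edges[, 1], net$edges[, 2]))
  expect_gt(sum(created), 0)
  expect_true(all(cur$signs[created] == 1L))
})

test_that("trajectories are reproducible and conserve N and link count", {
  net <- randomize_state(ring_lattice(30, 4), seed = 6)
  pars <- model_params(temperature = 2, p_rewire = 0.3)
  set.seed(7)
  a <- run_to_stationarity(net, pars, max_steps = 200,
                           check_convergence = FALSE)
  set.seed(7)
  b <- run_to_stationarity(net, pars, max_steps = 200,
                           check_convergence = FALSE)
  expect_identical(a$records, b$records)
  expect_identical(a$net, b$net)
  expect_equal(nrow(a$net$edges), nrow(net$edges))
  expect_equal(a$net$n_agents, net$n_agents)
  # incremental H agrees with the final full recomputation
  expect_equal(a$stress, total_stress(a$net, pars), tolerance = 1e-9)
})

test_that("the all-positive aligned state is absorbing as T -> 0", {
  net <- randomize_state(ring_lattice(20, 4), p_plus = 1, p_up = 1)
  pars <- model_params(temperature = 1e-6)
  set.seed(8)
  tr <- run_to_stationarity(net, pars, max_steps = 500,
                            check_convergence = FALSE)
  expect_identical(tr$net$opinions, net$opinions)
  expect_identical(tr$net$signs, net$signs)
  expect_equal(tr$stress, ground_state_stress(net, pars))
})

test_that("triangle-free topologies evolve independently of g", {
  net <- randomize_state(ring_lattice(16, 2), seed = 9)
  set.seed(10)
  a <- run_to_stationarity(net, model_params(g = 0, temperature = 1.5),
                           max_steps = 300, check_convergence = FALSE)
  set.seed(10)
  b <- run_to_stationarity(net, model_params(g = 7, temperature = 1.5),
                           max_steps = 300, check_convergence = FALSE)
  expect_identical(a$net, b$net)
  expect_identical(a$records$H, b$records$H)
})

test_that("fractional opinion rates attempt opinion flips probabilistically", {
  # rate * N = 0.5: about half of the steps carry an opinion attempt
  net <- randomize_state(ring_lattice(10, 2), seed = 11)
  pars <- model_params(rate = 0.05, temperature = 100)
  set.seed(12)
  tr <- run_to_stationarity(net, pars, max_steps = 2000,
                            check_convergence = FALSE)
  frac <- tr$accepted_opinions / 2000
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.62)
})

test_that("the K4 worked example relaxes to the balanced ground state", {
  fx <- fixture_k4()
  set.seed(13)
  reached <- 0L
  for (r in 1:100) {
    tr <- run_to_stationarity(fx$net, fx$params, max_steps = 2000)
    if (abs(tr$stress + 10) < 1e-9) reached <- reached + 1L
  }
  expect_gte(reached, 95)
})
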