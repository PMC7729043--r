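test_that("the four-agent fixture matches its documented initial state", {
  fx <- fixture_k4()
  expect_equal(triangle_census(fx$net), list(n_plus = 2L, n_minus = 2L))
  expect_identical(ground_state_stress(fx$net, fx$params), -10)
  expect_gt(total_stress(fx$net, fx$params), -10)
  expect_silent(validate_network(fx$net))
})

test_that("phase-diagram scans return in-range, reproducible cell summaries", {
  sc <- phase_diagram_scan(k_values = c(4, 6), t_values = c(1, 4),
                           n_agents = 40, realizations = 3,
                           max_steps = 400, seed = 31)
  expect_equal(nrow(sc), 4)
  expect_true(all(sc$mean_f >= -1 & sc$mean_f <= 1))
  expect_true(all(sc$mean_m >= 0 & sc$mean_m <= 1))
  expect_true(all(sc$mean_e_f >= -1))
  expect_true(all(sc$realizations == 3))
  sc2 <- phase_diagram_scan(k_values = c(4, 6), t_values = c(1, 4),
                            n_agents = 40, realizations = 3,
                            max_steps = 400, seed = 31)
  expect_identical(sc, sc2)
  # non-constructible cells are flagged, not fatal
  expect_warning(
    bad <- phase_diagram_scan(k_values = 5, t_values = 1, n_agents = 40,
                              realizations = 2, max_steps = 50),
    "not constructible")
  expect_true(is.na(bad$mean_f))
})

test_that("low temperature and high connectivity fragment society", {
  sc <- phase_diagram_scan(k_values = 8, t_values = c(1, 6),
                           n_agents = 60, realizations = 4,
                           max_steps = 6000, seed = 32)
  expect_gt(sc$mean_f[sc$temperature == 1], 0.85)
  expect_lt(sc$mean_f[sc$temperature == 6], 0.5)
})

test_that("strengthening the balance term raises stationary f in the transition region", {
  f_small <- phase_diagram_scan(k_values = 8, t_values = 2.5, n_agents = 60,
                                params = model_params(g = 0.01),
                                realizations = 6, max_steps = 4000,
                                seed = 33)$mean_f
  f_large <- phase_diagram_scan(k_values = 8, t_values = 2.5, n_agents = 60,
                                params = model_params(g = 1),
                                realizations = 6, max_steps = 4000,
                                seed = 33)$mean_f
  expect_gt(f_large, f_small)
})

test_that("hysteresis sweeps carry state across the temperature path", {
  hy <- hysteresis_sweep(t_values = c(2, 6, 10), k = 10, n_agents = 30,
                         realizations = 2, steps_per_temp = 300,
                         seed = 34)
  expect_equal(hy$temperature, c(2, 6, 10))
  expect_true(all(is.finite(hy$f_up)))
  expect_true(all(is.finite(hy$f_down)))
})

test_that("a strong pro-social field forces consensus and removes hostility", {
  # consensus formation is slow, so run with a strict stationarity
  # tolerance to avoid measuring before the opinions have aligned
  sc <- external_field_scan(h_values = c(0, 8), t_values = 1, k = 6,
                            n_agents = 50, realizations = 4,
                            max_steps = 20000, tol = 0.05, seed = 35)
  weak <- sc[sc$h == 0, ]
  strong <- sc[sc$h == 8, ]
  expect_lt(weak$mean_m, 0.9)       # opinion clusters persist
  expect_gt(strong$mean_m, 0.95)    # global consensus
  expect_lt(strong$mean_neg_frac, 0.02)
  expect_gt(weak$mean_neg_frac, strong$mean_neg_frac)
})

test_that("convergence-time experiments report per-run tau and censoring", {
  ct <- convergence_time_experiment(realizations = 6, n_agents = 40, k = 4,
                                    params = model_params(temperature = 1),
                                    seed = 36)
  expect_length(ct$tau, 6)
  expect_true(all(ct$tau[!is.na(ct$tau)] >= 0))
  expect_equal(ct$mean_tau, mean(ct$tau, na.rm = TRUE))
  # identical seeds give identical tau
  a <- convergence_time_experiment(realizations = 2, n_agents = 30, k = 4,
                                   seed = 37)
  b <- convergence_time_experiment(realizations = 2, n_agents = 30, k = 4,
                                   seed = 37)
  expect_identical(a$tau, b$tau)
  # impossibly small step budget censors runs, with a warning
  expect_warning(
    cc <- convergence_time_experiment(realizations = 2, n_agents = 40,
                                      k = 4, max_steps = 25, seed = 38),
    "censored")
  expect_equal(cc$n_censored, 2)
})

test_that("run configs round-trip through YAML and drive a full simulation", {
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c("N: 30", "k: 4", "T: 1.5", "seed: 39", "max_steps: 300"),
             cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$N, 30)
  expect_equal(cfg$T, 1.5)
  expect_equal(cfg$g, 1)  # default
  out <- tempfile()
  traj <- run_simulation(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "run_trajectory.csv")))
  expect_true(file.exists(file.path(out, "run_edges.csv")))
  expect_true(file.exists(file.path(out, "run_meta.json")))
  meta <- jsonlite::read_json(file.path(out, "run_meta.json"))
  expect_equal(meta$config$seed, 39)
  expect_equal(meta$package, "socialbalance")
  back <- read_edge_list(file.path(out, "run_edges.csv"), n_agents = 30)
  expect_equal(nrow(back$edges), 60)
  unlink(out, recursive = TRUE)
  writeLines("bogus_key: 1", cfg_path)
  expect_error(read_run_config(cfg_path), "unknown config keys")
  unlink(cfg_path)
})
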