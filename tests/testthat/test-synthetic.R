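test_that("config validation rejects malformed specifications", {
  expect_error(synthetic_config(extent_cells = 8), ">= 16")
  expect_error(synthetic_config(cell_size = 0), "> 0")
  expect_error(synthetic_config(n_stations = 1), ">= 2")
  expect_error(synthetic_config(covariates = list(
    list(name = "x", kind = "continuous", range = -5))), "non-negative")
  expect_error(synthetic_config(covariates = list(
    list(name = "x", kind = "categorical", range = 100, threshold = 1.5))),
    "quantile")
  expect_error(synthetic_config(activity = list(
    bad = list(weights = c(0.6, 0.6), means = c(0, 1), kappas = c(1, 1)))),
    "sum to 1")
  expect_error(synthetic_config(activity = list(
    bad = list(weights = 1, means = 0, kappas = -1))), ">= 0")
})

test_that("covariate stack: determinism, autocorrelation control, class fraction", {
  cfg <- synthetic_config(
    covariates = list(
      list(name = "white", kind = "continuous", range = 0),
      list(name = "smooth", kind = "continuous", range = 600),
      list(name = "forest", kind = "categorical", range = 600,
           threshold = 0.25)),
    n_stations = 10)
  s1 <- generate_covariate_stack(cfg, seed = 9)
  s2 <- generate_covariate_stack(cfg, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1$white$values,
                         generate_covariate_stack(cfg, seed = 10)$white$values))

  # range 0: neighbouring cells uncorrelated on the 128x128 grid
  w <- s1$white$values
  r_adj <- cor(as.vector(w[, -1]), as.vector(w[, -ncol(w)]))
  expect_lt(abs(r_adj), 0.05)
  # smoothed layer is strongly autocorrelated and standardized
  sm <- s1$smooth$values
  expect_gt(cor(as.vector(sm[, -1]), as.vector(sm[, -ncol(sm)])), 0.5)
  expect_equal(mean(sm), 0, tolerance = 1e-10)
  expect_equal(sd(sm), 1, tolerance = 1e-10)
  # categorical: fraction of 1-cells equals the configured class fraction
  expect_lt(abs(mean(s1$forest$values) - 0.25), 0.02)
  expect_true(all(s1$forest$values %in% c(0, 1)))
})

test_that("occurrence generator hits its logistic operating points", {
  cfg0 <- synthetic_config(n_stations = 1000, covariates = list(
    list(name = "noise", kind = "continuous", range = 0)),
    true_scales = c(noise = 120),
    true_beta = c("(Intercept)" = 0, noise = 0, effort = 0))
  surv <- list(stack = generate_covariate_stack(cfg0, seed = 2),
               stations = place_stations(cfg0, seed = 3))
  sim <- simulate_detections(surv$stack, surv$stations, cfg0, seed = 4)
  expect_lt(abs(mean(sim$presence) - 0.5), 0.05)
  expect_true(all(sim$counts[sim$presence == 0] == 0))
  expect_true(all(sim$counts[sim$presence == 1] >= 1))

  cfg_lo <- synthetic_config(n_stations = 500, covariates = cfg0$covariates,
                             true_scales = cfg0$true_scales,
                             true_beta = c("(Intercept)" = -10, noise = 0,
                                           effort = 0))
  sim_lo <- simulate_detections(surv$stack,
                                place_stations(cfg_lo, seed = 3),
                                cfg_lo, seed = 5)
  expect_true(all(sim_lo$counts == 0))

  # prevalence is monotone in the intercept (deterministic in `prob`)
  probs <- vapply(c(-1, 0, 1), function(b0) {
    cfg <- synthetic_config(n_stations = 500, covariates = cfg0$covariates,
                            true_scales = cfg0$true_scales,
                            true_beta = c("(Intercept)" = b0, noise = 0,
                                          effort = 0))
    mean(simulate_detections(surv$stack, place_stations(cfg, seed = 3),
                             cfg, seed = 6)$prob)
  }, 0)
  expect_true(all(diff(probs) > 0))

  cfg_bad <- synthetic_config(n_stations = 100, covariates = cfg0$covariates,
                              true_scales = c(ghost = 120),
                              true_beta = c("(Intercept)" = 0, ghost = 1))
  expect_error(simulate_detections(surv$stack,
                                   place_stations(cfg_bad, seed = 3),
                                   cfg_bad, seed = 1),
               "unknown covariate")
})

test_that("activity time generator: uniform, concentrated, reproducible", {
  cfg <- synthetic_config(n_stations = 10, activity = list(
    flat = list(weights = 1, means = 0, kappas = 0),
    spike = list(weights = 1, means = pi, kappas = 200)))
  flat <- simulate_activity_times("flat", 1000, cfg, seed = 1)
  expect_lt(resultant_length(flat), 0.1)
  expect_true(all(flat$angles >= 0 & flat$angles < 2 * pi))

  spike <- simulate_activity_times("spike", 500, cfg, seed = 2)
  expect_true(all(abs(spike$angles - pi) < 0.3))

  expect_identical(simulate_activity_times("flat", 50, cfg, seed = 7),
                   simulate_activity_times("flat", 50, cfg, seed = 7))
  expect_error(simulate_activity_times("ghost", 10, cfg, seed = 1),
               "no activity mixture")
})

test_that("community generator: independence under null, no cycles, positive effort", {
  cfg_null <- synthetic_config(
    n_stations = 1000,
    community = list(prey_rates = c(mousedeer = 2, civet = 1.5),
                     felids = list(cat = list(intercept = 0, effort = 0,
                                              beta = c(mousedeer = 0)))))
  st <- place_stations(cfg_null, seed = 5)
  mat <- simulate_community(st, cfg_null, seed = 6)
  expect_true(all(attr(mat, "effort") > 0))
  pres <- as.integer(unclass(mat)[, "cat"] > 0)
  for (prey in c("mousedeer", "civet"))
    expect_lt(abs(cor(pres, unclass(mat)[, prey])), 0.1)

  cfg_cyc <- synthetic_config(community = list(
    prey_rates = c(deer = 1),
    felids = list(a = list(intercept = 0, effort = 0, beta = c(b = 0.1)),
                  b = list(intercept = 0, effort = 0, beta = c(a = 0.1)))))
  expect_error(simulate_community(st[1:50, ], cfg_cyc, seed = 1), "cyclic")

  # acyclic felid-on-felid dependency is generated in topological order
  cfg_chain <- synthetic_config(community = list(
    prey_rates = c(deer = 1),
    felids = list(a = list(intercept = 0, effort = 0, beta = c(b = 0.3)),
                  b = list(intercept = 0, effort = 0, beta = c(deer = 0.3)))))
  expect_silent(m2 <- simulate_community(st[1:100, ], cfg_chain, seed = 2))
  expect_setequal(colnames(m2), c("deer", "a", "b"))
})
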