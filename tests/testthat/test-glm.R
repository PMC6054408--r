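test_that("fit_logistic reproduces closed forms and IC arithmetic", {
  # balanced intercept-only fit: logit(0.5) = 0
  y <- rep(c(1, 0), each = 50)
  f0 <- fit_logistic(y, cbind("(Intercept)" = rep(1, 100)))
  expect_lt(abs(f0$coef[["(Intercept)"]]), 1e-6)

  # grouped 2x2 table (a,b,c,d) = (10,20,30,40): slope = log odds ratio
  y2 <- c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40))
  x2 <- c(rep(1, 30), rep(0, 70))
  f2 <- fit_logistic(y2, cbind("(Intercept)" = 1, x = x2))
  expect_equal(unname(f2$coef["x"]), log(10 * 40 / (20 * 30)),
               tolerance = 1e-4)

  expect_equal(f2$aic, 2 * f2$k - 2 * f2$loglik)
  expect_equal(f2$aicc,
               f2$aic + 2 * f2$k * (f2$k + 1) / (f2$n - f2$k - 1))
  # log-likelihood matches direct Bernoulli evaluation at the coefficients
  p_hat <- plogis(f2$coef[["(Intercept)"]] + f2$coef[["x"]] * x2)
  expect_equal(f2$loglik, sum(dbinom(y2, 1, p_hat, log = TRUE)),
               tolerance = 1e-8)

  # perfect separation is flagged non-converged
  sep <- fit_logistic(c(rep(0, 20), rep(1, 20)),
                      cbind("(Intercept)" = 1, x = c(rep(0, 20), rep(1, 20))))
  expect_false(sep$converged)
})

test_that("scale_scan picks the lowest-AIC scale, smallest radius on ties", {
  withr::with_seed(8, {
    x <- rnorm(300)
    y <- rbinom(300, 1, plogis(x))
  })
  base <- cbind("(Intercept)" = rep(1, 300))
  same <- setNames(rep(list(x), 7),
                   c("120", "240", "480", "960", "1920", "3840", "7680"))
  scan <- scale_scan(y, same, base, name = "v")
  expect_equal(scan$best_scale, 120)
  expect_equal(length(scan$aic), 7L)
  expect_true(all(abs(scan$aic - scan$aic[1]) < 1e-8))

  # signal at one scale only: that scale wins
  withr::with_seed(9, noise <- replicate(6, rnorm(300), simplify = FALSE))
  mixed <- c(noise[1:3], list(x), noise[4:6])
  names(mixed) <- c("120", "240", "480", "960", "1920", "3840", "7680")
  expect_equal(scale_scan(y, mixed, base, name = "v")$best_scale, 960)
})

test_that("screening retains p <= threshold and drops p > threshold", {
  fake <- function(name, p) structure(list(variable = name, best_p = p),
                                      class = "scale_scan")
  scans <- list(fake("keep", 0.19), fake("drop", 0.25), fake("edge", 0.2))
  expect_setequal(screen_variables(scans), c("keep", "edge"))
  expect_length(screen_variables(list()), 0L)
})

test_that("collinearity pruning drops the higher-AIC member of each tight pair", {
  withr::with_seed(5, x <- rnorm(200))
  X <- cbind(a = x, b = x)
  expect_equal(prune_collinear(X, c(a = 100, b = 90)), "b")

  Xr <- correlated_pair(200, 0.69)
  expect_setequal(prune_collinear(Xr, c(a = 100, b = 90)), c("a", "b"))
  Xr71 <- correlated_pair(200, 0.71)
  expect_equal(prune_collinear(Xr71, c(a = 100, b = 90)), "b")

  # three mutually identical columns cascade to the single lowest-AIC one
  X3 <- cbind(a = x, b = x, c = x)
  expect_equal(prune_collinear(X3, c(a = 100, b = 80, c = 90)), "b")
})

test_that("all-subsets ensemble enumerates 2^p subsets with normalized weights", {
  withr::with_seed(12, {
    X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("v1", "v2")))
    y <- rbinom(200, 1, plogis(X[, 1]))
  })
  forced <- cbind("(Intercept)" = rep(1, 200))
  ens <- all_subsets(y, X, forced)
  expect_length(ens$fits, 4L)
  expect_equal(length(unique(vapply(ens$masks, function(m)
    paste(as.integer(m), collapse = ""), ""))), 4L)
  expect_equal(sum(ens$weight), 1, tolerance = 1e-9)
  # weight identity and invariance to a constant shift of the criterion
  w_direct <- exp(-(ens$crit - min(ens$crit)) / 2)
  expect_equal(ens$weight, w_direct / sum(w_direct), tolerance = 1e-12)
  w_shift <- exp(-((ens$crit + 1000) - min(ens$crit + 1000)) / 2)
  expect_equal(ens$weight, w_shift / sum(w_shift), tolerance = 1e-12)
  # the canonical two-model case: deltas {0, 2} -> weights {0.731, 0.269}
  two <- exp(-c(0, 2) / 2); two <- two / sum(two)
  expect_equal(two, c(0.731, 0.269), tolerance = 1e-3)

  big <- matrix(rnorm(200 * 16), 200, 16,
                dimnames = list(NULL, paste0("t", 1:16)))
  expect_error(all_subsets(y, big, forced), "15")
})

test_that("full model averaging: zero substitution, unconditional SE, importance", {
  withr::with_seed(13, {
    X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("v1", "v2", "v3")))
    y <- rbinom(200, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
    eff <- rnorm(200, 100, 25)
  })
  forced <- cbind("(Intercept)" = 1, effort = eff)
  ens <- all_subsets(y, X, forced)
  av <- model_average(ens)

  expect_setequal(av$term, c("(Intercept)", "effort", "v1", "v2", "v3"))
  expect_equal(av$importance[av$term %in% c("(Intercept)", "effort")],
               c(1, 1), tolerance = 1e-12)
  expect_true(all(av$importance >= 0 & av$importance <= 1))

  # averaged beta and unconditional variance recomputed by hand for one term
  for (t in c("v1", "v3")) {
    beta_i <- vapply(ens$fits, function(f)
      if (t %in% names(f$coef)) unname(f$coef[t]) else 0, 0)
    se_i <- vapply(ens$fits, function(f)
      if (t %in% names(f$se)) unname(f$se[t]) else 0, 0)
    bbar <- sum(ens$weight * beta_i)
    v_u <- sum(ens$weight * (se_i^2 + (beta_i - bbar)^2))
    row <- av[av$term == t, ]
    expect_equal(row$estimate, bbar, tolerance = 1e-12)
    expect_equal(row$adj_se, sqrt(v_u), tolerance = 1e-12)
    # unconditional variance dominates the within-model part
    expect_gte(v_u, sum(ens$weight * se_i^2) - 1e-15)
  }

  # single-model ensemble: averaging returns that model
  ens1 <- all_subsets(y, X[, 0, drop = FALSE], forced)
  av1 <- model_average(ens1)
  f1 <- ens1$fits[[1]]
  expect_equal(av1$estimate, unname(f1$coef), tolerance = 1e-12)
  expect_equal(av1$adj_se, unname(f1$se), tolerance = 1e-12)
})
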