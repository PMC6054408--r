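survey <- small_survey()

make_small_matrix <- function(survey, seed = 99) {
  sim <- simulate_detections(survey$stack, survey$stations, survey$config,
                             seed = seed)
  counts <- cbind(focal_cat = sim$counts)
  detection_matrix(counts, setNames(survey$stations$effort,
                                    survey$stations$station_id))
}

test_that("habitat pipeline is deterministic and audits every stage", {
  mat <- make_small_matrix(survey)
  hm1 <- run_habitat_pipeline("focal_cat", survey$stack, survey$stations, mat,
                              scales = c(120, 240, 480, 960))
  hm2 <- run_habitat_pipeline("focal_cat", survey$stack, survey$stations, mat,
                              scales = c(120, 240, 480, 960))
  expect_identical(hm1$averaged, hm2$averaged)
  expect_named(hm1$scans, c("tree_cover", "human_footprint"))
  expect_true(all(c("(Intercept)", "effort") %in% hm1$averaged$term))
  # the generating covariate survives screening in this strong-signal setup
  expect_true("tree_cover" %in% hm1$pruned)
  expect_true(all(hm1$averaged$importance[
    hm1$averaged$term %in% c("(Intercept)", "effort")] == 1))
})

test_that("an impossible screen falls back to the forced-terms model", {
  mat <- make_small_matrix(survey)
  expect_warning(
    hm <- run_habitat_pipeline("focal_cat", survey$stack, survey$stations,
                               mat, scales = c(120, 240), p_screen = 1e-12),
    "screened out")
  expect_setequal(hm$averaged$term, c("(Intercept)", "effort"))
})

test_that("predicted surfaces reproduce the averaged model at the stations", {
  mat <- make_small_matrix(survey)
  hm <- run_habitat_pipeline("focal_cat", survey$stack, survey$stations, mat,
                             scales = c(120, 240, 480, 960))
  eff <- hm$effort_mean
  surf <- predict_surface(hm, survey$stack, effort_value = eff)
  expect_s3_class(surf, "occurrence_surface")
  v <- surf$values
  expect_true(all(v[is.finite(v)] >= 0 & v[is.finite(v)] <= 1))

  # model-side linear predictor recomputed from the averaged coefficients
  av <- setNames(hm$averaged$estimate, hm$averaged$term)
  z <- rep(av[["(Intercept)"]] + av[["effort"]] * eff,
           nrow(survey$stations))
  for (t in names(hm$covariates)) {
    info <- hm$covariates[[t]]
    sc <- extract_standardize(focal_mean(survey$stack[[t]], info$scale),
                              survey$stations, standardize = FALSE)
    z <- z + av[[t]] * (sc$values - info$center) / info$sd
  }
  idx <- felidniche:::cell_index(surf, survey$stations$x, survey$stations$y)
  expect_equal(unname(v[idx]), unname(plogis(z)), tolerance = 1e-10)
})

test_that("intercept-only surfaces are flat at the logistic of the intercept", {
  hm <- structure(list(
    species = "toy",
    averaged = data.frame(term = c("(Intercept)", "effort"),
                          estimate = c(-2.2348, 0), adj_se = 1, z = 1, p = 1,
                          importance = 1),
    covariates = list(), effort_mean = 0), class = "habitat_model")
  surf <- predict_surface(hm, survey$stack["tree_cover"])
  expect_equal(unique(as.vector(surf$values)), plogis(-2.2348),
               tolerance = 1e-6)
  expect_lt(abs(plogis(-2.2348) - 0.0967), 1e-4)
})

test_that("surface comparison matches elementwise arithmetic", {
  a <- eco_raster(matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9),
                         3, 3), cell_size = 10)
  same <- compare_surfaces(a, a)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$mean_abs_diff, 0)

  b <- eco_raster(1 - a$values, cell_size = 10)
  expect_equal(compare_surfaces(a, b)$pearson_r, -1)

  withr::with_seed(71, bv <- matrix(runif(9), 3, 3))
  b2 <- eco_raster(bv, cell_size = 10)
  cmp <- compare_surfaces(a, b2)
  expect_equal(cmp$pearson_r, cor(as.vector(a$values), as.vector(bv)))
  expect_equal(cmp$mean_abs_diff, mean(abs(a$values - bv)))

  const <- eco_raster(matrix(0.5, 3, 3), cell_size = 10)
  cmp_c <- compare_surfaces(a, const)
  expect_true(is.na(cmp_c$pearson_r))
  expect_equal(cmp_c$mean_abs_diff, mean(abs(a$values - 0.5)))
})

test_that("road/ridge univariate association delegates to the logistic core", {
  withr::with_seed(81, {
    flag <- rbinom(1000, 1, 0.3)
    y <- rbinom(1000, 1, plogis(-0.5 + 0.8 * flag))
  })
  ua <- univariate_association(y, flag, name = "road")
  direct <- fit_logistic(y, cbind("(Intercept)" = 1, road = flag))
  expect_equal(ua$coef, direct$coef)
  expect_equal(ua$aic, direct$aic)

  # null flag: the Wald test is calibrated (about 5% false positives) and
  # estimated effects are centred on zero
  null_stats <- withr::with_seed(82, replicate(100, {
    fl <- rbinom(1000, 1, 0.5)
    yy <- rbinom(1000, 1, 0.5)
    f <- univariate_association(yy, fl)
    c(coef = f$coef[["flag"]], p = f$p[["flag"]])
  }))
  expect_lte(sum(null_stats["p", ] < 0.05), 12)
  expect_lt(abs(mean(null_stats["coef", ])), 0.05)
  expect_lt(mean(abs(null_stats["coef", ])), 0.2)

  # detections only at flagged stations: separation flagged
  sep <- univariate_association(flag, flag)
  expect_false(sep$converged)
  expect_error(univariate_association(y, rep(1, 1000)), "both levels")
})

test_that("co-occurrence models cap candidates by univariate AICc pre-screening", {
  n <- 120
  withr::with_seed(91, {
    prey <- matrix(rpois(n * 20, 3), n, 20,
                   dimnames = list(sprintf("S%03d", 1:n), paste0("prey", 1:20)))
    felid <- rbinom(n, 1, plogis(-0.5 + 0.4 * prey[, 1]))
    eff <- round(rnorm(n, 100, 15), 1)
  })
  counts <- cbind(prey, felid = felid)
  mat <- detection_matrix(counts, setNames(eff, rownames(counts)))
  st <- data.frame(station_id = rownames(counts), x = 1, y = 1,
                   effort = eff, stringsAsFactors = FALSE)
  cm <- prey_cooccurrence_model("felid", mat, st, cap = 4)
  expect_length(cm$candidates, 4L)
  expect_equal(cm$prescreened_from, 20L)
  # the true driver survives the AICc pre-screen
  expect_true("prey1" %in% cm$candidates)
  expect_true(all(c("(Intercept)", "effort") %in% cm$averaged$term))
  expect_error(prey_cooccurrence_model("ghost", mat, st), "not in")
})
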