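# Shared fixtures, all generated in code.

# Brute-force focal mean: double loop over cells and window candidates.
brute_focal <- function(m, cell, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- numeric(0)
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      if (sqrt((a - i)^2 + (b - j)^2) * cell <= radius && !is.na(m[a, b]))
        acc <- c(acc, m[a, b])
    }
    if (length(acc)) out[i, j] <- mean(acc)
  }
  out
}

# Detection records from a compact spec: station, species, "HH:MM" times on
# one day (or full timestamps).
make_records <- function(station, species, times, day = "2024-03-01") {
  ts <- ifelse(grepl(" ", times), times, paste(day, times))
  data.frame(station_id = station, species = species, timestamp = ts,
             stringsAsFactors = FALSE)
}

# Minimal station table.
demo_stations <- function(n, effort = 100) {
  data.frame(station_id = sprintf("S%03d", seq_len(n)),
             x = seq_len(n) * 10, y = seq_len(n) * 10,
             elevation = 100, effort = rep_len(effort, n),
             road = rep_len(c(TRUE, FALSE), n),
             ridge = rep_len(c(FALSE, TRUE), n),
             area_id = "A01", stringsAsFactors = FALSE)
}

# Two columns with an exact empirical Pearson correlation rho.
correlated_pair <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    u <- stats::rnorm(n); v <- stats::rnorm(n)
    u <- (u - mean(u)) / stats::sd(u)
    v <- stats::residuals(stats::lm(v ~ u))
    v <- (v - mean(v)) / stats::sd(v)
    cbind(a = u, b = rho * u + sqrt(1 - rho^2) * v)
  })
}

# Small landscape + stations for pipeline-level tests.
small_survey <- function(seed = 11, n_stations = 150, extent = 64,
                         covs = NULL) {
  if (is.null(covs))
    covs <- list(
      list(name = "tree_cover", kind = "continuous", range = 240),
      list(name = "human_footprint", kind = "continuous", range = 600))
  cfg <- synthetic_config(extent_cells = extent, n_stations = n_stations,
                          covariates = covs, n_clusters = 5,
                          true_scales = c(tree_cover = 480),
                          true_beta = c("(Intercept)" = -0.2, tree_cover = 1.0,
                                        effort = 0.004),
                          seed = seed)
  list(config = cfg,
       stack = generate_covariate_stack(cfg, seed = seed),
       stations = place_stations(cfg, seed = seed + 1L))
}
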