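# Synthetic landscape / survey generator. Emulates the statistical structure
# the downstream analysis assumes: spatially autocorrelated covariate rasters,
# clustered station placement over multiple survey areas, occurrence as a
# logistic function of focal-window covariates at species-specific scales plus
# a trap-effort term, zero-truncated detection counts, von Mises mixture
# detection times, and multi-species matrices with known co-occurrence effects.

#' Configuration for the synthetic survey generator
#'
#' Defaults describe a survey of the scale the pipeline targets: 578 stations
#' clustered in 10 survey areas, mean effort 125 trap-nights per station, a
#' 128 x 128 landscape at 120 m resolution, and diel archetypes (nocturnal,
#' diurnal, crepuscular, cathemeral) as von Mises mixtures.
#'
#' @param extent_cells Grid width/height in cells (>= 16).
#' @param cell_size Metres per cell (> 0).
#' @param covariates List of covariate specs: each a list with `name`,
#'   `kind` (`"continuous"`/`"categorical"`), `range` (autocorrelation range,
#'   m; 0 = white noise) and, for categorical layers, `threshold` (the target
#'   class fraction, in (0,1): cells above the complementary quantile of the
#'   smoothed field form the class).
#' @param n_stations Number of camera stations (>= 2).
#' @param n_clusters,cluster_sd Number of station clusters (survey areas) and
#'   their within-cluster dispersion (m).
#' @param true_scales Named vector: generating focal radius (m) per covariate
#'   used in `true_beta`.
#' @param true_beta Named vector of logit-scale effects for standardized
#'   covariates, plus `"(Intercept)"` and `"effort"` (per trap-night, raw).
#' @param effort_mean,effort_sd Trap-night distribution per station
#'   (truncated > 0).
#' @param count_mean Mean of the extra Poisson component of detection counts
#'   given presence (counts are `presence * (1 + Poisson)`).
#' @param p_road,p_ridge Probability a station sits on a logging road /
#'   ridgeline.
#' @param activity Named list of von Mises mixtures, each a list with equal
#'   length numeric `weights` (sum 1), `means` (radians) and `kappas` (>= 0).
#' @param community Co-occurrence generator: list with `prey_rates` (named
#'   mean detection counts per station) and `felids`, a named list of
#'   `list(intercept=, effort=, beta=)` where `beta` is a named vector of
#'   per-detection logit effects of predictor columns (prey, or previously
#'   generated felids - dependencies must be acyclic).
#' @param seed Default integer seed; every generator also accepts an explicit
#'   one.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(extent_cells = 128,
                             cell_size = 120,
                             covariates = list(
                               list(name = "tree_cover", kind = "continuous", range = 720),
                               list(name = "elevation", kind = "continuous", range = 1680),
                               list(name = "human_footprint", kind = "continuous", range = 2400),
                               list(name = "dipterocarp_forest", kind = "categorical",
                                    range = 960, threshold = 0.5)),
                             n_stations = 578,
                             n_clusters = 10,
                             cluster_sd = 1500,
                             true_scales = c(tree_cover = 960, human_footprint = 3840,
                                             elevation = 120),
                             true_beta = c("(Intercept)" = -1.5, tree_cover = 1.0,
                                           human_footprint = -0.7, elevation = 0.45,
                                           effort = 0.006),
                             effort_mean = 125,
                             effort_sd = 40,
                             count_mean = 2,
                             p_road = 0.3,
                             p_ridge = 0.25,
                             activity = list(
                               nocturnal = list(weights = 1, means = 0, kappas = 1.5),
                               diurnal = list(weights = 1, means = pi, kappas = 1.5),
                               crepuscular = list(weights = c(0.5, 0.5),
                                                  means = c(pi / 2, 3 * pi / 2),
                                                  kappas = c(6, 6)),
                               cathemeral = list(weights = c(0.6, 0.4),
                                                 means = c(0, pi),
                                                 kappas = c(0.8, 0.3))),
                             community = list(
                               prey_rates = c(mousedeer = 3, porcupine = 1.5,
                                              civet = 2, macaque = 2.5),
                               felids = list(
                                 clouded_leopard = list(
                                   intercept = -1.2, effort = 0.004,
                                   beta = c(mousedeer = 0.25, porcupine = 0.3)),
                                 leopard_cat = list(
                                   intercept = -0.8, effort = 0.004,
                                   beta = c(civet = 0.3)))),
                             seed = 1L) {
  cfg <- list(extent_cells = as.integer(extent_cells), cell_size = cell_size,
              covariates = covariates, n_stations = as.integer(n_stations),
              n_clusters = as.integer(n_clusters), cluster_sd = cluster_sd,
              true_scales = true_scales, true_beta = true_beta,
              effort_mean = effort_mean, effort_sd = effort_sd,
              count_mean = count_mean, p_road = p_road, p_ridge = p_ridge,
              activity = activity, community = community, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$extent_cells < 16L) stop("`extent_cells` must be >= 16")
  if (cfg$cell_size <= 0) stop("`cell_size` must be > 0")
  if (cfg$n_stations < 2L) stop("`n_stations` must be >= 2")
  for (cv in cfg$covariates) {
    if (!all(c("name", "kind", "range") %in% names(cv)))
      stop("each covariate spec needs name, kind and range")
    if (cv$range < 0) stop("autocorrelation range must be non-negative: ", cv$name)
    if (cv$kind == "categorical") {
      if (is.null(cv$threshold) || cv$threshold <= 0 || cv$threshold >= 1)
        stop("categorical layer needs a class threshold quantile in (0,1): ",
             cv$name)
    } else if (cv$kind != "continuous") {
      stop("unknown covariate kind: ", cv$kind)
    }
  }
  for (sp in names(cfg$activity)) {
    a <- cfg$activity[[sp]]
    if (length(a$weights) != length(a$means) ||
        length(a$weights) != length(a$kappas))
      stop("activity mixture components mismatched for ", sp)
    if (abs(sum(a$weights) - 1) > 1e-9)
      stop("activity mixture weights must sum to 1 for ", sp)
    if (any(a$kappas < 0)) stop("concentrations must be >= 0 for ", sp)
  }
  invisible(cfg)
}

# ---- covariate fields --------------------------------------------------------

gaussian_kernel2 <- function(sigma_cells) {
  half <- max(1L, ceiling(3 * sigma_cells))
  g <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  outer(g, g)
}

smooth_field <- function(x, sigma_cells) {
  if (sigma_cells <= 0) return(x)
  k <- gaussian_kernel2(sigma_cells)
  num <- conv2_same(x, k)
  den <- conv2_same(matrix(1, nrow(x), ncol(x)), k)
  num / den
}

#' Generate the synthetic covariate raster stack
#'
#' Continuous layers are Gaussian-smoothed white noise (smoothing length =
#' the layer's autocorrelation range), z-scored over cells. Categorical
#' layers are 0/1 indicators obtained by thresholding a smoothed field at the
#' configured quantile (1 = above the threshold).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (default: `config$seed`).
#' @return Named list of [eco_raster()] layers on a shared grid.
#' @export
generate_covariate_stack <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  n <- config$extent_cells
  withr::with_seed(seed, {
    out <- lapply(config$covariates, function(cv) {
      z <- matrix(stats::rnorm(n * n), n, n)
      f <- smooth_field(z, cv$range / config$cell_size)
      if (cv$kind == "categorical") {
        cut <- stats::quantile(f, 1 - cv$threshold, names = FALSE)
        m <- (f > cut) * 1
        eco_raster(m, config$cell_size, name = cv$name, kind = "indicator")
      } else {
        m <- (f - mean(f)) / stats::sd(f)
        eco_raster(m, config$cell_size, name = cv$name, kind = "continuous")
      }
    })
    names(out) <- vapply(config$covariates, `[[`, "", "name")
    out
  })
}

# ---- stations ----------------------------------------------------------------

#' Place clustered camera stations
#'
#' Cluster centres (one per survey area) are uniform over the interior of the
#' landscape; stations scatter around them with Gaussian dispersion, redrawn
#' until inside the extent. Effort is truncated-normal trap-nights (> 0).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (default: `config$seed`).
#' @return A station table (`data.frame`): `station_id`, `x`, `y`,
#'   `elevation`, `effort`, `road`, `ridge`, `area_id`.
#' @export
place_stations <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  ext <- config$extent_cells * config$cell_size
  margin <- min(config$cluster_sd, ext / 4)
  withr::with_seed(seed, {
    cx <- stats::runif(config$n_clusters, margin, ext - margin)
    cy <- stats::runif(config$n_clusters, margin, ext - margin)
    cl <- sort(rep_len(seq_len(config$n_clusters), config$n_stations))
    draw_in <- function(centre) {
      repeat {
        p <- stats::rnorm(1, centre, config$cluster_sd)
        if (p >= 0 && p < ext) return(p)
      }
    }
    x <- vapply(cl, function(i) draw_in(cx[i]), 0)
    y <- vapply(cl, function(i) draw_in(cy[i]), 0)
    effort <- stats::rnorm(config$n_stations, config$effort_mean, config$effort_sd)
    while (any(effort <= 0))
      effort[effort <= 0] <- stats::rnorm(sum(effort <= 0), config$effort_mean,
                                          config$effort_sd)
    data.frame(
      station_id = sprintf("S%04d", seq_len(config$n_stations)),
      x = x, y = y,
      elevation = 200 + 800 * y / ext + stats::rnorm(config$n_stations, 0, 50),
      effort = round(effort, 1),
      road = stats::rbinom(config$n_stations, 1, config$p_road) == 1,
      ridge = stats::rbinom(config$n_stations, 1, config$p_ridge) == 1,
      area_id = sprintf("A%02d", cl),
      stringsAsFactors = FALSE)
  })
}

# ---- occurrence / detections -------------------------------------------------

# Station-level design implied by true_scales/true_beta: focal value of each
# covariate at its generating scale, standardized across stations.
station_true_design <- function(stack, stations, config) {
  vars <- setdiff(names(config$true_beta), c("(Intercept)", "effort"))
  missing <- setdiff(vars, names(stack))
  if (length(missing))
    stop("unknown covariate(s) in true_beta: ", paste(missing, collapse = ", "))
  cols <- lapply(vars, function(v) {
    sc <- config$true_scales[[v]]
    if (is.null(sc)) stop("no true scale configured for ", v)
    extract_standardize(focal_mean(stack[[v]], sc), stations, scale_m = sc)$values
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vars
  X
}

#' Simulate occurrence and detection counts for one species
#'
#' Presence at each station is Bernoulli with logit equal to the configured
#' intercept plus standardized focal covariates at their generating scales
#' plus the (raw trap-night) effort term; counts are `presence * (1 +
#' Poisson(count_mean))` (zero-truncated given presence).
#'
#' @param stack Covariate stack from [generate_covariate_stack()].
#' @param stations Station table from [place_stations()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List: `counts`, `presence`, `prob` (named by station), `design`
#'   (the standardized generating design matrix).
#' @export
simulate_detections <- function(stack, stations, config, seed = config$seed) {
  X <- station_true_design(stack, stations, config)
  beta <- config$true_beta
  z <- rep(beta[["(Intercept)"]], nrow(stations))
  if (ncol(X)) z <- z + drop(X %*% beta[colnames(X)])
  if ("effort" %in% names(beta)) z <- z + beta[["effort"]] * stations$effort
  prob <- stats::plogis(z)
  withr::with_seed(seed, {
    presence <- stats::rbinom(nrow(stations), 1, prob)
    extra <- stats::rpois(nrow(stations), config$count_mean)
    counts <- presence * (1 + extra)
  })
  names(counts) <- names(presence) <- names(prob) <- stations$station_id
  list(counts = counts, presence = presence, prob = prob, design = X)
}

# ---- activity times ----------------------------------------------------------

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` is the circular uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (>= 0).
#' @return Angles in `[0, 2 * pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(keep)
    if (nk) {
      theta <- sign(stats::runif(nk) - 0.5) * acos(pmin(1, pmax(-1, f[keep])))
      out[got + seq_len(nk)] <- theta
      got <- got + nk
    }
  }
  (out + mu) %% (2 * pi)
}

#' Simulate diel detection times for a species archetype
#'
#' @param species Name of an entry in `config$activity`.
#' @param n Number of detection times (>= 1).
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return An `activity_sample`: angles in `[0, 2 * pi)` (midnight = 0,
#'   noon = pi).
#' @export
simulate_activity_times <- function(species, n, config, seed = config$seed) {
  if (!species %in% names(config$activity))
    stop("no activity mixture configured for species: ", species)
  if (n < 1) stop("`n` must be >= 1")
  mix <- config$activity[[species]]
  withr::with_seed(seed, {
    comp <- sample.int(length(mix$weights), n, replace = TRUE,
                       prob = mix$weights)
    ang <- numeric(n)
    for (j in unique(comp)) {
      sel <- comp == j
      ang[sel] <- rvonmises(sum(sel), mix$means[j], mix$kappas[j])
    }
    activity_sample(ang, species = species)
  })
}

# ---- multi-species community -------------------------------------------------

# Order felids so every dependency on another felid is generated first.
felid_order <- function(felids) {
  names_f <- names(felids)
  deps <- lapply(felids, function(f) intersect(names(f$beta), names_f))
  ord <- character(0)
  remaining <- names_f
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(f)
      all(deps[[f]] %in% ord), TRUE)]
    if (!length(ready))
      stop("cyclic felid-on-felid co-occurrence dependency: ",
           paste(remaining, collapse = ", "))
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  ord
}

#' Simulate a multi-species detection matrix with known co-occurrence effects
#'
#' Prey counts are independent Poisson per station; each felid's presence is
#' Bernoulli with logit = intercept + per-detection co-occurrence effects
#' times predictor counts + effort term, and its counts are zero-truncated
#' given presence. Felids may depend on previously generated felids but not
#' cyclically.
#'
#' @param stations Station table from [place_stations()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A `detection_matrix` (stations x species) with effort attached.
#' @export
simulate_community <- function(stations, config, seed = config$seed) {
  stopifnot(all(stations$effort > 0))
  comm <- config$community
  ord <- felid_order(comm$felids)
  n <- nrow(stations)
  withr::with_seed(seed, {
    cols <- lapply(comm$prey_rates, function(lam) stats::rpois(n, lam))
    names(cols) <- names(comm$prey_rates)
    for (f in ord) {
      sp <- comm$felids[[f]]
      preds <- names(sp$beta)
      missing <- setdiff(preds, names(cols))
      if (length(missing))
        stop("co-occurrence predictors without a count process: ",
             paste(missing, collapse = ", "))
      z <- sp$intercept + sp$effort * stations$effort
      for (p in preds) z <- z + sp$beta[[p]] * cols[[p]]
      pres <- stats::rbinom(n, 1, stats::plogis(z))
      cols[[f]] <- pres * (1 + stats::rpois(n, config$count_mean))
    }
    m <- do.call(cbind, cols)
    rownames(m) <- stations$station_id
    detection_matrix(m, effort = stats::setNames(stations$effort,
                                                 stations$station_id))
  })
}
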