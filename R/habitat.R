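# Per-species habitat pipeline: scale optimization -> screening -> pruning ->
# all-subsets averaging; occurrence surfaces and their comparison; road/ridge
# univariate associations; felid/candidate-prey co-occurrence ensembles.

#' Explode a multi-class categorical raster into per-class indicators
#'
#' Habitat classes are modelled as separate 0/1 variables (class proportion
#' after focal averaging), so rasters holding several integer class codes are
#' split into one indicator layer per class before scaling.
#'
#' @param raster An [eco_raster()] with integer class codes.
#' @param classes Codes to explode (default: all observed).
#' @return Named list of indicator `eco_raster`s (`name.class`).
#' @export
explode_categorical <- function(raster, classes = NULL) {
  v <- raster$values
  if (is.null(classes)) classes <- sort(unique(v[!is.na(v)]))
  out <- lapply(classes, function(cl) {
    m <- (v == cl) * 1
    eco_raster(m, raster$cell_size, raster$xll, raster$yll,
               name = paste(raster$name, cl, sep = "."), kind = "indicator")
  })
  names(out) <- paste(raster$name, classes, sep = ".")
  out
}

#' Run the multi-scale habitat pipeline for one species
#'
#' Executes, in order: focal statistics at every analysis scale, station
#' extraction with standardization, univariate scale scan per covariate
#' (lowest-AIC scale), p-value screening, collinearity pruning, all-subsets
#' logistic regression with the intercept and effort forced, and full model
#' averaging. All intermediate artifacts are returned for audit.
#'
#' @param species Column of `matrix` to model (detected/not detected).
#' @param rasters Named list of [eco_raster()] covariate layers.
#' @param stations Station table aligned with `matrix` rows.
#' @param matrix A [detection_matrix()].
#' @param scales Analysis radii in metres (default the 120--7680 m ladder).
#' @param p_screen Univariate screening threshold (default 0.2).
#' @param r_prune Collinearity threshold on `|Pearson r|` (default 0.7).
#' @param criterion Ensemble information criterion (`"AICc"` default).
#' @param scaled Optional precomputed result of `lapply(rasters, scale_stack)`
#'   to reuse across species.
#' @return A `habitat_model`: `scans`, `screened`, `pruned`, `ensemble`,
#'   `averaged`, per-term scale and standardization constants, and the forced
#'   effort statistics used for prediction.
#' @export
run_habitat_pipeline <- function(species, rasters, stations, matrix,
                                 scales = c(120, 240, 480, 960, 1920, 3840, 7680),
                                 p_screen = 0.2, r_prune = 0.7,
                                 criterion = c("AICc", "AIC"),
                                 scaled = NULL) {
  criterion <- match.arg(criterion)
  if (!species %in% colnames(matrix))
    stop("species not in detection matrix: ", species)
  if (!identical(rownames(matrix), stations$station_id))
    stop("detection matrix rows must match the station table")
  y <- as.integer(unclass(matrix)[, species] > 0)
  X_forced <- cbind("(Intercept)" = 1, effort = stations$effort)

  if (is.null(scaled)) scaled <- lapply(rasters, scale_stack, scales = scales)
  station_vals <- lapply(names(rasters), function(nm) {
    lapply(stats::setNames(as.character(scales), as.character(scales)),
           function(s) extract_standardize(scaled[[nm]][[s]], stations,
                                           scale_m = as.numeric(s)))
  })
  names(station_vals) <- names(rasters)
  degenerate <- vapply(station_vals, function(vs)
    all(vapply(vs, `[[`, TRUE, "degenerate")), TRUE)
  if (any(degenerate))
    warning("degenerate covariate(s) excluded: ",
            paste(names(rasters)[degenerate], collapse = ", "))
  usable <- names(rasters)[!degenerate]

  scans <- lapply(usable, function(nm)
    scale_scan(y, station_vals[[nm]], X_forced, name = nm))
  names(scans) <- usable

  screened <- screen_variables(scans, p_threshold = p_screen)
  if (!length(screened)) {
    warning("all covariates screened out; returning forced-terms-only model")
    ens <- all_subsets(y, matrix(numeric(0), nrow = length(y), ncol = 0),
                       X_forced, criterion = criterion)
    return(structure(list(species = species, scans = scans,
                          screened = character(0), pruned = character(0),
                          ensemble = ens, averaged = model_average(ens),
                          covariates = list(),
                          effort_mean = mean(stations$effort)),
                     class = "habitat_model"))
  }

  best_cov <- lapply(screened, function(nm)
    station_vals[[nm]][[as.character(scans[[nm]]$best_scale)]])
  names(best_cov) <- screened
  X_best <- do.call(cbind, lapply(best_cov, `[[`, "values"))
  colnames(X_best) <- screened
  best_aic <- vapply(scans[screened], function(s) min(s$aic, na.rm = TRUE), 0)

  pruned <- prune_collinear(X_best, best_aic, r_threshold = r_prune)
  X_free <- X_best[, pruned, drop = FALSE]

  ens <- all_subsets(y, X_free, X_forced, criterion = criterion)
  structure(list(species = species, scans = scans, screened = screened,
                 pruned = pruned, ensemble = ens,
                 averaged = model_average(ens),
                 covariates = lapply(best_cov[pruned], function(cv)
                   list(scale = cv$scale, center = cv$center, sd = cv$sd)),
                 effort_mean = mean(stations$effort)),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("<habitat_model> %s: %d scanned -> %d screened -> %d pruned terms\n",
              x$species, length(x$scans), length(x$screened), length(x$pruned)))
  av <- x$averaged
  av$scale_m <- vapply(av$term, function(t)
    if (t %in% names(x$covariates)) x$covariates[[t]]$scale else NA_real_, 0)
  print(cbind(av["term"], round(av[c("estimate", "adj_se", "z", "p",
                                     "importance", "scale_m")], 4)))
  invisible(x)
}

#' Predict a probability-of-occurrence surface
#'
#' Per cell, `z` is the averaged intercept plus each averaged coefficient
#' times the covariate's focal value at its optimal scale (standardized with
#' the constants from the fitting stations) plus the effort coefficient times
#' a fixed effort value; the surface is `p = exp(z) / (1 + exp(z))`. Nodata
#' propagates.
#'
#' @param model A [run_habitat_pipeline()] result.
#' @param rasters The covariate stack used to fit the model.
#' @param effort_value Fixed effort entered in the prediction (default: mean
#'   station effort from fitting).
#' @param scaled Optional precomputed `lapply(rasters, scale_stack)`.
#' @return An `occurrence_surface` (an [eco_raster()] of probabilities).
#' @export
predict_surface <- function(model, rasters, effort_value = model$effort_mean,
                            scaled = NULL) {
  stopifnot(inherits(model, "habitat_model"))
  av <- model$averaged
  beta <- stats::setNames(av$estimate, av$term)
  terms <- setdiff(av$term, c("(Intercept)", "effort"))
  missing <- setdiff(terms, names(rasters))
  if (length(missing))
    stop("no raster supplied for model term(s): ",
         paste(missing, collapse = ", "))
  template <- if (length(rasters)) rasters[[1]] else
    stop("need at least one raster to define the grid")
  z <- matrix(beta[["(Intercept)"]] + beta[["effort"]] * effort_value,
              nrow(template$values), ncol(template$values))
  for (t in terms) {
    info <- model$covariates[[t]]
    layer <- if (!is.null(scaled))
      scaled[[t]][[as.character(info$scale)]]
    else focal_mean(rasters[[t]], info$scale)
    std <- (layer$values - info$center) / info$sd
    z <- z + beta[[t]] * std
  }
  p <- stats::plogis(z)
  out <- eco_raster(p, template$cell_size, template$xll, template$yll,
                    name = paste0("p_occurrence_", model$species))
  attr(out, "species") <- model$species
  attr(out, "provenance") <- list(
    terms = av$term, coefficients = beta,
    scales = vapply(model$covariates, `[[`, 0, "scale"),
    effort_value = effort_value)
  class(out) <- c("occurrence_surface", class(out))
  out
}

#' Compare two occurrence surfaces
#'
#' Pearson correlation and mean absolute difference of the probabilities over
#' cells finite in both surfaces. If either surface is constant the
#' correlation is undefined and returned as `NA` (the mean absolute
#' difference is still computed).
#'
#' @param a,b Occurrence surfaces ([predict_surface()]) on a shared grid.
#' @return A `surface_comparison`: `pearson_r`, `mean_abs_diff`, `n_cells`.
#' @export
compare_surfaces <- function(a, b) {
  if (!raster_compatible(a, b)) stop("surfaces must share the grid")
  va <- a$values; vb <- b$values
  ok <- is.finite(va) & is.finite(vb)
  if (!any(ok)) stop("no jointly finite cells")
  va <- va[ok]; vb <- vb[ok]
  r <- if (stats::sd(va) < 1e-15 || stats::sd(vb) < 1e-15) NA_real_
  else stats::cor(va, vb)
  structure(list(species = c(attr(a, "species"), attr(b, "species")),
                 pearson_r = r, mean_abs_diff = mean(abs(va - vb)),
                 n_cells = sum(ok)),
            class = "surface_comparison")
}

#' @export
print.surface_comparison <- function(x, ...) {
  cat(sprintf("<surface_comparison> %s vs %s: r = %s, mean |diff| = %.4f (%d cells)\n",
              x$species[1], x$species[2],
              if (is.na(x$pearson_r)) "undefined (constant surface)"
              else sprintf("%.4f", x$pearson_r),
              x$mean_abs_diff, x$n_cells))
  invisible(x)
}

#' Univariate association with a fine-scale station attribute
#'
#' Logistic regression of occurrence on a single 0/1 station flag (logging
#' road, ridgeline). Complete separation is reported through the fit's
#' `converged` flag.
#'
#' @param y 0/1 occurrence vector.
#' @param flag Logical/0-1 station attribute; both levels must be present.
#' @param name Label for the flag coefficient.
#' @return A `logit_fit`.
#' @export
univariate_association <- function(y, flag, name = "flag") {
  flag <- as.numeric(flag)
  if (length(unique(flag)) < 2L)
    stop("`flag` must have both levels present")
  X <- cbind("(Intercept)" = 1, flag)
  colnames(X)[2] <- name
  fit_logistic(y, X)
}

#' Felid / candidate-prey co-occurrence ensemble
#'
#' Models a felid's per-station occurrence (detected / not detected) as a
#' function of the raw independent detection counts of candidate prey
#' species, with effort forced. Candidates must pass the minimum-detection
#' filter; if more than `cap` remain they are pre-screened to the `cap` best
#' by univariate AICc (a documented gap-filling step, recorded in the
#' output).
#'
#' @param felid Column of `matrix` to predict.
#' @param matrix A [detection_matrix()] holding felid and prey counts.
#' @param stations Station table aligned with `matrix` rows.
#' @param min_detections Candidate filter threshold (default 20).
#' @param cap Maximum free terms entering all-subsets (default 15).
#' @param exclude Species never used as predictors (default: the felid).
#' @param criterion Ensemble information criterion.
#' @return A `cooccurrence_model`: ensemble, averaged table, candidates used
#'   and pre-screening provenance.
#' @export
prey_cooccurrence_model <- function(felid, matrix, stations,
                                    min_detections = 20, cap = 15,
                                    exclude = felid,
                                    criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  if (!felid %in% colnames(matrix))
    stop("felid not in detection matrix: ", felid)
  if (!identical(rownames(matrix), stations$station_id))
    stop("detection matrix rows must match the station table")
  y <- as.integer(unclass(matrix)[, felid] > 0)
  candidates <- setdiff(filter_min_detections(matrix, min_detections), exclude)
  if (!length(candidates)) stop("no candidate passes the detection filter")
  X_forced <- cbind("(Intercept)" = 1, effort = stations$effort)
  prescreened_from <- length(candidates)
  if (length(candidates) > cap) {
    aicc <- vapply(candidates, function(sp) {
      X <- cbind(X_forced, unclass(matrix)[, sp])
      colnames(X)[3] <- sp
      f <- fit_logistic(y, X)
      if (f$converged) f$aicc else Inf
    }, 0)
    candidates <- names(sort(aicc))[seq_len(cap)]
  }
  X_free <- unclass(matrix)[, candidates, drop = FALSE]
  storage.mode(X_free) <- "double"
  ens <- all_subsets(y, X_free, X_forced, criterion = criterion)
  structure(list(felid = felid, candidates = candidates,
                 prescreened_from = prescreened_from,
                 cap = cap, ensemble = ens, averaged = model_average(ens)),
            class = "cooccurrence_model")
}

#' @export
print.cooccurrence_model <- function(x, ...) {
  cat(sprintf("<cooccurrence_model> %s ~ %d candidate(s)%s\n",
              x$felid, length(x$candidates),
              if (x$prescreened_from > length(x$candidates))
                sprintf(" (pre-screened from %d by univariate AICc)",
                        x$prescreened_from) else ""))
  av <- x$averaged
  print(cbind(av["term"],
              round(av[c("importance", "estimate", "adj_se", "z", "p")], 4)))
  invisible(x)
}
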