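# Validated readers/writers for the interchange formats, the run
# configuration, and the staged pipeline driver.

#' Default run configuration
#'
#' All thresholds of the analysis in one place: screening p (0.2),
#' collinearity r (0.7), candidate minimum detections (20), the
#' Delta 1 / Delta 4 sample-size cutoff (75), bootstrap replicates (10000)
#' and CI level (95), the seven analysis radii, and the independence gap
#' (1 h). Values can be overridden from a YAML file or an override list.
#'
#' @param path Optional YAML file with overrides.
#' @param overrides Optional named list of overrides (applied after the
#'   file).
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    stations = NULL, detections = NULL, raster_dir = NULL,
    output_dir = "output", seed = 1L,
    scales = c(120, 240, 480, 960, 1920, 3840, 7680),
    min_gap = 3600, p_screen = 0.2, r_prune = 0.7, min_detections = 20,
    size_cutoff = 75, bootstrap_B = 10000, ci_level = 95,
    adjust = 1.0, grid_m = 128, criterion = "AICc", cap = 15,
    focal_species = c("clouded_leopard", "leopard_cat"),
    species_activity = list(clouded_leopard = "cathemeral",
                            leopard_cat = "nocturnal",
                            mousedeer = "diurnal", porcupine = "nocturnal",
                            civet = "nocturnal", macaque = "diurnal"),
    groups = list())
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  if (!is.null(overrides)) cfg[names(overrides)] <- overrides
  stopifnot(cfg$p_screen > 0, cfg$p_screen < 1,
            cfg$r_prune > 0, cfg$r_prune < 1,
            cfg$min_detections >= 0, cfg$size_cutoff >= 2,
            cfg$bootstrap_B >= 1, cfg$ci_level > 50, cfg$ci_level < 100,
            !is.unsorted(cfg$scales, strictly = TRUE), all(cfg$scales > 0))
  class(cfg) <- "run_config"
  cfg
}

# ---- tabular readers/writers -------------------------------------------------

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Read / write the station table
#'
#' CSV columns: `station_id`, `x`, `y` (projected metres), `effort`
#' (trap-nights, > 0); optional `elevation`, `road`, `ridge`, `area_id`.
#'
#' @param path CSV path.
#' @return Validated station `data.frame`.
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("station_id", "x", "y", "effort"), "station table")
  if (anyDuplicated(df$station_id))
    stop("duplicate station_id(s): ",
         paste(unique(df$station_id[duplicated(df$station_id)]), collapse = ", "))
  if (any(df$effort <= 0)) stop("station effort must be > 0")
  for (col in c("road", "ridge"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' @rdname read_stations
#' @param stations Station table.
#' @export
write_stations <- function(stations, path) {
  utils::write.csv(stations, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write detection records
#'
#' CSV columns: `station_id`, `species`, `timestamp` (ISO 8601 local clock).
#' Species labels are case-normalized to lower case.
#'
#' @param path CSV path.
#' @param stations Optional station table for referential-integrity checking.
#' @return Validated record `data.frame` (timestamps parsed to POSIXct).
#' @export
read_detections <- function(path, stations = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("station_id", "species", "timestamp"),
                  "detection table")
  df$species <- tolower(trimws(df$species))
  df$timestamp <- parse_timestamps(df$timestamp)
  if (!is.null(stations)) {
    unknown <- setdiff(unique(df$station_id), stations$station_id)
    if (length(unknown))
      stop("detection(s) at station(s) absent from the station table: ",
           paste(unknown, collapse = ", "))
  }
  df
}

#' @rdname read_detections
#' @param records Detection records.
#' @export
write_detections <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Load and cross-validate all pipeline inputs
#'
#' @param config A [run_config()] with `stations`, `detections` and
#'   `raster_dir` paths set.
#' @return List: `stations`, `records`, `rasters` (grid-consistent stack).
#' @export
load_inputs <- function(config) {
  stations <- read_stations(config$stations)
  records <- read_detections(config$detections, stations)
  files <- sort(list.files(config$raster_dir, pattern = "\\.asc$",
                           full.names = TRUE))
  rasters <- lapply(files, read_ascii_raster)
  names(rasters) <- vapply(rasters, `[[`, "", "name")
  if (length(rasters) > 1L)
    for (i in seq_along(rasters)[-1L])
      if (!raster_compatible(rasters[[1L]], rasters[[i]]))
        stop("raster grids disagree: ", names(rasters)[i])
  list(stations = stations, records = records, rasters = rasters)
}

# ---- pipeline ----------------------------------------------------------------

pipeline_meta <- function(config, out_dir, extra = list()) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(config), cfg_file)
  meta <- c(list(config_hash = unname(tools::md5sum(cfg_file)),
                 seed = config$seed,
                 thresholds = config[c("min_gap", "p_screen", "r_prune",
                                       "min_detections", "size_cutoff",
                                       "bootstrap_B", "ci_level")],
                 timestamp_format = "ISO 8601 local clock"),
            extra)
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(meta)
}

simulate_stage <- function(config, syn) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "rasters"), showWarnings = FALSE)
  stack <- generate_covariate_stack(syn, seed = config$seed)
  stations <- place_stations(syn, seed = config$seed + 1L)
  mat <- simulate_community(stations, syn, seed = config$seed + 2L)
  # expand counts into timestamped records with archetype diel times
  recs <- list()
  counts <- unclass(mat)
  for (sp in colnames(counts)) {
    tot <- sum(counts[, sp])
    if (!tot) next
    arch <- config$species_activity[[sp]]
    ang <- if (!is.null(arch))
      simulate_activity_times(arch, tot, syn,
                              seed = config$seed + 10L + match(sp, colnames(counts)))$angles
    else withr::with_seed(config$seed + 10L + match(sp, colnames(counts)),
                          stats::runif(tot, 0, 2 * pi))
    day <- withr::with_seed(config$seed + 100L + match(sp, colnames(counts)),
                            sample.int(120L, tot, replace = TRUE))
    secs <- round(ang * 86400 / (2 * pi))
    ts <- as.POSIXct("2024-01-01", tz = "UTC") + (day - 1L) * 86400 + secs
    recs[[sp]] <- data.frame(
      station_id = rep(rownames(counts), counts[, sp]),
      species = sp, timestamp = ts, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$station_id, records$species,
                           records$timestamp), ]
  write_stations(stations, file.path(out, "stations.csv"))
  write_detections(records, file.path(out, "detections.csv"))
  for (nm in names(stack))
    write_ascii_raster(stack[[nm]], file.path(out, "rasters",
                                              paste0(nm, ".asc")))
  message(sprintf("simulate: %d stations, %d records, %d rasters",
                  nrow(stations), nrow(records), length(stack)))
  invisible(list(stations = stations, records = records, stack = stack))
}

matrix_from_inputs <- function(inputs, config) {
  kept <- enforce_independence(inputs$records, min_gap = config$min_gap)
  message(sprintf("independence filter: %d -> %d records",
                  nrow(inputs$records), nrow(kept)))
  build_matrix(kept, inputs$stations)
}

habitat_stage <- function(config, inputs) {
  out <- config$output_dir
  mat <- matrix_from_inputs(inputs, config)
  species <- intersect(config$focal_species, colnames(mat))
  if (!length(species)) stop("no focal species present in the detections")
  scaled <- lapply(inputs$rasters, scale_stack, scales = config$scales)
  surfaces <- list()
  for (sp in species) {
    hm <- run_habitat_pipeline(sp, inputs$rasters, inputs$stations, mat,
                               scales = config$scales,
                               p_screen = config$p_screen,
                               r_prune = config$r_prune,
                               criterion = config$criterion, scaled = scaled)
    av <- hm$averaged
    av$scale_m <- vapply(av$term, function(t)
      if (t %in% names(hm$covariates)) hm$covariates[[t]]$scale else NA_real_, 0)
    utils::write.csv(av, file.path(out, paste0("habitat_model_", sp, ".csv")),
                     row.names = FALSE)
    surf <- predict_surface(hm, inputs$rasters, scaled = scaled)
    write_ascii_raster(surf, file.path(out, paste0("surface_", sp, ".asc")))
    surfaces[[sp]] <- surf
    # fine-scale road/ridge associations, when the station table carries them
    y <- as.integer(unclass(mat)[, sp] > 0)
    assoc <- list()
    for (fl in c("road", "ridge"))
      if (fl %in% names(inputs$stations) &&
          length(unique(inputs$stations[[fl]])) > 1L) {
        f <- univariate_association(y, inputs$stations[[fl]], name = fl)
        assoc[[fl]] <- data.frame(species = sp, variable = fl,
                                  coefficient = unname(f$coef[fl]),
                                  AIC = f$aic, p = unname(f$p[fl]))
      }
    if (length(assoc))
      utils::write.csv(do.call(rbind, assoc),
                       file.path(out, paste0("fine_scale_", sp, ".csv")),
                       row.names = FALSE)
  }
  if (length(surfaces) > 1L) {
    prs <- utils::combn(names(surfaces), 2L)
    cmp <- apply(prs, 2L, function(pr) {
      sc <- compare_surfaces(surfaces[[pr[1]]], surfaces[[pr[2]]])
      data.frame(a = pr[1], b = pr[2], pearson_r = sc$pearson_r,
                 mean_abs_diff = sc$mean_abs_diff)
    })
    utils::write.csv(do.call(rbind, cmp),
                     file.path(out, "surface_comparison.csv"),
                     row.names = FALSE)
  }
  invisible(surfaces)
}

activity_stage <- function(config, inputs) {
  out <- config$output_dir
  kept <- enforce_independence(inputs$records, min_gap = config$min_gap)
  dens_rows <- list(); mass_rows <- list(); ang_rows <- list()
  for (sp in sort(unique(kept$species))) {
    ts <- kept$timestamp[kept$species == sp]
    if (length(ts) < 2L) next
    smp <- activity_sample(time_to_angle(ts), species = sp)
    ang_rows[[sp]] <- data.frame(species = sp, angle = smp$angles)
    kde <- fit_vonmises_kde(smp, adjust = config$adjust,
                            grid_m = config$grid_m)
    dens_rows[[sp]] <- data.frame(
      species = sp, angle = kde$grid,
      clock_h = kde$grid * 24 / (2 * pi), density = kde$density)
    pm <- period_mass(kde)
    pm$species <- sp
    mass_rows[[sp]] <- pm
  }
  utils::write.csv(do.call(rbind, ang_rows),
                   file.path(out, "activity_angles.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, dens_rows),
                   file.path(out, "activity_density.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, mass_rows),
                   file.path(out, "period_mass.csv"), row.names = FALSE)
  invisible(NULL)
}

overlap_stage <- function(config, inputs) {
  out <- config$output_dir
  ang_path <- file.path(out, "activity_angles.csv")
  if (!file.exists(ang_path))
    stop("overlap stage requires the activity stage outputs (",
         ang_path, " missing); run stage 'activity' first")
  ang <- utils::read.csv(ang_path, stringsAsFactors = FALSE)
  samples <- lapply(split(ang$angle, ang$species), activity_sample)
  for (sp in names(samples)) samples[[sp]]$species <- sp
  focal <- intersect(config$focal_species, names(samples))
  rows <- list(); cls_rows <- list()
  for (f in focal) {
    others <- setdiff(names(samples), f)
    deltas <- numeric(0)
    for (o in others) {
      res <- smoothed_bootstrap_ci(samples[[f]], samples[[o]],
                                   B = config$bootstrap_B,
                                   level = config$ci_level,
                                   seed = config$seed + length(rows),
                                   adjust = config$adjust,
                                   grid_m = config$grid_m,
                                   size_cutoff = config$size_cutoff)
      deltas[o] <- res$estimate
      rows[[paste(f, o)]] <- data.frame(
        felid = f, candidate = o, n1 = res$n1, n2 = res$n2,
        estimator = res$estimator, delta = res$estimate,
        ci_low = res$ci[1], ci_high = res$ci[2])
    }
    if (length(deltas) >= 2L) {
      cls <- suppressWarnings(classify_overlap_set(deltas, felid = f))
      tab <- cls$table
      tab$felid <- f
      cls_rows[[f]] <- tab
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(out, "overlap.csv"),
                   row.names = FALSE)
  if (length(cls_rows))
    utils::write.csv(do.call(rbind, cls_rows),
                     file.path(out, "overlap_classification.csv"),
                     row.names = FALSE)
  invisible(NULL)
}

cooccur_stage <- function(config, inputs) {
  out <- config$output_dir
  mat <- matrix_from_inputs(inputs, config)
  felids <- intersect(config$focal_species, colnames(mat))
  rows <- list()
  for (f in felids) {
    cm <- prey_cooccurrence_model(f, mat, inputs$stations,
                                  min_detections = config$min_detections,
                                  cap = config$cap,
                                  exclude = config$focal_species,
                                  criterion = config$criterion)
    av <- cm$averaged
    av$felid <- f
    rows[[f]] <- av
  }
  utils::write.csv(do.call(rbind, rows), file.path(out, "cooccurrence.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (write a synthetic survey into the output directory),
#' `habitat` (multi-scale models, surfaces, comparisons, road/ridge
#' associations), `activity` (circular KDEs and diel period masses),
#' `overlap` (pairwise overlap coefficients with bootstrap CIs and the
#' percentile classification; requires the activity stage), `cooccur`
#' (felid/candidate co-occurrence ensembles), or `all`. When a `simulate`
#' output directory is used as input, station/detection/raster paths default
#' into it. A `run_meta.json` with the configuration hash, seed and
#' thresholds is written alongside the outputs.
#'
#' @param config A [run_config()].
#' @param stage One of `"simulate"`, `"habitat"`, `"activity"`, `"overlap"`,
#'   `"cooccur"`, `"all"`.
#' @param synthetic A [synthetic_config()] for the simulate stage.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "habitat",
                                           "activity", "overlap", "cooccur"),
                         synthetic = synthetic_config()) {
  stage <- match.arg(stage)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage %in% c("simulate", "all")) {
    simulate_stage(config, synthetic)
    if (is.null(config$stations)) {
      config$stations <- file.path(config$output_dir, "stations.csv")
      config$detections <- file.path(config$output_dir, "detections.csv")
      config$raster_dir <- file.path(config$output_dir, "rasters")
    }
  }
  if (stage == "simulate") {
    pipeline_meta(config, config$output_dir)
    return(invisible(config$output_dir))
  }
  if (is.null(config$stations))
    stop("no input paths configured; run the 'simulate' stage first or set ",
         "`stations`, `detections` and `raster_dir`")
  inputs <- load_inputs(config)
  if (stage %in% c("habitat", "all")) habitat_stage(config, inputs)
  if (stage %in% c("activity", "all")) activity_stage(config, inputs)
  if (stage %in% c("overlap", "all")) overlap_stage(config, inputs)
  if (stage %in% c("cooccur", "all")) cooccur_stage(config, inputs)
  pipeline_meta(config, config$output_dir,
                extra = list(n_stations = nrow(inputs$stations),
                             n_records = nrow(inputs$records)))
  invisible(config$output_dir)
}
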