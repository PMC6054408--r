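# Raw camera-trap records -> independent-detection matrices, detection
# frequencies, candidate sets and guild body-mass summaries.

#' Detection count matrix
#'
#' Stations x species matrix of independent detection counts, carrying
#' per-station trap-night effort as an attribute.
#'
#' @param counts Non-negative integer matrix with station row names and
#'   species column names.
#' @param effort Named numeric vector of trap-nights per station (> 0),
#'   names matching the row names.
#' @return A `detection_matrix`.
#' @export
detection_matrix <- function(counts, effort) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("detection counts must be non-negative integers")
  if (is.null(rownames(counts))) stop("`counts` needs station row names")
  if (!all(rownames(counts) %in% names(effort)))
    stop("effort missing for station(s): ",
         paste(setdiff(rownames(counts), names(effort)), collapse = ", "))
  effort <- effort[rownames(counts)]
  if (any(effort <= 0)) stop("effort must be > 0 for every station")
  structure(counts, effort = effort, class = c("detection_matrix", "matrix"))
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("<detection_matrix> %d stations x %d species, %d detections, %g trap-nights\n",
              nrow(x), ncol(x), sum(x), sum(attr(x, "effort"))))
  tot <- sort(colSums(unclass(x)), decreasing = TRUE)
  show <- utils::head(tot, 8L)
  cat("  totals:", paste(sprintf("%s=%d", names(show), show), collapse = ", "),
      if (length(tot) > 8L) "..." else "", "\n")
  invisible(x)
}

station_effort <- function(matrix) attr(matrix, "effort")

parse_timestamps <- function(ts) {
  if (inherits(ts, "POSIXt")) return(as.POSIXct(ts, tz = "UTC"))
  ts <- as.character(ts)
  out <- as.POSIXct(rep(NA_character_, length(ts)), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M")) {
    need <- is.na(out)
    if (!any(need)) break
    out[need] <- as.POSIXct(strptime(ts[need], fmt, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(ts))
  if (length(bad))
    stop("unparseable timestamp at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ": ",
         paste(utils::head(ts[bad], 5L), collapse = ", "))
  out
}

#' Filter records to independent detections
#'
#' Within each (station, species) stream, records are scanned in time order
#' and one is kept iff at least `min_gap` has elapsed since the previously
#' *kept* record (greedy rule; the earliest record of a burst represents it).
#' A gap exactly equal to `min_gap` counts as independent. Different stations
#' or species never interact. `method = "hour_bin"` instead keeps the first
#' record per clock hour, should calendar-hour binning be wanted.
#'
#' @param records Data frame with `station_id`, `species`, `timestamp`
#'   (POSIXct or ISO 8601 text, local clock).
#' @param min_gap Minimum separation in seconds (default 3600 = 1 h).
#' @param method `"greedy"` (default) or `"hour_bin"`.
#' @return The kept records, in (station, species, time) order.
#' @export
enforce_independence <- function(records, min_gap = 3600, method = c("greedy", "hour_bin")) {
  method <- match.arg(method)
  if (!nrow(records)) return(records)
  ts <- parse_timestamps(records$timestamp)
  ord <- order(records$station_id, records$species, ts)
  rec <- records[ord, , drop = FALSE]
  ts <- ts[ord]
  key <- paste(rec$station_id, rec$species, sep = "\r")
  keep <- logical(nrow(rec))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (method == "hour_bin") {
      hour <- format(ts[idx], "%Y-%m-%d %H")
      keep[idx[!duplicated(hour)]] <- TRUE
    } else {
      last <- -Inf
      for (i in idx) {
        if (as.numeric(ts[i]) - last >= min_gap) {
          keep[i] <- TRUE
          last <- as.numeric(ts[i])
        }
      }
    }
  }
  out <- rec[keep, , drop = FALSE]
  out$timestamp <- ts[keep]
  rownames(out) <- NULL
  out
}

#' Build the station x species detection matrix
#'
#' @param records Independence-filtered records ([enforce_independence()]).
#' @param stations Station table (`station_id`, `effort`, ...).
#' @param species_list Species columns to tabulate (default: all in
#'   `records`, sorted).
#' @return A [detection_matrix()]; column totals equal the per-species record
#'   counts.
#' @export
build_matrix <- function(records, stations, species_list = NULL) {
  unknown <- setdiff(unique(records$station_id), stations$station_id)
  if (length(unknown))
    stop("record(s) at unknown station(s): ", paste(unknown, collapse = ", "))
  if (is.null(species_list)) species_list <- sort(unique(records$species))
  m <- matrix(0L, nrow = nrow(stations), ncol = length(species_list),
              dimnames = list(stations$station_id, species_list))
  if (nrow(records)) {
    rec <- records[records$species %in% species_list, , drop = FALSE]
    tab <- table(factor(rec$station_id, levels = stations$station_id),
                 factor(rec$species, levels = species_list))
    m[] <- as.integer(tab)
  }
  detection_matrix(m, stats::setNames(stations$effort, stations$station_id))
}

#' Detection frequency per 100 trap-nights
#'
#' @param count Independent detection count.
#' @param effort Trap-nights (> 0).
#' @return `100 * count / effort`, rounded to 3 decimals.
#' @export
detection_frequency <- function(count, effort) {
  if (any(effort <= 0)) stop("`effort` must be > 0")
  round(100 * count / effort, 3)
}

#' Species passing the minimum-detection filter
#'
#' @param matrix A [detection_matrix()].
#' @param threshold Minimum total independent detections (default 20;
#'   species with totals >= threshold are kept).
#' @return Character vector of retained species names.
#' @export
filter_min_detections <- function(matrix, threshold = 20) {
  tot <- colSums(unclass(matrix))
  names(tot)[tot >= threshold]
}

#' Body-mass ratio matrix with similar-size flags
#'
#' Pairwise heavier/lighter mean-mass ratios (always >= 1), rounded to one
#' decimal; a pair is flagged as very similar in size when its rounded ratio
#' is below 2, the conventional threshold for strong dietary competition.
#'
#' @param means Named numeric vector of mean body masses (kg, > 0).
#' @return List with `ratio` (rounded matrix) and `similar` (logical matrix).
#' @export
body_mass_ratio_matrix <- function(means) {
  if (any(means <= 0)) stop("body masses must be > 0")
  ratio <- outer(means, means, function(a, b) pmax(a, b) / pmin(a, b))
  ratio <- round(ratio, 1)
  similar <- ratio < 2
  diag(similar) <- FALSE
  list(ratio = ratio, similar = similar)
}
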