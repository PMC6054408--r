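# In-memory single-band raster with a projected (metric) grid.
# Values are stored as a numeric matrix with row 1 at the TOP of the map
# (largest y), matching how grid files list rows north-to-south.

#' Create a raster layer
#'
#' Lightweight single-band raster on a regular metric grid. Cell centres are
#' at `xll + (col - 0.5) * cell_size` and `yll + (nrow - row + 0.5) *
#' cell_size`; row 1 is the northernmost row.
#'
#' @param values Numeric matrix of cell values; `NA` marks nodata.
#' @param cell_size Cell edge length in metres (> 0).
#' @param xll,yll Coordinates of the lower-left corner of the grid, metres.
#' @param name Layer name.
#' @param kind `"continuous"` or `"indicator"` (0/1 class membership).
#' @return An object of class `eco_raster`.
#' @export
eco_raster <- function(values, cell_size, xll = 0, yll = 0,
                       name = "layer", kind = c("continuous", "indicator")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("empty raster")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (kind == "indicator") {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% c(0, 1)))
      stop("indicator raster cells must be 0, 1 or NA")
  }
  structure(list(values = values, cell_size = cell_size, xll = xll, yll = yll,
                 name = name, kind = kind),
            class = "eco_raster")
}

#' @export
print.eco_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eco_raster> '%s' (%s): %d x %d cells @ %g m\n",
              x$name, x$kind, nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m; %d nodata cells\n",
              x$xll, x$xll + ncol(v) * x$cell_size,
              x$yll, x$yll + nrow(v) * x$cell_size, sum(is.na(v))))
  fin <- v[!is.na(v)]
  if (length(fin))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
                min(fin), mean(fin), max(fin)))
  invisible(x)
}

#' @export
dim.eco_raster <- function(x) dim(x$values)

raster_compatible <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
}

# ---- FFT convolution helpers -------------------------------------------------

# 'same'-size 2-D convolution of matrix x with (odd-sized, centred) kernel k.
conv2_same <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(k); kc <- ncol(k)
  pr <- stats::nextn(nr + kr - 1L, c(2L, 3L, 5L))
  pc <- stats::nextn(nc + kc - 1L, c(2L, 3L, 5L))
  X <- matrix(0, pr, pc); X[seq_len(nr), seq_len(nc)] <- x
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- k
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L
  c0 <- (kc - 1L) %/% 2L
  full[r0 + seq_len(nr), c0 + seq_len(nc)]
}

# Disc-shaped kernel: 1 where the cell-centre offset is within radius_m.
disc_kernel <- function(radius_m, cell_size) {
  r_cells <- floor(radius_m / cell_size)
  off <- seq(-r_cells, r_cells)
  d <- outer(off, off, function(i, j) sqrt(i^2 + j^2) * cell_size)
  (d <= radius_m) * 1
}

# ---- Focal statistics --------------------------------------------------------

#' Circular focal mean of a raster
#'
#' Each output cell is the mean of all cells whose centre lies within
#' `radius_m` (Euclidean, in metres) of the focal cell's centre. Nodata cells
#' are ignored; windows are truncated at the raster edge (mean over the cells
#' actually available). For an indicator raster the result is the within-window
#' class proportion. A cell whose whole window is nodata is nodata.
#'
#' @param raster An [eco_raster()].
#' @param radius_m Window radius in metres (>= 0). A radius smaller than half
#'   a cell returns the input unchanged.
#' @return An `eco_raster` (kind `"continuous"`).
#' @export
focal_mean <- function(raster, radius_m) {
  stopifnot(inherits(raster, "eco_raster"))
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m < 0)
    stop("`radius_m` must be a single non-negative number")
  v <- raster$values
  if (radius_m < raster$cell_size / 2) {
    out <- raster
    out$name <- paste0(raster$name, "_r", format(radius_m))
    out$kind <- "continuous"
    return(out)
  }
  k <- disc_kernel(radius_m, raster$cell_size)
  valid <- !is.na(v)
  x <- v; x[!valid] <- 0
  num <- conv2_same(x, k)
  den <- conv2_same(valid * 1, k)
  den <- round(den)                     # counts are integers; remove FFT noise
  out <- num / den
  out[den < 0.5] <- NA_real_
  eco_raster(out, raster$cell_size, raster$xll, raster$yll,
             name = paste0(raster$name, "_r", format(radius_m)),
             kind = "continuous")
}

#' Focal means at a ladder of analysis scales
#'
#' Applies [focal_mean()] at each radius of the multi-scale analysis ladder.
#' The default ladder is the seven doubling radii 120--7680 m.
#'
#' @param raster An [eco_raster()].
#' @param scales Ascending positive radii in metres.
#' @return Named list of `eco_raster`, one per scale (names are the radii).
#' @export
scale_stack <- function(raster, scales = c(120, 240, 480, 960, 1920, 3840, 7680)) {
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be positive and strictly ascending")
  out <- lapply(scales, function(s) focal_mean(raster, s))
  names(out) <- as.character(scales)
  out
}

# ---- Station extraction ------------------------------------------------------

# Row/col of the cell containing each point; half-open cells [x0, x0 + cell).
cell_index <- function(raster, x, y) {
  nrows <- nrow(raster$values)
  col <- floor((x - raster$xll) / raster$cell_size) + 1L
  row <- nrows - floor((y - raster$yll) / raster$cell_size)
  ok <- col >= 1L & col <= ncol(raster$values) & row >= 1L & row <= nrows
  if (!all(ok))
    stop("stations outside raster extent: ",
         paste(which(!ok), collapse = ", "))
  cbind(row = row, col = col)
}

#' Extract and standardize station-level covariate values
#'
#' Reads the raster cell containing each station point, then z-scores the
#' values across the station set (the analysis population). A covariate with
#' (near-)zero variance across stations is flagged degenerate and should be
#' excluded from model building.
#'
#' @param raster An [eco_raster()] (typically a focal-mean layer).
#' @param stations Station table (see [read_stations()]): needs `station_id`,
#'   `x`, `y`.
#' @param scale_m Focal radius the raster was computed at (for bookkeeping).
#' @param standardize Z-score across stations (default `TRUE`).
#' @return A `scaled_covariate`: station values plus the centring constants
#'   needed to apply the same transform to map cells.
#' @export
extract_standardize <- function(raster, stations, scale_m = NA_real_,
                                standardize = TRUE) {
  stopifnot(inherits(raster, "eco_raster"))
  idx <- cell_index(raster, stations$x, stations$y)
  vals <- raster$values[idx]
  if (anyNA(vals))
    stop("station(s) fall on nodata cells: ",
         paste(stations$station_id[is.na(vals)], collapse = ", "))
  m <- mean(vals); s <- stats::sd(vals)
  degenerate <- !is.finite(s) || s < 1e-12
  z <- if (standardize && !degenerate) (vals - m) / s else vals
  structure(list(name = raster$name, scale = scale_m,
                 station_id = stations$station_id, values = z,
                 standardized = standardize && !degenerate,
                 degenerate = degenerate, center = m, sd = s),
            class = "scaled_covariate")
}

# ---- ASCII grid IO -----------------------------------------------------------

#' Read a raster from an ESRI ASCII grid file
#'
#' @param path File path (`.asc`).
#' @param name Layer name (default: file stem).
#' @param kind Layer kind, as in [eco_raster()].
#' @return An [eco_raster()].
#' @export
read_ascii_raster <- function(path, name = NULL,
                              kind = c("continuous", "indicator")) {
  kind <- match.arg(kind)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) >= 2L)
      hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) in ", path)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nd <- hdr$nodata_value
  if (!is.null(nd)) vals[vals == nd] <- NA_real_
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  eco_raster(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, name, kind)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param raster An [eco_raster()].
#' @param path Output path.
#' @param nodata Sentinel written for `NA` cells.
#' @param digits Significant digits for cell values.
#' @export
write_ascii_raster <- function(raster, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(raster, "eco_raster"))
  v <- raster$values
  hdr <- c(sprintf("NCOLS %d", ncol(v)),
           sprintf("NROWS %d", nrow(v)),
           sprintf("XLLCORNER %.10g", raster$xll),
           sprintf("YLLCORNER %.10g", raster$yll),
           sprintf("CELLSIZE %.10g", raster$cell_size),
           sprintf("NODATA_VALUE %g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
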