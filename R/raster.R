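#' Single-band covariate raster
#'
#' A minimal in-memory raster: a numeric matrix on a regular square grid,
#' anchored in projected map coordinates (meters). Row 1 is the northern-most
#' row, matching the on-disk ESRI ASCII grid layout.
#'
#' @param values Numeric matrix of cell values; row 1 = top (north).
#' @param cell_size Cell edge length in meters (> 0).
#' @param xll,yll Map coordinates of the lower-left corner of the raster.
#' @param name Covariate label.
#' @param year Integer year the layer represents.
#' @param nodata Value standing in for missing cells on disk; stored
#'   internally as `NA`.
#'
#' @return An object of class `covariate_raster`.
#' @export
covariate_raster <- function(values, cell_size, xll = 0, yll = 0,
                             name = "covariate", year = NA_integer_,
                             nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA_real_
  if (any(is.infinite(values)))
    stop("raster contains non-finite values that are not nodata")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         name = name, year = as.integer(year), nodata = nodata),
    class = "covariate_raster")
}

#' @export
print.covariate_raster <- function(x, ...) {
  cat(sprintf("<covariate_raster> %s (year %s): %d x %d cells @ %g m\n",
              x$name, x$year, nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]; %d missing cells\n",
              x$xll, x$xll + ncol(x$values) * x$cell_size,
              x$yll, x$yll + nrow(x$values) * x$cell_size,
              sum(is.na(x$values))))
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cell_size,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cell_size)
}

# Map coordinates of every cell center, as two matrices conformable with
# r$values. Row i (from the top) has center y = ymax - (i - 1/2) * cs.
cell_centers <- function(r) {
  cs <- r$cell_size
  nr <- nrow(r$values); nc <- ncol(r$values)
  x <- r$xll + (seq_len(nc) - 0.5) * cs
  y <- r$yll + nr * cs - (seq_len(nr) - 0.5) * cs
  list(x = x, y = y)
}

# Row/column of the cell containing a point; errors if outside the extent.
cell_index <- function(r, easting, northing, id = "?") {
  ext <- raster_extent(r)
  if (easting < ext["xmin"] || easting > ext["xmax"] ||
      northing < ext["ymin"] || northing > ext["ymax"])
    stop(sprintf("centroid for grid '%s' (%.1f, %.1f) falls outside raster '%s'",
                 id, easting, northing, r$name))
  col <- pmin(ncol(r$values), 1L + floor((easting - r$xll) / r$cell_size))
  row <- pmin(nrow(r$values),
              1L + floor((ext["ymax"] - northing) / r$cell_size))
  c(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values, north row first.
#'
#' @param path File to read.
#' @param name,year Metadata not carried by the format itself.
#' @return A [covariate_raster].
#' @export
read_ascii_grid <- function(path, name = NULL, year = NA_integer_) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("ASCII grid body has %d values, expected %d",
                 length(vals), hdr$ncols * hdr$nrows))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (is.null(name))
    name <- sub("\\.asc$", "", basename(path))
  covariate_raster(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
                   name = name, year = year, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param r A [covariate_raster].
#' @param path Output file (`.asc`).
#' @param digits Significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  stopifnot(inherits(r, "covariate_raster"))
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", r$nodata))
  body <- apply(v, 1L, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Gap-fill a missing raster year by averaging its neighbours
#'
#' Annual landcover products sometimes skip a year; the convention is to
#' substitute the cell-wise mean of the bracketing years.
#'
#' @param before,after [covariate_raster]s for the bracketing years.
#' @param year Year to assign to the filled layer.
#' @return A [covariate_raster] with cell values `(before + after) / 2`
#'   (`NA` wherever either neighbour is `NA`).
#' @export
fill_raster_year <- function(before, after, year) {
  stopifnot(identical(dim(before$values), dim(after$values)),
            before$cell_size == after$cell_size)
  covariate_raster((before$values + after$values) / 2, before$cell_size,
                   before$xll, before$yll, name = before$name,
                   year = year, nodata = before$nodata)
}

#' Circular moving-window mean of a raster
#'
#' Focal mean with the center-in rule: the window at a cell averages every
#' cell whose center lies within `radius` meters of that cell's center.
#' Used to build prediction-surface covariates at the posterior-mode
#' scale of effect.
#'
#' @param r A [covariate_raster].
#' @param radius Window radius in meters; `0` returns `r` unchanged.
#' @return A [covariate_raster] of the same shape.
#' @export
moving_window_mean <- function(r, radius) {
  stopifnot(radius >= 0)
  if (radius == 0) return(r)
  cs <- r$cell_size
  k <- floor(radius / cs)
  offs <- expand.grid(di = -k:k, dj = -k:k)
  offs <- offs[(offs$di^2 + offs$dj^2) * cs^2 <= radius^2, , drop = FALSE]
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  for (q in seq_len(nrow(offs))) {
    di <- offs$di[q]; dj <- offs$dj[q]
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    acc[si, sj] <- acc[si, sj] + v0[si + di, sj + dj]
    cnt[si, sj] <- cnt[si, sj] + ok[si + di, sj + dj]
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  covariate_raster(out, cs, r$xll, r$yll, name = r$name, year = r$year,
                   nodata = r$nodata)
}
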