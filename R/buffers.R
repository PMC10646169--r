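#' Mean covariate values within nested buffers around grid centroids
#'
#' For each centroid, computes the mean of all non-missing raster cells whose
#' cell-center distance to the centroid is at most `r`, for every radius `r`
#' in `radii` (the center-in rule). Radius 0 returns the value of the cell
#' containing the centroid. This is the per-layer building block of a
#' [buffer_stack].
#'
#' @param raster A [covariate_raster].
#' @param centroids Data frame with columns `grid_id`, `easting`, `northing`
#'   (meters, same projection as the raster).
#' @param radii Ascending numeric vector of buffer radii in meters; the
#'   canonical analysis uses 0, 100, ..., 10000.
#' @return Numeric matrix `[grid, radius]` with dimnames. An entry is `NA`
#'   (with a warning) when every cell within the radius is nodata.
#' @export
summarize_buffers <- function(raster, centroids, radii) {
  stopifnot(inherits(raster, "covariate_raster"),
            all(c("grid_id", "easting", "northing") %in% names(centroids)))
  radii <- as.numeric(radii)
  if (is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing")
  if (any(radii < 0)) stop("radii must be non-negative")

  bi <- buffer_index(raster, centroids, radii)
  apply_buffer_index(bi, raster$values)
}

# Geometry-only part of the buffer summaries: per centroid, the candidate
# cells sorted by center distance and the cell count at each radius.
# Reusable across every raster sharing the same geometry.
buffer_index <- function(raster, centroids, radii) {
  cs <- raster$cell_size
  cc <- cell_centers(raster)
  nr <- nrow(raster$values)
  nG <- nrow(centroids)
  rmax <- max(radii)
  per_grid <- vector("list", nG)
  for (g in seq_len(nG)) {
    ex <- centroids$easting[g]; ny <- centroids$northing[g]
    idx <- cell_index(raster, ex, ny, id = centroids$grid_id[g])
    jr <- which(abs(cc$x - ex) <= rmax + cs / 2)
    ir <- which(abs(cc$y - ny) <= rmax + cs / 2)
    dist <- sqrt(outer((cc$y[ir] - ny)^2, (cc$x[jr] - ex)^2, "+"))
    lin <- outer(ir, (jr - 1L) * nr, "+")
    o <- order(dist)
    per_grid[[g]] <- list(lin = lin[o], dsort = dist[o],
                          k = findInterval(radii, dist[o]),
                          cell0 = idx["row"] + (idx["col"] - 1L) * nr)
  }
  structure(list(per_grid = per_grid, radii = radii,
                 grid_ids = centroids$grid_id,
                 geom = c(dim(raster$values), cs, raster$xll, raster$yll)),
            class = "buffer_index")
}

apply_buffer_index <- function(bi, values) {
  radii <- bi$radii
  nG <- length(bi$per_grid)
  out <- matrix(NA_real_, nG, length(radii),
                dimnames = list(as.character(bi$grid_ids),
                                paste0("r", radii)))
  any_missing <- FALSE
  for (g in seq_len(nG)) {
    pg <- bi$per_grid[[g]]
    vsort <- values[pg$lin]
    fin <- !is.na(vsort)
    cum_v <- cumsum(ifelse(fin, vsort, 0))
    cum_n <- cumsum(fin)
    k <- pg$k
    m <- ifelse(k > 0 & cum_n[pmax(k, 1L)] > 0,
                cum_v[pmax(k, 1L)] / cum_n[pmax(k, 1L)], NA_real_)
    # a buffer smaller than the cell spacing falls back to the centroid cell
    m[k == 0] <- values[pg$cell0]
    if (any(radii == 0)) m[radii == 0] <- values[pg$cell0]
    if (anyNA(m)) any_missing <- TRUE
    out[g, ] <- m
  }
  if (any_missing)
    warning("some buffers contain only nodata cells; entries flagged NA")
  out
}

#' Multi-radius covariate stack
#'
#' Container for buffer-mean covariate values indexed by grid, year,
#' covariate and radius: the substrate on which continuous scale-of-effect
#' parameters are estimated by interpolating between tabulated radii.
#' Covariates summarized at a single fixed radius (e.g. elevation at 564 m)
#' or at the centroid only are stored as radius-degenerate stacks so that one
#' code path serves both.
#'
#' @param values 4-D numeric array `[grid, year, covariate, radius]`.
#' @param grid_ids,years,covariates,radii Index vectors matching `values`.
#' @param center,scale Optional named per-covariate standardization
#'   constants (set by [standardize_stack]).
#' @return An object of class `buffer_stack`.
#' @export
buffer_stack <- function(values, grid_ids, years, covariates, radii,
                         center = NULL, scale = NULL) {
  radii <- as.numeric(radii)
  if (length(radii) > 1 && is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing")
  stopifnot(length(dim(values)) == 4,
            dim(values)[1] == length(grid_ids),
            dim(values)[2] == length(years),
            dim(values)[3] == length(covariates),
            dim(values)[4] == length(radii))
  dimnames(values) <- list(as.character(grid_ids), as.character(years),
                           covariates, paste0("r", radii))
  structure(list(values = values, grid_ids = grid_ids, years = years,
                 covariates = covariates, radii = radii,
                 center = center, scale = scale),
            class = "buffer_stack")
}

#' @export
print.buffer_stack <- function(x, ...) {
  cat(sprintf("<buffer_stack> %d grids x %d years x %d covariates x %d radii [%g..%g m]%s\n",
              length(x$grid_ids), length(x$years), length(x$covariates),
              length(x$radii), min(x$radii), max(x$radii),
              if (!is.null(x$center)) " (standardized)" else ""))
  invisible(x)
}

#' Build a buffer stack from covariate rasters
#'
#' @param rasters List of [covariate_raster]s. Layers sharing a `name` are
#'   treated as one covariate across years; a covariate supplied for a single
#'   year (or with `year = NA`) is recycled to every panel year.
#' @param centroids Data frame `grid_id`, `easting`, `northing`.
#' @param radii Buffer radii in meters (default the canonical 101).
#' @param years Panel years; defaults to the years present among the rasters.
#' @return A [buffer_stack] of raw (unstandardized) buffer means.
#' @export
build_buffer_stack <- function(rasters, centroids,
                               radii = seq(0, 10000, by = 100),
                               years = NULL) {
  stopifnot(length(rasters) > 0)
  covs <- unique(vapply(rasters, `[[`, "", "name"))
  ryrs <- vapply(rasters, function(r) as.integer(r$year), 1L)
  if (is.null(years)) {
    years <- sort(unique(ryrs[!is.na(ryrs)]))
    if (!length(years)) years <- NA_integer_
  }
  nG <- nrow(centroids)
  vals <- array(NA_real_, c(nG, length(years), length(covs), length(radii)))
  # reuse the distance-sorted cell index across rasters sharing a geometry
  geom_key <- vapply(rasters, function(r)
    paste(dim(r$values)[1], dim(r$values)[2], r$cell_size, r$xll, r$yll),
    "")
  idx_cache <- list()
  val_cache <- list()   # reuse summaries of year-constant layers
  for (ci in seq_along(covs)) {
    mine <- which(vapply(rasters, `[[`, "", "name") == covs[ci])
    for (yi in seq_along(years)) {
      ri <- mine[match(years[yi], ryrs[mine])]
      if (is.na(ri)) {
        if (length(mine) == 1L) ri <- mine  # year-constant layer
        else stop(sprintf("covariate '%s' has no raster for year %s",
                          covs[ci], years[yi]))
      }
      key <- geom_key[ri]
      if (is.null(idx_cache[[key]]))
        idx_cache[[key]] <- buffer_index(rasters[[ri]], centroids, radii)
      vkey <- paste0("v", ri)
      if (is.null(val_cache[[vkey]]))
        val_cache[[vkey]] <- apply_buffer_index(idx_cache[[key]],
                                                rasters[[ri]]$values)
      vals[, yi, ci, ] <- val_cache[[vkey]]
    }
  }
  buffer_stack(vals, centroids$grid_id, years, covs, radii)
}

#' Center and scale a buffer stack
#'
#' Standardizes each covariate to mean 0, sd 1 using a single pair of
#' constants per covariate computed jointly over all grids, years and radii
#' (so the shape of the radius profile is preserved and interpolation across
#' radii stays meaningful).
#'
#' @param stack A raw [buffer_stack].
#' @return A standardized [buffer_stack] carrying `center` and `scale`.
#' @export
standardize_stack <- function(stack) {
  stopifnot(inherits(stack, "buffer_stack"))
  if (!is.null(stack$center)) stop("stack is already standardized")
  ctr <- scl <- stats::setNames(numeric(length(stack$covariates)),
                                stack$covariates)
  v <- stack$values
  for (ci in seq_along(stack$covariates)) {
    x <- v[, , ci, , drop = FALSE]
    ctr[ci] <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning("covariate '", stack$covariates[ci],
              "' has zero variance; left uncentered")
      ctr[ci] <- 0; s <- 1
    }
    scl[ci] <- s
    v[, , ci, ] <- (v[, , ci, , drop = FALSE] - ctr[ci]) / s
  }
  buffer_stack(v, stack$grid_ids, stack$years, stack$covariates, stack$radii,
               center = ctr, scale = scl)
}

#' Undo stack standardization
#'
#' @param stack A standardized [buffer_stack].
#' @return The raw-scale [buffer_stack]; exact round trip with
#'   [standardize_stack] to machine precision.
#' @export
destandardize_stack <- function(stack) {
  stopifnot(inherits(stack, "buffer_stack"))
  if (is.null(stack$center)) stop("stack is not standardized")
  v <- stack$values
  for (ci in seq_along(stack$covariates))
    v[, , ci, ] <- v[, , ci, , drop = FALSE] * stack$scale[ci] +
      stack$center[ci]
  buffer_stack(v, stack$grid_ids, stack$years, stack$covariates, stack$radii)
}

# Linear interpolation of a [n x n_radii] value matrix at scale s (meters).
# Returns a length-n vector; exact at tabulated radii.
interp_radius_matrix <- function(vmat, radii, s) {
  if (length(radii) == 1L) {
    if (s != radii)
      stop(sprintf("scale %g m outside tabulated radius %g m", s, radii))
    return(vmat[, 1L])
  }
  if (s < radii[1] || s > radii[length(radii)])
    stop(sprintf("scale %g m outside tabulated range [%g, %g] m",
                 s, radii[1], radii[length(radii)]))
  k <- findInterval(s, radii, rightmost.closed = TRUE)
  if (radii[k] == s) return(vmat[, k])
  f <- (s - radii[k]) / (radii[k + 1] - radii[k])
  (1 - f) * vmat[, k] + f * vmat[, k + 1]
}

#' Interpolate a buffer stack at a continuous spatial scale
#'
#' Piecewise-linear interpolation in radius between the tabulated buffer
#' means, the device that turns the discrete 101-radius table into a
#' continuous scale-of-effect parameter.
#'
#' @param stack A [buffer_stack].
#' @param covariate Covariate label.
#' @param grid,year Indices into the stack (single values).
#' @param s Scale (radius) in meters, within the tabulated range.
#' @return The interpolated value (exactly the stored value when `s` is a
#'   tabulated radius).
#' @export
interpolate_at_scale <- function(stack, covariate, grid, year, s) {
  stopifnot(inherits(stack, "buffer_stack"))
  ci <- match(covariate, stack$covariates)
  if (is.na(ci)) stop("unknown covariate: ", covariate)
  gi <- match(as.character(grid), as.character(stack$grid_ids))
  yi <- match(as.character(year), as.character(stack$years))
  if (is.na(gi)) stop("unknown grid: ", grid)
  if (is.na(yi)) stop("unknown year: ", year)
  vmat <- matrix(stack$values[gi, yi, ci, ], nrow = 1L)
  as.numeric(interp_radius_matrix(vmat, stack$radii, s))
}

# All grid-year rows of one covariate as a [n_surveys x n_radii] matrix,
# in the row order of the (grid, year) pairs supplied.
stack_rows <- function(stack, covariate, grid_ids, years) {
  ci <- match(covariate, stack$covariates)
  if (is.na(ci)) stop("unknown covariate: ", covariate)
  gi <- match(as.character(grid_ids), as.character(stack$grid_ids))
  yi <- match(as.character(years), as.character(stack$years))
  if (anyNA(gi)) stop("unknown grid id(s) in panel")
  if (anyNA(yi)) stop("unknown year(s) in panel")
  nr <- length(gi)
  m <- matrix(NA_real_, nr, length(stack$radii))
  for (k in seq_len(nr)) m[k, ] <- stack$values[gi[k], yi[k], ci, ]
  m
}

#' Serialize a buffer stack to tidy CSV
#'
#' Long format: one row per (grid, year, covariate, radius).
#'
#' @param stack A [buffer_stack].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stack_csv <- function(stack, path) {
  stopifnot(inherits(stack, "buffer_stack"))
  d <- expand.grid(grid_id = stack$grid_ids, year = stack$years,
                   covariate = stack$covariates, radius_m = stack$radii,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$value <- as.vector(stack$values)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a buffer stack from tidy CSV
#'
#' @param path CSV written by [write_stack_csv].
#' @return A [buffer_stack].
#' @export
read_stack_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("grid_id", "year", "covariate", "radius_m", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("stack CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  gids <- unique(d$grid_id); yrs <- sort(unique(d$year))
  covs <- unique(d$covariate); radii <- sort(unique(d$radius_m))
  a <- array(NA_real_, c(length(gids), length(yrs), length(covs),
                         length(radii)))
  a[cbind(match(d$grid_id, gids), match(d$year, yrs),
          match(d$covariate, covs), match(d$radius_m, radii))] <- d$value
  buffer_stack(a, gids, yrs, covs, radii)
}
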