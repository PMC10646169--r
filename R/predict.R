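#' Predicted density surface with QA masks
#'
#' Builds a per-pixel density map from a fitted model: covariate rasters
#' are smoothed with a circular moving window at the posterior-mode scale
#' of effect (564 m for fixed-scale covariates), standardized with the
#' training constants, pushed through the habitat model for every retained
#' posterior draw (without the survey-level random effect), multiplied by
#' the zero-inflation probability at the pixel's location, and the
#' per-pixel posterior median converted to birds per km^2 by the
#' `pi * maxd^2` effective-area rule. Two masks accompany the density band:
#' a disturbance mask where the masking covariate exceeds its training
#' maximum, and a QA mask where any covariate falls outside the 2.5-97.5%
#' quantiles of the training values.
#'
#' @param fit A `songscape_fit`.
#' @param rasters Named list of [covariate_raster]s, one per model
#'   covariate, approximating conditions in `year`. All must share one
#'   geometry.
#' @param year Prediction year.
#' @param bcr BCR whose intercept and trend to use.
#' @param mask_covariate Covariate whose exceedance of the training maximum
#'   triggers the disturbance mask (default `"point_disturbance"` when
#'   present, else none).
#' @param qa_quantiles Training-quantile bounds for the QA mask.
#' @param max_draws Cap on posterior draws used per pixel (default all).
#' @return A `density_surface`: [covariate_raster]s `density`,
#'   `mask_disturbance`, `mask_qa` (masks are 0/1), plus the scale modes
#'   used. Masked pixels carry `NA` in the density band.
#' @export
predict_density_map <- function(fit, rasters, year, bcr,
                                mask_covariate = NULL,
                                qa_quantiles = c(0.025, 0.975),
                                max_draws = NULL) {
  dat <- fit$dat
  cfg <- dat$config
  covs <- c(cfg$fixed_covariates, cfg$scaled_covariates)
  miss <- setdiff(covs, names(rasters))
  if (length(miss))
    stop("missing covariate raster(s): ", paste(miss, collapse = ", "))
  if (is.null(mask_covariate) && "point_disturbance" %in% covs)
    mask_covariate <- "point_disturbance"

  geom <- rasters[[covs[1]]]
  m <- posterior_matrix(fit)
  if (!is.null(max_draws) && nrow(m) > max_draws)
    m <- m[round(seq(1, nrow(m), length.out = max_draws)), , drop = FALSE]

  # posterior-mode scale per scale-selected covariate
  modes <- stats::setNames(rep(564, length(covs)), covs)
  for (cv in cfg$scaled_covariates)
    modes[cv] <- scale_posterior_mode(m[, paste0("scale[", cv, "]")])

  # moving-window + standardization; training values for the QA bounds
  std <- dat$stack
  pix <- list(); train <- list()
  for (cv in covs) {
    mw <- moving_window_mean(rasters[[cv]], modes[cv])
    v <- as.vector(mw$values)
    pix[[cv]] <- (v - 0) # raw-scale for masks
    train_rows <- if (cv %in% cfg$scaled_covariates)
      interp_radius_matrix(dat$W[[cv]], dat$radii, modes[cv])
    else dat$x[, cv]
    # dat values are standardized; bring pixels onto the same scale
    pix_std <- (v - std$center[cv]) / std$scale[cv]
    pix[[cv]] <- list(raw = v, std = pix_std)
    train[[cv]] <- train_rows
  }

  npix <- length(pix[[covs[1]]]$raw)

  # design matrix on the standardized scale, matching the fit's columns
  cols <- list()
  for (cv in cfg$fixed_covariates) cols[[cv]] <- pix[[cv]]$std
  for (cv in cfg$fixed_quad) cols[[paste0(cv, "_sq")]] <- pix[[cv]]$std^2
  for (cv in cfg$scaled_covariates) cols[[cv]] <- pix[[cv]]$std
  for (cv in cfg$scaled_quad) cols[[paste0(cv, "_sq")]] <- pix[[cv]]$std^2
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, npix, 0)

  beta_cols <-c(if (ncol(dat$x)) paste0("beta[", colnames(dat$x), "]"),
                 if (length(cfg$scaled_covariates))
                   paste0("Gamma[", c(cfg$scaled_covariates,
                                      paste0(cfg$scaled_quad, "_sq",
                                             recycle0 = TRUE)), "]"))
  stopifnot(ncol(X) == length(beta_cols))
  coefs <- t(m[, beta_cols, drop = FALSE])        # ncoef x ndraw
  eta0 <- m[, paste0("beta0[", bcr, "]")]
  if (cfg$trend)
    eta0 <- eta0 + m[, paste0("mu[", bcr, "]")] * (year - cfg$t0)

  # psi at pixel locations
  if (cfg$spline) {
    cc <- cell_centers(geom)
    xy <- cbind(rep(cc$x, each = length(cc$y)), rep(cc$y, length(cc$x)))
    # as.vector(values) stacks columns: row index fastest -> y fastest
    Zp <- tps_eval(dat$basis, xy)
    psi_eta0 <- Zp %*% t(m[, paste0("b[", seq_len(ncol(dat$basis$Z)), "]"),
                           drop = FALSE])
    psi_eta0 <- sweep(psi_eta0, 2, m[, "a0"], `+`)
    psi <- stats::plogis(clamp(psi_eta0, -30, 30))  # npix x ndraw
  } else {
    p <- cfg$fixed$psi; if (is.null(p)) p <- 1
    psi <- matrix(p, npix, nrow(m))
  }

  lam <- exp(clamp(X %*% coefs +
                     matrix(eta0, npix, nrow(m), byrow = TRUE), -700, 30))
  med <- apply(lam * psi, 1, stats::median)
  dens <- density_from_prediction(med, dat$maxd)

  mask_dist <- rep(0, npix)
  if (!is.null(mask_covariate)) {
    mx <- max(train[[mask_covariate]] * std$scale[mask_covariate] +
                std$center[mask_covariate], na.rm = TRUE)
    mask_dist <- as.numeric(pix[[mask_covariate]]$raw > mx)
  }
  mask_qa <- rep(0, npix)
  for (cv in covs) {
    qb <- stats::quantile(train[[cv]], qa_quantiles, na.rm = TRUE)
    mask_qa <- pmax(mask_qa,
                    as.numeric(pix[[cv]]$std < qb[1] | pix[[cv]]$std > qb[2]))
  }
  nap <- vapply(covs, function(cv) is.na(pix[[cv]]$raw), logical(npix))
  nap <- if (is.matrix(nap)) rowSums(nap) > 0 else any(nap)
  dens[mask_dist == 1 | mask_qa == 1 | nap] <- NA_real_
  mask_dist[nap] <- NA; mask_qa[nap] <- NA

  shape <- dim(geom$values)
  band <- function(v, nm) covariate_raster(matrix(v, shape[1], shape[2]),
                                           geom$cell_size, geom$xll,
                                           geom$yll, name = nm, year = year)
  structure(list(density = band(dens, "density"),
                 mask_disturbance = band(mask_dist, "mask_disturbance"),
                 mask_qa = band(mask_qa, "mask_qa"),
                 scale_modes = modes, year = year, bcr = bcr,
                 maxd = dat$maxd),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  v <- x$density$values
  cat(sprintf("<density_surface> year %s, BCR %s: median %.2f birds/km2 (%.0f%% masked)\n",
              x$year, x$bcr, stats::median(v, na.rm = TRUE),
              100 * mean(is.na(v))))
  invisible(x)
}

#' Write a density surface as ASCII-grid bands
#'
#' Three plain-text rasters: `<prefix>_density.asc`,
#' `<prefix>_mask_disturbance.asc`, `<prefix>_mask_qa.asc`.
#'
#' @param surface A `density_surface`.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_density_surface <- function(surface, prefix) {
  paths <- c(paste0(prefix, "_density.asc"),
             paste0(prefix, "_mask_disturbance.asc"),
             paste0(prefix, "_mask_qa.asc"))
  write_ascii_grid(surface$density, paths[1])
  write_ascii_grid(surface$mask_disturbance, paths[2])
  write_ascii_grid(surface$mask_qa, paths[3])
  invisible(paths)
}
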