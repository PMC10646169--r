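#' Model configuration
#'
#' Collects the structural choices and priors of the density-habitat model:
#' which covariates enter with a fixed summarization radius (the `beta`
#' block), which get a continuous scale-of-effect parameter (the `Gamma`
#' block), optional quadratic terms, the spatial-spline dimension for the
#' zero-inflation probability, and the prior hyperparameters.
#'
#' Priors (defaults): regression, availability and detection coefficients
#' `Normal(0, 100^2)`; `log(omega) ~ Uniform(-12, 12)`;
#' `sd.survey ~ Uniform(0, 5)`; BCR (intercept, trend) pairs multivariate
#' normal with inverse-Wishart covariance, scale `diag(500, 1)`, 3 df;
#' scale-of-effect radii `Uniform(0, 10000)` m.
#'
#' @param fixed_covariates Covariate names entering at a fixed radius.
#' @param scaled_covariates Covariate names with scale-of-effect selection.
#' @param fixed_quad,scaled_quad Subsets of the above that also get a
#'   quadratic term (conventionally elevation and NDVI; the quadratic is the
#'   square of the standardized linear term and shares its radius).
#' @param spline Model the zero-inflation probability with a 2-D spline?
#' @param K Spline basis dimension (default 100; reduce for desk-scale
#'   fits).
#' @param survey_effect Include the lognormal survey-level random effect?
#' @param trend Include per-BCR linear year trends?
#' @param B Number of distance bins.
#' @param trunc_q Distance-truncation quantile (default 0.90).
#' @param t0 Trend time origin (default 2008).
#' @param fixed Named list of parameters to hold fixed during fitting
#'   (e.g. `list(psi = 1, sd_survey = 0)`); used by degenerate-model checks.
#' @param prior_sd,R_wish,df_wish,log_omega_range,sd_survey_max,scale_range
#'   Prior hyperparameters.
#' @param min_bcr_detections Drop BCRs with fewer detections than this
#'   (0 = off, the default).
#' @return An object of class `model_config`.
#' @export
model_config <- function(fixed_covariates = character(),
                         scaled_covariates = character(),
                         fixed_quad = character(),
                         scaled_quad = character(),
                         spline = TRUE, K = 100,
                         survey_effect = TRUE, trend = TRUE,
                         B = 10, trunc_q = 0.90, t0 = 2008,
                         fixed = list(),
                         prior_sd = 100,
                         R_wish = diag(c(500, 1)), df_wish = 3,
                         log_omega_range = c(-12, 12),
                         sd_survey_max = 5,
                         scale_range = c(0, 10000),
                         min_bcr_detections = 0) {
  stopifnot(all(fixed_quad %in% fixed_covariates),
            all(scaled_quad %in% scaled_covariates),
            K >= 3, B >= 1, trunc_q > 0, trunc_q <= 1)
  if (!is.null(fixed$psi)) spline <- FALSE
  if (!is.null(fixed$sd_survey) && fixed$sd_survey == 0)
    survey_effect <- FALSE
  structure(list(
    fixed_covariates = fixed_covariates,
    scaled_covariates = scaled_covariates,
    fixed_quad = fixed_quad, scaled_quad = scaled_quad,
    spline = spline, K = K, survey_effect = survey_effect, trend = trend,
    B = B, trunc_q = trunc_q, t0 = t0, fixed = fixed,
    prior_sd = prior_sd, R_wish = R_wish, df_wish = df_wish,
    log_omega_range = log_omega_range, sd_survey_max = sd_survey_max,
    scale_range = scale_range, min_bcr_detections = min_bcr_detections),
    class = "model_config")
}

#' Assemble model-ready data
#'
#' Validates and cross-links the survey panel, detection records and
#' covariate stack into the fixed quantities the likelihood needs: distance
#' truncation and binning, per-survey detection tallies by minute and
#' distance bin, standardized observation covariates, fixed-covariate design
#' matrix, per-covariate radius tables for scale interpolation, the spatial
#' spline basis, and grid/BCR index structures.
#'
#' @param surveys Survey panel (see [read_surveys]); one row per grid-year.
#' @param detections Detection records for one species (see
#'   [read_detections]).
#' @param stack A standardized [buffer_stack] covering the panel's grids and
#'   years (standardized automatically, with a message, if raw).
#' @param config A [model_config].
#' @return An object of class `model_data`.
#' @export
prepare_model_data <- function(surveys, detections, stack, config) {
  stopifnot(inherits(config, "model_config"))
  if (anyDuplicated(paste(surveys$grid_id, surveys$year)))
    stop("survey panel has duplicate grid-year rows")
  if (!is.null(stack) && is.null(stack$center)) {
    message("standardizing covariate stack")
    stack <- standardize_stack(stack)
  }

  if (config$min_bcr_detections > 0 && nrow(detections)) {
    skey <- match(paste(detections$grid_id, detections$year),
                  paste(surveys$grid_id, surveys$year))
    tab <- table(surveys$bcr_id[skey])
    bad <- names(tab)[tab < config$min_bcr_detections]
    if (length(bad)) {
      message("dropping sparse BCR(s): ", paste(bad, collapse = ", "))
      surveys <- surveys[!as.character(surveys$bcr_id) %in% bad, ,
                         drop = FALSE]
    }
  }

  # contiguous grid blocks let per-grid sums use a cumsum trick (hot path)
  surveys <- surveys[order(as.character(surveys$grid_id), surveys$year), ,
                     drop = FALSE]
  rownames(surveys) <- NULL

  tr <- truncate_detections(detections, config$trunc_q)
  det <- tr$records
  maxd <- tr$maxd
  det$dclass <- distance_bin(det$distance_m, maxd, config$B)

  key_s <- paste(surveys$grid_id, surveys$year)
  det$survey <- match(paste(det$grid_id, det$year), key_s)
  if (anyNA(det$survey))
    stop("detection(s) reference grid-years absent from the survey panel: ",
         paste(utils::head(unique(
           paste(det$grid_id, det$year)[is.na(det$survey)]), 3),
           collapse = "; "))
  if (any(det$minute > surveys$minutes[det$survey]))
    stop("detection minute exceeds the survey's count length")

  nS <- nrow(surveys)
  Mmax <- max(surveys$minutes)
  y_min <- matrix(0L, nS, Mmax)
  y_bin <- matrix(0L, nS, config$B)
  if (nrow(det)) {
    tm <- table(factor(det$survey, levels = seq_len(nS)),
                factor(det$minute, levels = seq_len(Mmax)))
    y_min[] <- as.integer(tm)
    tb <- table(factor(det$survey, levels = seq_len(nS)),
                factor(det$dclass, levels = seq_len(config$B)))
    y_bin[] <- as.integer(tb)
  }
  d <- as.integer(rowSums(y_bin))

  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) s <- 1
    list(x = (v - mean(v)) / s, center = mean(v), scale = s)
  }
  od <- std(surveys$ordinal_date)
  ms <- std(surveys$mean_min_since_sunrise)
  z <- cbind(intercept = 1, experienced = surveys$observer_experienced,
             minutes_since_sunrise = ms$x)

  # fixed-radius covariates (value at their degenerate radius, else 564 m)
  xcols <- list()
  for (cv in config$fixed_covariates) {
    vm <- stack_rows(stack, cv, surveys$grid_id, surveys$year)
    xcols[[cv]] <- if (length(stack$radii) == 1L) vm[, 1L]
                   else interp_radius_matrix(vm, stack$radii,
                                             min(564, max(stack$radii)))
  }
  for (cv in config$fixed_quad) xcols[[paste0(cv, "_sq")]] <- xcols[[cv]]^2
  x <- if (length(xcols)) do.call(cbind, xcols) else
    matrix(0, nS, 0)

  W <- lapply(config$scaled_covariates, function(cv)
    stack_rows(stack, cv, surveys$grid_id, surveys$year))
  names(W) <- config$scaled_covariates
  # per-radius dispersion of each scaled covariate (and its square); the
  # sampler uses these to rescale Gamma when jumping between radii
  W_sd <- lapply(W, function(m) pmax(apply(m, 2, stats::sd), 1e-8))
  Wsq_sd <- lapply(W, function(m) pmax(apply(m^2, 2, stats::sd), 1e-8))

  grid_ids <- unique(as.character(surveys$grid_id))
  gidx <- match(as.character(surveys$grid_id), grid_ids)
  stopifnot(!is.unsorted(gidx))
  nG <- length(grid_ids)
  gends <- cumsum(tabulate(gidx, nG))
  anyd <- as.vector(rowsum(d, gidx) > 0)

  basis <- NULL
  if (config$spline) {
    cent <- surveys[!duplicated(as.character(surveys$grid_id)),
                    c("easting", "northing")]
    basis <- tps_basis(cent, config$K)
  }

  bcr_levels <- as.character(sort(unique(surveys$bcr_id)))
  structure(list(
    surveys = surveys, detections = det, stack = stack, config = config,
    maxd = maxd, d = d, lgamma_d1 = lgamma(d + 1),
    y_min = y_min, y_bin = y_bin, Mmax = Mmax,
    M = surveys$minutes, E = od$x, E_std = od[c("center", "scale")],
    mins_std = ms[c("center", "scale")], z = z, x = x, W = W,
    W_sd = W_sd, Wsq_sd = Wsq_sd,
    radii = stack$radii, offset = log(surveys$n_points),
    year = surveys$year, bcr = as.character(surveys$bcr_id),
    bcr_levels = bcr_levels,
    bcr_idx = match(as.character(surveys$bcr_id), bcr_levels),
    grid_ids = grid_ids, gidx = gidx, gends = gends, nG = nG, nS = nS,
    anyd = anyd,
    basis = basis),
    class = "model_data")
}

#' @export
print.model_data <- function(x, ...) {
  cat(sprintf(paste0("<model_data> %d surveys on %d grids, %d BCR(s), ",
                     "%d detections (maxd %.1f m)\n"),
              x$nS, x$nG, length(x$bcr_levels), sum(x$d), x$maxd))
  cat(sprintf("  fixed covariates: %s | scale-selected: %s\n",
              paste(colnames(x$x), collapse = ", "),
              paste(names(x$W), collapse = ", ")))
  invisible(x)
}
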