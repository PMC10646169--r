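#' Configuration for a synthetic point-count study
#'
#' Describes a complete synthetic world with the structure the analysis
#' assumes: 1-km2 grids holding up to 16 point-count stations, 5-minute
#' counts in the first two program years and 6-minute counts after,
#' detections binned by distance and minute, BCR membership, smooth
#' landscape covariate fields with known scales of effect, and a spatially
#' varying range indicator. True parameter values are drawn once from the
#' seed (and written into fixture manifests) unless supplied explicitly via
#' `truth`.
#'
#' @param n_grids,n_years,n_bcrs Panel dimensions.
#' @param K_points Stations per grid (<= 16).
#' @param incomplete_frac Fraction of surveys with fewer than `K_points`
#'   completed counts (effort varies in real programs).
#' @param cell_size Raster cell size in meters.
#' @param radii Buffer radii tabulated in the covariate stack.
#' @param scaled_covariates,fixed_covariates Covariate names to generate.
#' @param spline Spatially varying zero-inflation (vs `psi = 1`)?
#' @param survey_effect Lognormal survey-level overdispersion?
#' @param perfect_detection Every individual detected (pmarg = 1); used by
#'   degenerate checks.
#' @param r_sim Radius (m) of the disk on which individuals are placed
#'   around a station.
#' @param start_year First program year (5-minute counts in the first two).
#' @param seed Seed; drives both the truth draw and [simulate_study].
#' @param truth Optional named list overriding any drawn true parameter.
#' @return An object of class `sim_config` with a `truth` element.
#' @export
sim_config <- function(n_grids = 300, n_years = 5, n_bcrs = 2,
                       K_points = 16, incomplete_frac = 0.3,
                       cell_size = 250, radii = seq(0, 10000, by = 100),
                       scaled_covariates = c("sagebrush", "pinyon_juniper"),
                       fixed_covariates = "elevation",
                       spline = TRUE, survey_effect = TRUE,
                       perfect_detection = FALSE, r_sim = 125,
                       start_year = 2008, seed = 1L, truth = list()) {
  stopifnot(K_points >= 1, K_points <= 16, n_grids >= 2, n_years >= 1)
  nB <- n_bcrs
  tr <- withr_seed(seed * 1000L + 7L, {
    nSc <- length(scaled_covariates)
    nF <- length(fixed_covariates)
    list(
      alpha = stats::qlogis(0.35),
      A = c(0.10, -0.15),
      tau = c(log(70), 0.10, -0.05),
      beta0 = stats::setNames(stats::rnorm(nB, -1.0, 0.3), seq_len(nB)),
      mu = stats::setNames(stats::rnorm(nB, 0.02, 0.04), seq_len(nB)),
      beta = stats::setNames(stats::rnorm(nF, 0, 0.3), fixed_covariates),
      Gamma = stats::setNames(0.5 * sample(c(-1, 1), nSc, replace = TRUE),
                              scaled_covariates),
      scales = stats::setNames(
        stats::runif(nSc, 0.05 * max(radii), 0.4 * max(radii)),
        scaled_covariates),
      sd_survey = 0.25,
      a0 = 1.2, psi_amp = 1.5)
  })
  tr[names(truth)] <- truth
  structure(list(n_grids = n_grids, n_years = n_years, n_bcrs = n_bcrs,
                 K_points = K_points, incomplete_frac = incomplete_frac,
                 cell_size = cell_size, radii = radii,
                 scaled_covariates = scaled_covariates,
                 fixed_covariates = fixed_covariates,
                 spline = spline, survey_effect = survey_effect,
                 perfect_detection = perfect_detection, r_sim = r_sim,
                 start_year = start_year, seed = as.integer(seed),
                 truth = tr),
            class = "sim_config")
}

# Smooth covariate field: white noise blurred with separable Gaussian
# kernels at several correlation ranges, plus a white-noise floor. A
# positive-definite monotone covariance makes buffer means at different
# radii positively correlated with smoothly decaying strength, which is
# what keeps the scale-of-effect parameter identifiable (periodic surfaces
# produce sign-flipping disk-mean correlations and mirror modes).
smooth_noise <- function(ny, nx, range_cells) {
  pad <- ceiling(3 * range_cells)
  k <- -pad:pad
  w <- stats::dnorm(k, 0, range_cells)
  w <- w / sum(w)
  z <- matrix(stats::rnorm((ny + 2 * pad) * (nx + 2 * pad)),
              ny + 2 * pad, nx + 2 * pad)
  z <- apply(z, 2, function(col) stats::filter(col, w, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, w, sides = 2)))
  z <- z[pad + seq_len(ny), pad + seq_len(nx)]
  z / stats::sd(z)
}

gaussian_mix_field <- function(xg, yg, cs,
                               ranges_m = c(600, 2000, 6000),
                               amps = c(1.0, 0.9, 0.7),
                               noise_sd = 0.4) {
  ny <- length(yg); nx <- length(xg)
  f <- matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
  for (h in seq_along(ranges_m))
    f <- f + amps[h] * smooth_noise(ny, nx, ranges_m[h] / cs)
  f
}

#' Simulate a complete synthetic study
#'
#' Runs the full generative model forward: covariate rasters are built and
#' summarized into a buffer stack, the habitat model at the true scales
#' gives expected abundance per survey, the spatial field gives the range
#' indicator, true abundance is zero-inflated Poisson, and every individual
#' is simulated explicitly through the removal and distance observation
#' process (so detections never exceed true abundance by construction).
#'
#' @param config A [sim_config].
#' @param seed Seed for the realization (defaults to `config$seed`).
#' @return A `synthetic_study`: `rasters`, `surveys`, `detections`,
#'   `stack` (raw), `stack_std` (standardized), `grids`, and `truth` (the
#'   parameters plus the full latent state: `psi`, `Active`, `N`, `lambda`,
#'   `pa`, `pd`, `pmarg`, `eps` per survey).
#' @export
simulate_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  tr <- config$truth
  cs <- config$cell_size
  rmax <- max(config$radii)

  # grid centroids on a 1-km lattice (non-overlapping 1-km2 cells)
  side_km <- ceiling(sqrt(config$n_grids * 4))
  lat <- expand.grid(e = seq_len(side_km) * 1000, n = seq_len(side_km) * 1000)
  pick <- sample(nrow(lat), config$n_grids)
  grids <- data.frame(grid_id = paste0("g", seq_len(config$n_grids)),
                      easting = lat$e[pick], northing = lat$n[pick])
  # spatially coherent BCR bands by easting
  br <- stats::quantile(grids$easting, seq(0, 1, length.out = config$n_bcrs + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  grids$bcr_id <- as.integer(cut(grids$easting, br, labels = FALSE))

  # rasters covering the largest buffer around every grid
  xll <- min(grids$easting) - rmax - cs
  yll <- min(grids$northing) - rmax - cs
  nx <- ceiling((max(grids$easting) + rmax + cs - xll) / cs)
  ny <- ceiling((max(grids$northing) + rmax + cs - yll) / cs)
  xg <- xll + (seq_len(nx) - 0.5) * cs
  yg <- yll + ny * cs - (seq_len(ny) - 0.5) * cs
  covs <- c(config$scaled_covariates, config$fixed_covariates)
  rasters <- lapply(covs, function(cv)
    covariate_raster(gaussian_mix_field(xg, yg, cs), cs, xll, yll,
                     name = cv, year = NA_integer_))
  names(rasters) <- covs

  stack <- build_buffer_stack(rasters, grids, radii = config$radii,
                              years = config$start_year +
                                seq_len(config$n_years) - 1L)
  stack_std <- standardize_stack(stack)

  years <- config$start_year + seq_len(config$n_years) - 1L
  sv <- expand.grid(grid_id = grids$grid_id, year = years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(sv$grid_id, grids$grid_id)
  sv$bcr_id <- grids$bcr_id[gi]
  sv$easting <- grids$easting[gi]
  sv$northing <- grids$northing[gi]
  sv$minutes <- ifelse(sv$year - config$start_year < 2, 5L, 6L)
  sv$n_points <- ifelse(stats::runif(nrow(sv)) < config$incomplete_frac,
                        sample(8:15, nrow(sv), replace = TRUE),
                        config$K_points)
  sv$ordinal_date <- sample(152:190, nrow(sv), replace = TRUE)
  sv$mean_min_since_sunrise <- round(stats::runif(nrow(sv), 30, 240), 1)
  sv$observer_experienced <- stats::rbinom(nrow(sv), 1, 0.7)
  nS <- nrow(sv)

  # linear predictor at the true scales (standardized covariate values)
  wm <- vapply(config$scaled_covariates, function(cv)
    interp_radius_matrix(stack_rows(stack_std, cv, sv$grid_id, sv$year),
                         config$radii, tr$scales[cv]), numeric(nS))
  wm <- matrix(wm, nS)
  xm <- vapply(config$fixed_covariates, function(cv)
    interp_radius_matrix(stack_rows(stack_std, cv, sv$grid_id, sv$year),
                         config$radii, min(564, max(config$radii))),
    numeric(nS))
  xm <- matrix(xm, nS)
  eta <- tr$beta0[sv$bcr_id] + tr$mu[sv$bcr_id] * (sv$year - config$start_year) +
    log(sv$n_points)
  if (length(tr$beta)) eta <- eta + as.vector(xm %*% tr$beta)
  if (length(tr$Gamma)) eta <- eta + as.vector(wm %*% tr$Gamma)
  eps <- if (config$survey_effect)
    stats::rnorm(nS, 0, tr$sd_survey) else numeric(nS)
  lambda <- exp(eta + eps)

  # spatially varying range indicator (time-constant)
  if (config$spline) {
    e0 <- (grids$easting - mean(grids$easting)) / 1000
    n0 <- (grids$northing - mean(grids$northing)) / 1000
    span <- max(diff(range(e0)), 1)
    f <- tr$psi_amp * cos(pi * e0 / span) * sin(pi * n0 / span + 0.5)
    psi <- stats::plogis(tr$a0 + f)
  } else psi <- rep(1, config$n_grids)
  Active <- stats::rbinom(config$n_grids, 1, psi)
  N <- stats::rpois(nS, lambda * Active[gi])

  # observation process: per-minute availability and half-normal detection
  Ed <- (sv$ordinal_date - mean(sv$ordinal_date)) / stats::sd(sv$ordinal_date)
  a <- stats::plogis(tr$alpha + tr$A[1] * Ed + tr$A[2] * Ed^2)
  pa <- 1 - (1 - a)^sv$minutes
  msd <- (sv$mean_min_since_sunrise - mean(sv$mean_min_since_sunrise)) /
    stats::sd(sv$mean_min_since_sunrise)
  sigma <- exp(tr$tau[1] + tr$tau[2] * sv$observer_experienced +
                 tr$tau[3] * msd)

  si <- rep(seq_len(nS), N)
  det <- data.frame()
  if (length(si)) {
    minute <- stats::rgeom(length(si), a[si]) + 1L
    dist <- config$r_sim * sqrt(stats::runif(length(si)))
    if (config$perfect_detection) {
      seen <- rep(TRUE, length(si))
      minute <- pmin(minute, sv$minutes[si])
    } else {
      avail <- minute <= sv$minutes[si]
      gdet <- exp(-dist^2 / (2 * sigma[si]^2))
      seen <- avail & stats::runif(length(si)) < gdet
    }
    det <- data.frame(
      grid_id = sv$grid_id[si][seen], year = sv$year[si][seen],
      species = "SIMSP", distance_m = round(dist[seen], 1),
      minute = minute[seen],
      observer_experienced = sv$observer_experienced[si][seen],
      flyover = 0L, migrant = 0L)
  }

  # pd over the placement disk (for the truth record)
  pd_disk <- vapply(sigma, function(s) {
    r <- config$r_sim
    2 * s^2 / r^2 * (1 - exp(-r^2 / (2 * s^2)))
  }, 1)

  structure(list(config = config, grids = grids, rasters = rasters,
                 surveys = sv, detections = det,
                 stack = stack, stack_std = stack_std,
                 truth = c(tr, list(psi = psi, Active = Active, N = N,
                                    lambda = lambda, eps = eps, a = a,
                                    pa = pa, sigma = sigma, pd = pd_disk,
                                    pmarg = if (config$perfect_detection)
                                      rep(1, nS) else pa * pd_disk))),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d grids x %d years, %d BCR(s), %d detections\n",
              x$config$n_grids, x$config$n_years, x$config$n_bcrs,
              nrow(x$detections)))
  invisible(x)
}

#' Model configuration matching a synthetic study
#'
#' @param study A `synthetic_study` (or a [sim_config]).
#' @param K Spline basis dimension for fitting (default 20 at desk scale).
#' @param ... Passed on to [model_config].
#' @return A [model_config].
#' @export
model_config_from_sim <- function(study, K = 20, ...) {
  cfg <- if (inherits(study, "synthetic_study")) study$config else study
  model_config(fixed_covariates = cfg$fixed_covariates,
               scaled_covariates = cfg$scaled_covariates,
               spline = cfg$spline, K = K,
               survey_effect = cfg$survey_effect,
               t0 = cfg$start_year, ...)
}

#' Write / load an on-disk synthetic fixture
#'
#' Writes the plain-text interchange set for a named study size:
#' `surveys.csv`, `detections.csv`, `grids.csv`, `stack.csv` (raw buffer
#' means), one ASCII grid per covariate under `rasters/`, and a
#' `manifest.json` recording the configuration and the drawn true
#' parameters. Sizes: tiny = 20 grids x 2 years, small = 300 x 5,
#' medium = 1000 x 8.
#'
#' @param size `"tiny"`, `"small"` or `"medium"`.
#' @param seed Master seed.
#' @param dir Output directory (created).
#' @return The `synthetic_study`, invisibly.
#' @export
fixture_suite <- function(size = c("tiny", "small", "medium"), seed = 1L,
                          dir) {
  size <- match.arg(size)
  args <- switch(size,
    tiny = list(n_grids = 20, n_years = 2, n_bcrs = 1),
    small = list(n_grids = 300, n_years = 5, n_bcrs = 2),
    medium = list(n_grids = 1000, n_years = 8, n_bcrs = 2))
  cfg <- do.call(sim_config, c(args, list(seed = seed)))
  study <- simulate_study(cfg)
  write_study(study, dir)
  invisible(study)
}

#' @rdname fixture_suite
#' @param study A `synthetic_study` to write.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "rasters"), showWarnings = FALSE)
  seed <- study$config$seed
  write_csv_prov(study$surveys, file.path(dir, "surveys.csv"), seed)
  write_csv_prov(study$detections, file.path(dir, "detections.csv"), seed)
  write_csv_prov(study$grids, file.path(dir, "grids.csv"), seed)
  write_stack_csv(study$stack, file.path(dir, "stack.csv"))
  for (nm in names(study$rasters))
    write_ascii_grid(study$rasters[[nm]],
                     file.path(dir, "rasters", paste0(nm, ".asc")))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    man <- study$config
    class(man) <- NULL
    man$truth <- lapply(study$truth[c("alpha", "A", "tau", "beta0", "mu",
                                      "beta", "Gamma", "scales",
                                      "sd_survey", "a0", "psi_amp")],
                        unclass)
    jsonlite::write_json(man, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a fixture written by [write_study]
#'
#' @param dir Fixture directory.
#' @return List with `surveys`, `detections`, `grids`, `stack`, `rasters`,
#'   and `manifest` (when present).
#' @export
load_study <- function(dir) {
  surveys <- read_surveys(file.path(dir, "surveys.csv"))
  detections <- read_detections(file.path(dir, "detections.csv"),
                                quiet = TRUE)
  grids <- utils::read.csv(file.path(dir, "grids.csv"), comment.char = "#")
  stack <- read_stack_csv(file.path(dir, "stack.csv"))
  rfiles <- list.files(file.path(dir, "rasters"), pattern = "\\.asc$",
                       full.names = TRUE)
  rasters <- lapply(rfiles, read_ascii_grid)
  names(rasters) <- vapply(rasters, `[[`, "", "name")
  man <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf) && requireNamespace("jsonlite", quietly = TRUE))
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  list(surveys = surveys, detections = detections, grids = grids,
       stack = stack, rasters = rasters, manifest = man)
}
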