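#' Log expected abundance
#'
#' The log-linear habitat model for the mean expected number of individuals
#' in a grid-year:
#' `log(mu.lambda) = beta0[bcr] + beta . x + Gamma . w + mu[bcr] * (t - t0) + offset`
#' where `x` are fixed-scale covariates, `w` are covariates interpolated at
#' their estimated spatial scales, and the offset is the log number of point
#' counts conducted (effort).
#'
#' @param beta0_r Named vector of BCR intercepts.
#' @param beta Fixed-covariate coefficients (length = `ncol(x)`).
#' @param Gamma Scale-selected covariate coefficients (length = `ncol(w)`).
#' @param mu_r Named vector of BCR trend slopes (per year since `t0`).
#' @param x,w Design matrices (rows = surveys); either may have 0 columns.
#' @param bcr Vector of BCR ids per survey.
#' @param t Calendar year per survey.
#' @param offset Log effort per survey.
#' @param t0 Trend time origin (default 2008).
#' @return Vector of `log(mu.lambda)` per survey.
#' @export
log_mu_lambda <- function(beta0_r, beta, Gamma, mu_r, x, w, bcr, t, offset,
                          t0 = 2008) {
  bi <- match(as.character(bcr), names(beta0_r))
  if (anyNA(bi)) stop("unknown BCR id(s): ",
                      paste(unique(bcr[is.na(bi)]), collapse = ", "))
  if (!identical(names(beta0_r), names(mu_r)))
    stop("beta0_r and mu_r must be indexed by the same BCRs")
  eta <- beta0_r[bi] + mu_r[bi] * (t - t0) + offset
  if (length(beta)) eta <- eta + as.vector(as.matrix(x) %*% beta)
  if (length(Gamma)) eta <- eta + as.vector(as.matrix(w) %*% Gamma)
  unname(eta)
}

#' Survey-level overdispersion
#'
#' Perturbs the expected abundance with a survey-level (grid-year) random
#' effect. The effect is placed on the log scale (lognormal
#' overdispersion), so `log(lambda) = log(mu.lambda) + eps`,
#' `eps ~ Normal(0, sd_survey)`, keeping `lambda > 0` always.
#'
#' @param mu_lambda Expected abundance (vector).
#' @param sd_survey Random-effect standard deviation (>= 0).
#' @param eps Optional standard-normal-scale draws; generated if missing.
#' @return Vector of `lambda` draws (`mu_lambda` exactly when
#'   `sd_survey = 0`).
#' @export
survey_effect <- function(mu_lambda, sd_survey, eps = NULL) {
  stopifnot(sd_survey >= 0)
  if (is.null(eps)) eps <- stats::rnorm(length(mu_lambda), 0, sd_survey)
  else eps <- eps * if (sd_survey == 0) 0 else 1
  mu_lambda * exp(eps)
}

#' Marginal zero-inflated, thinned Poisson log-likelihood
#'
#' Log-likelihood of an observed count with the latent true abundance `N`
#' and the range indicator `Active` summed out, using the thinning identity
#' `Binomial(N, p)` over `N ~ Poisson(lambda)` giving `Poisson(lambda p)`:
#' `log[(1 - psi) 1{d = 0} + psi * Poisson(d; lambda * pmarg)]`.
#'
#' @param d Observed count (non-negative integer; vectorized).
#' @param lambda Expected abundance.
#' @param pmarg Joint detection probability in (0, 1].
#' @param psi Probability the grid lies within the usable range, in (0, 1].
#' @return Vector of log-likelihood contributions.
#' @export
zip_marginal_loglik <- function(d, lambda, pmarg, psi) {
  if (any(d < 0) || any(d != floor(d))) stop("d must be non-negative integers")
  if (any(pmarg <= 0 | pmarg > 1)) stop("pmarg must lie in (0, 1]")
  lp_pois <- stats::dpois(d, lambda * pmarg, log = TRUE)
  # log( (1-psi) [d == 0] + psi exp(lp_pois) ), stably
  out <- log(psi) + lp_pois
  psi <- rep_len(psi, length(out))
  z <- d == 0 & psi < 1
  if (any(z)) {
    a <- log1p(-psi[z])
    b <- log(psi[z]) + lp_pois[z]
    m <- pmax(a, b)
    out[z] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}

#' Thin-plate-style spatial basis
#'
#' Builds a two-dimensional thin-plate radial basis over grid-centroid
#' coordinates: two standardized linear terms plus `K - 3` radial terms
#' `phi(r) = r^2 log(r)` centered on k-means space-filling knots, for a
#' total of `K - 1` columns (the intercept `a0` is carried separately by
#' the model). Smoothing enters downstream as a Gaussian precision `omega`
#' on the radial coefficients.
#'
#' @param coords Data frame or matrix with easting/northing columns
#'   (meters).
#' @param K Total basis dimension including the intercept (`K >= 3`).
#' @param seed Seed for the k-means knot placement (kept explicit so a
#'   basis is reproducible).
#' @return An object of class `tps_basis`: `Z` (design matrix, `K - 1`
#'   columns), `penalized` (logical per column; `TRUE` for radial terms),
#'   plus the knots and standardization constants needed to evaluate the
#'   basis at new coordinates via [tps_eval].
#' @export
tps_basis <- function(coords, K, seed = 1L) {
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (K < 3) stop("K must be at least 3")
  ux <- unique(xy)
  if (nrow(ux) < K)
    stop(sprintf("only %d distinct coordinates for K = %d basis dimensions%s",
                 nrow(ux), K,
                 if (nrow(ux) < nrow(xy)) " (duplicate-heavy coordinates)"
                 else ""))
  ctr <- colMeans(xy)
  scl <- apply(xy, 2, stats::sd)
  scl[scl == 0] <- 1
  n_rad <- K - 3L
  knots <- NULL
  if (n_rad > 0) {
    zs <- sweep(sweep(ux, 2, ctr), 2, scl, "/")
    km <- withr_seed(seed, stats::kmeans(zs, centers = n_rad,
                                         nstart = 5, iter.max = 50))
    knots <- km$centers
  }
  b <- structure(list(knots = knots, center = ctr, scale = scl, K = K),
                 class = "tps_basis")
  Zr <- tps_eval(b, xy)
  # center and unit-scale the radial columns (computed on the training
  # coordinates, reused for prediction): decorrelates them from the
  # intercept and evens out coefficient scales for the sampler
  if (n_rad > 0) {
    rc <- 2 + seq_len(n_rad)
    b$col_center <- colMeans(Zr[, rc, drop = FALSE])
    b$col_scale <- pmax(apply(Zr[, rc, drop = FALSE], 2, stats::sd), 1e-8)
  }
  Z <- tps_eval(b, xy)
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1)
    stop("spatial basis is rank deficient; coordinates too duplicate-heavy ",
         "(rank ", qrz$rank, " < ", ncol(Z) + 1, ")")
  b$Z <- Z
  b$penalized <- c(FALSE, FALSE, rep(TRUE, n_rad))
  b
}

# evaluate stats::kmeans (or any expression) under a local RNG seed
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Evaluate a spatial basis at (new) coordinates
#'
#' @param basis A [tps_basis].
#' @param coords Matrix/data frame of easting/northing.
#' @return Design matrix with `K - 1` columns.
#' @export
tps_eval <- function(basis, coords) {
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  zs <- sweep(sweep(xy, 2, basis$center), 2, basis$scale, "/")
  Z <- zs
  colnames(Z) <- c("east", "north")
  if (!is.null(basis$knots)) {
    R <- matrix(0, nrow(zs), nrow(basis$knots))
    for (k in seq_len(nrow(basis$knots))) {
      r2 <- (zs[, 1] - basis$knots[k, 1])^2 + (zs[, 2] - basis$knots[k, 2])^2
      R[, k] <- ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
    }
    if (!is.null(basis$col_center))
      R <- sweep(sweep(R, 2, basis$col_center), 2, basis$col_scale, "/")
    colnames(R) <- paste0("tps", seq_len(ncol(R)))
    Z <- cbind(Z, R)
  }
  Z
}

#' Penalized fit of a spatial field on a thin-plate basis
#'
#' Ridge-penalized (IRLS for binomial) fit of `y ~ a0 + Z b` with penalty
#' `omega/2 * sum(b_k^2)` on the radial coefficients. Used for
#' initialization and for desk checks of the basis; the full model estimates
#' these coefficients by MCMC.
#'
#' @param basis A [tps_basis].
#' @param y Response (Gaussian) or 0/1 indicator (binomial).
#' @param omega Gaussian precision on penalized coefficients.
#' @param family `"gaussian"` or `"binomial"`.
#' @return List `a0`, `b` (coefficients), `fitted` (linear predictor at the
#'   training coordinates).
#' @export
fit_tps <- function(basis, y, omega = 1, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  X <- cbind(a0 = 1, basis$Z)
  pen <- c(FALSE, basis$penalized)
  P <- diag(ifelse(pen, omega, 1e-8), ncol(X))
  if (family == "gaussian") {
    co <- solve(crossprod(X) + P, crossprod(X, y))
  } else {
    co <- rep(0, ncol(X))
    for (it in 1:50) {
      eta <- as.vector(X %*% co)
      p <- stats::plogis(eta)
      wt <- pmax(p * (1 - p), 1e-6)
      z <- eta + (y - p) / wt
      co_new <- solve(crossprod(X * sqrt(wt)) + P,
                      crossprod(X, wt * z))
      if (max(abs(co_new - co)) < 1e-8) { co <- co_new; break }
      co <- co_new
    }
  }
  co <- as.vector(co)
  list(a0 = co[1], b = co[-1], fitted = as.vector(X %*% co))
}

#' Random-effects prior for BCR intercepts and trends
#'
#' Log prior density of the per-BCR (intercept, trend) pairs under a
#' bivariate normal with mean `mu_wish` and covariance `Sigma_w`, plus the
#' inverse-Wishart log density of `Sigma_w` itself.
#'
#' @param beta0_r,mu_r Named per-BCR vectors (same BCRs, same order).
#' @param Sigma_w 2x2 symmetric positive-definite covariance.
#' @param mu_wish Length-2 prior mean of the pairs.
#' @param R Inverse-Wishart scale matrix (default `diag(c(500, 1))`).
#' @param df Inverse-Wishart degrees of freedom (default 3).
#' @return List `lp_pairs` (MVN part), `lp_sigma` (inverse-Wishart part),
#'   `lp` (their sum).
#' @export
bcr_random_effects_prior <- function(beta0_r, mu_r, Sigma_w,
                                     mu_wish = c(0, 0),
                                     R = diag(c(500, 1)), df = 3) {
  stopifnot(length(beta0_r) == length(mu_r))
  Sigma_w <- (Sigma_w + t(Sigma_w)) / 2
  ev <- eigen(Sigma_w, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma_w must be positive-definite")
  pairs <- cbind(beta0_r, mu_r)
  lp_pairs <- sum(dmvnorm2(pairs, mu_wish, Sigma_w))
  lp_sigma <- dinvwishart(Sigma_w, R, df)
  list(lp_pairs = lp_pairs, lp_sigma = lp_sigma, lp = lp_pairs + lp_sigma)
}

# bivariate (general p) multivariate normal log density, rows of x
dmvnorm2 <- function(x, mean, Sigma) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  p <- ncol(x)
  ch <- chol(Sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# inverse-Wishart log density of Sigma with scale R, df nu
dinvwishart <- function(Sigma, R, nu) {
  p <- ncol(Sigma)
  ldR <- determinant(R, logarithm = TRUE)$modulus
  ldS <- determinant(Sigma, logarithm = TRUE)$modulus
  tr <- sum(diag(R %*% solve(Sigma)))
  as.numeric(0.5 * nu * ldR - 0.5 * nu * p * log(2) - lmvgamma(nu / 2, p) -
             0.5 * (nu + p + 1) * ldS - 0.5 * tr)
}

lmvgamma <- function(a, p) {
  0.25 * p * (p - 1) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

#' Detection-cell log-likelihood
#'
#' Sum over detections of the log conditional minute-interval and
#' distance-bin cell probabilities (categorical likelihood of `tint` and
#' `dclass` given detection).
#'
#' @param records Data frame with columns `survey` (row index into the cell
#'   matrices), `minute`, `dclass`.
#' @param pi_a_c Conditional minute-cell matrix (rows = surveys, each row
#'   sums to 1).
#' @param pi_d_c Conditional distance-cell matrix (rows = surveys).
#' @return Total log-likelihood; `-Inf` (with a warning naming the first
#'   offender) if any detection falls in a zero-probability cell.
#' @export
cell_loglik_detections <- function(records, pi_a_c, pi_d_c) {
  if (!nrow(records)) return(0)
  pa_cell <- pi_a_c[cbind(records$survey, records$minute)]
  pd_cell <- pi_d_c[cbind(records$survey, records$dclass)]
  if (any(pa_cell <= 0) || any(pd_cell <= 0)) {
    bad <- which(pa_cell <= 0 | pd_cell <= 0)[1]
    warning(sprintf("detection %d falls in a zero-probability cell", bad))
    return(-Inf)
  }
  sum(log(pa_cell)) + sum(log(pd_cell))
}
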