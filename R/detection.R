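#' Removal-model availability cells
#'
#' Geometric minute-interval cell probabilities for the removal model of
#' availability: an individual first becomes available in minute `m` with
#' probability `a (1 - a)^(m - 1)`, and is available at least once during an
#' `M`-minute count with probability `pa = 1 - (1 - a)^M`.
#'
#' @param a Per-minute availability probability, strictly in (0, 1). May be
#'   a vector (one survey per element).
#' @param M Minutes per count (5 in the first two program years, 6 after).
#' @return List with `pi_a` (`length(a) x M` matrix of cell probabilities)
#'   and `pa` (vector of overall availability).
#' @export
removal_cells <- function(a, M) {
  if (any(!is.finite(a)) || any(a <= 0) || any(a >= 1))
    stop("per-minute availability a must lie strictly in (0, 1)")
  if (length(M) != 1L || M < 1) stop("M must be a single integer >= 1")
  M <- as.integer(M)
  pi_a <- outer(a, 0:(M - 1), function(av, m) av * (1 - av)^m)
  colnames(pi_a) <- paste0("min", seq_len(M))
  list(pi_a = pi_a, pa = 1 - (1 - a)^M)
}

#' Availability from ordinal date
#'
#' Places a logit-linear predictor with linear and quadratic ordinal-date
#' effects on the per-minute availability, then derives the removal cells:
#' `logit(a) = alpha + A1 * E + A2 * E^2`.
#'
#' @param alpha Logit-scale intercept.
#' @param A Length-2 vector of linear and quadratic ordinal-date
#'   coefficients.
#' @param E Standardized ordinal date (vectorized).
#' @param M Minutes per count.
#' @return List `a`, `pi_a`, `pa` as in [removal_cells].
#' @export
availability_from_date <- function(alpha, A, E, M) {
  stopifnot(length(A) == 2, all(is.finite(c(alpha, A))), all(is.finite(E)))
  eta <- alpha + A[1] * E + A[2] * E^2
  a <- stats::plogis(pmin(pmax(eta, -30), 30))
  a <- pmin(pmax(a, 1e-12), 1 - 1e-12)
  c(list(a = a), removal_cells(a, M))
}

#' Binned half-normal distance-detection cells
#'
#' Rectangular-rule approximation of the half-normal detection integral over
#' `B` equal-width distance bins on (0, maxd]: with bin width `delta` and
#' midpoints `r_b`, `pi_d_b = g(r_b) f(r_b) delta` where
#' `g(r) = exp(-r^2 / (2 sigma^2))` and `f(r) = 2 r / maxd^2` is the density
#' of radial distance under uniform spatial intensity. `pd = sum_b pi_d_b`.
#'
#' @param sigma Half-normal scale in meters (vectorized over surveys).
#' @param maxd Truncation distance in meters.
#' @param B Number of distance bins (default 10).
#' @return List with `pi_d` (`length(sigma) x B` matrix), `pd` (vector),
#'   `midpoints`, `delta`.
#' @export
distance_cells <- function(sigma, maxd, B = 10) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be > 0")
  if (!is.finite(maxd) || maxd <= 0) stop("maxd must be > 0")
  if (B < 1) stop("need at least one distance bin")
  delta <- maxd / B
  r_b <- (seq_len(B) - 0.5) * delta
  g <- exp(-outer(1 / (2 * sigma^2), r_b^2))
  f <- 2 * r_b / maxd^2
  pi_d <- sweep(g, 2L, f * delta, `*`)
  colnames(pi_d) <- paste0("bin", seq_len(B))
  list(pi_d = pi_d, pd = rowSums(pi_d), midpoints = r_b, delta = delta)
}

#' Half-normal scale from detection covariates
#'
#' `log(sigma) = tau . z` with `z` a design row holding an intercept, the
#' observer-experience flag and standardized mean minutes since sunrise.
#'
#' @param tau Coefficient vector.
#' @param z Design matrix (rows = surveys) or a single design row.
#' @return Vector of `sigma > 0` in meters.
#' @export
sigma_from_covariates <- function(tau, z) {
  z <- if (is.null(dim(z))) matrix(z, nrow = 1) else as.matrix(z)
  stopifnot(ncol(z) == length(tau), all(is.finite(tau)), all(is.finite(z)))
  exp(pmin(as.vector(z %*% tau), 30))
}

#' Truncate the furthest detections
#'
#' Discards the furthest `1 - q` fraction of detections (default the
#' furthest 10%) and returns the truncation distance, which also defines
#' the effective sampled area `pi * maxd^2` of a point count. The quantile
#' uses linear interpolation of order statistics (type 7), so with distances
#' 10, 20, ..., 100 and `q = 0.9` the truncation distance is 91 m.
#'
#' @param records Data frame of detections with a `distance_m` column.
#' @param q Retained quantile (default 0.90).
#' @return List `maxd` (meters) and `records` (retained rows).
#' @export
truncate_detections <- function(records, q = 0.90) {
  d <- records$distance_m
  d <- d[is.finite(d)]
  if (!length(d)) stop("no finite detection distances to truncate")
  maxd <- as.numeric(stats::quantile(d, q, type = 7))
  keep <- is.finite(records$distance_m) & records$distance_m <= maxd
  list(maxd = maxd, records = records[keep, , drop = FALSE])
}

#' Joint detection probability
#'
#' Product of availability and conditional detectability:
#' `pmarg = pa * pd`.
#'
#' @param pa,pd Probabilities in (0, 1] (vectorized).
#' @return `pa * pd`.
#' @export
pmarg <- function(pa, pd) {
  if (any(pa <= 0 | pa > 1) || any(pd <= 0 | pd > 1))
    stop("pa and pd must lie in (0, 1]")
  pa * pd
}

# Bin a continuous distance into 1..B equal bins on (0, maxd].
# Distance 0 lands in bin 1; distances > maxd must be truncated upstream.
distance_bin <- function(distance_m, maxd, B = 10) {
  if (any(distance_m > maxd)) stop("distance beyond maxd; truncate first")
  b <- pmax(1L, as.integer(ceiling(distance_m / (maxd / B))))
  if (any(b > B)) stop("internal: bin index out of range")
  b
}
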