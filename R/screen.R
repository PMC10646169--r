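#' Multi-scale pairwise correlation screen
#'
#' Screens covariate pairs for collinearity at three benchmark buffer
#' extents. A pair is flagged at a scale when the absolute Pearson
#' correlation across grid-years reaches the threshold there; a covariate is
#' proposed for removal when a pair containing it is flagged at two or more
#' of the three scales. Covariates stored at a single fixed radius
#' (elevation, ruggedness, drought index) contribute that value at every
#' scale.
#'
#' @param stack A [buffer_stack].
#' @param scales Benchmark radii in meters (default 200, 5000, 10000).
#' @param threshold Flagging threshold on |r| (default 0.6).
#' @return A `correlation_screen` list: `r` (covariate x covariate x scale
#'   correlation array), `pairs` (data frame of flagged pairs with the number
#'   of scales flagged), `drop` (covariates proposed for removal, the
#'   later-listed member of each offending pair), and `zero_variance`.
#' @export
correlation_screen <- function(stack, scales = c(200, 5000, 10000),
                               threshold = 0.6) {
  stopifnot(inherits(stack, "buffer_stack"))
  covs <- stack$covariates
  if (length(covs) < 2) stop("need at least two covariates to screen")
  nG <- length(stack$grid_ids); nY <- length(stack$years)

  # grid-year rows x covariates, one matrix per benchmark scale
  mats <- lapply(scales, function(s) {
    m <- matrix(NA_real_, nG * nY, length(covs), dimnames = list(NULL, covs))
    for (ci in seq_along(covs)) {
      vm <- matrix(stack$values[, , ci, ], nG * nY, length(stack$radii))
      m[, ci] <- if (length(stack$radii) == 1L) vm[, 1L]
                 else interp_radius_matrix(vm, stack$radii, s)
    }
    m
  })

  zv <- covs[vapply(covs, function(cv) {
    all(vapply(mats, function(m) stats::sd(m[, cv], na.rm = TRUE) == 0,
               TRUE))
  }, TRUE)]
  if (length(zv))
    warning("zero-variance covariate(s) excluded from screen: ",
            paste(zv, collapse = ", "))
  keep <- setdiff(covs, zv)

  rarr <- array(NA_real_, c(length(covs), length(covs), length(scales)),
                dimnames = list(covs, covs, paste0("s", scales)))
  for (si in seq_along(scales)) {
    cm <- suppressWarnings(
      stats::cor(mats[[si]][, keep, drop = FALSE],
                 use = "pairwise.complete.obs"))
    rarr[keep, keep, si] <- cm
  }

  flags <- abs(rarr) >= threshold
  pairs <- data.frame(cov1 = character(), cov2 = character(),
                      n_scales_flagged = integer())
  drop <- character()
  for (i in seq_along(covs)[-length(covs)]) {
    for (j in (i + 1):length(covs)) {
      nf <- sum(flags[i, j, ], na.rm = TRUE)
      if (nf > 0)
        pairs <- rbind(pairs, data.frame(
          cov1 = covs[i], cov2 = covs[j], n_scales_flagged = nf))
      if (nf >= 2) drop <- union(drop, covs[j])
    }
  }
  structure(list(r = rarr, pairs = pairs, drop = drop,
                 zero_variance = zv, scales = scales,
                 threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> |r| >= %.2f at scales {%s} m\n",
              x$threshold, paste(x$scales, collapse = ", ")))
  if (nrow(x$pairs)) print(x$pairs) else cat("  no pairs flagged\n")
  cat("  proposed drops:",
      if (length(x$drop)) paste(x$drop, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column `j`
#' of the design matrix on all other columns (with an intercept). The
#' conventional cutoff for this model family is 3.0.
#'
#' @param design Numeric matrix of standardized covariates (no intercept
#'   column).
#' @return Named numeric vector of VIFs; `Inf` for exactly collinear
#'   columns.
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  if (ncol(design) < 2) stop("need at least two columns for VIF")
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  out <- stats::setNames(numeric(ncol(design)), colnames(design))
  for (j in seq_len(ncol(design))) {
    y <- design[, j]
    X <- cbind(1, design[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) { out[j] <- NA_real_; next }
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}
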