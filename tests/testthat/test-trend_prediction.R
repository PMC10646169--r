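test_that("percent change identities", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(1.01)), 1)
  expect_equal(percent_change(-log(1.01)), 100 * (1 / 1.01 - 1))
})

test_that("classify_trend applies the 90% / 1% rule", {
  expect_equal(classify_trend(rep(0.05, 200))$label, "increasing")
  set.seed(30)
  near_zero <- sample(c(-0.001, 0.001), 500, replace = TRUE)
  cl <- classify_trend(near_zero)
  expect_equal(cl$label, "neither")
  expect_lt(cl$pr_increase + cl$pr_decrease, 0.01)
  expect_error(classify_trend(rep(0.1, 50)), "100")
})

test_that("classification is invariant to draw order and mild thinning", {
  set.seed(31)
  draws <- rnorm(2000, 0.02, 0.006)
  a <- classify_trend(draws)
  b <- classify_trend(sample(draws))
  expect_identical(a$label, b$label)
  expect_equal(a$pr_increase, b$pr_increase)
  thin <- classify_trend(draws[seq(1, 2000, by = 4)])
  expect_identical(thin$label, a$label)
  expect_lt(abs(thin$pr_increase - a$pr_increase), 0.05)
})

test_that("a trend can never be increasing and decreasing at once", {
  set.seed(32)
  for (m in c(-0.05, 0, 0.05)) {
    cl <- classify_trend(rnorm(500, m, 0.04))
    expect_lte(cl$pr_increase + cl$pr_decrease, 1)
    expect_false(cl$pr_increase >= 0.9 && cl$pr_decrease >= 0.9)
  }
})

test_that("summary-based rule handles percent and proportion inputs alike", {
  expect_equal(classify_trend_summary(c(0.1, -0.1, 0.1, 0),
                                      c(95, 95, 50, 99)),
               c("increasing", "decreasing", "neither", "neither"))
  expect_equal(classify_trend_summary(0.1, 0.95), "increasing")
  expect_equal(classify_trend_summary(0.1, 0.90), "increasing")  # boundary
})

test_that("density conversion follows the effective-area rule", {
  expect_equal(density_from_prediction(1, 125), 1 / (pi * 0.125^2))
  expect_equal(round(density_from_prediction(1, 125), 2), 20.37)
  # doubling r quarters density
  expect_equal(density_from_prediction(5, 250),
               density_from_prediction(5, 125) / 4)
  set.seed(33)
  N <- runif(10, 0, 50); r <- runif(10, 50, 400)
  expect_equal(density_from_prediction(N, r), N / (pi * (r / 1000)^2),
               tolerance = 1e-12)
  expect_error(density_from_prediction(1, 0), "positive")
})

test_that("scale posterior mode uses 100-m histogram bins", {
  draws <- c(rep(1490, 30), rep(1510, 40), rep(3000, 50), 8000)
  expect_equal(scale_posterior_mode(draws), 1500)
})

test_that("phase expectation follows the sign rules", {
  expect_equal(phase_expectation(sagebrush = 1, pinyon_juniper = -1),
               "sagebrush")
  expect_equal(phase_expectation(1, 1), "early-successional PJ (Phase I-II)")
  expect_equal(phase_expectation(-0.2, 0.5, 0.1),
               "late-successional PJ (Phase III)")
  expect_equal(phase_expectation(0.3, 0.5, -0.4),
               "early-successional PJ (Phase I-II)")
  expect_equal(phase_expectation(-1, -1), "none")
})

test_that("trend_table classifies each BCR of a fit", {
  fit <- tiny_fit()
  tt <- trend_table(fit, species = "SIMSP")
  expect_equal(nrow(tt), length(fit$dat$bcr_levels))
  expect_true(all(tt$label %in% c("increasing", "decreasing", "neither")))
  expect_true(all(tt$pr_increase >= 0 & tt$pr_increase <= 1))
})

test_that("density surface: constant covariates and psi = 1 give the closed form", {
  st <- tiny_study()
  dat <- tiny_model_data()
  fit <- tiny_fit()
  # constant rasters at the training mean (standardized value 0)
  geom <- st$rasters[[1]]
  covs <- c(dat$config$fixed_covariates, dat$config$scaled_covariates)
  const <- lapply(covs, function(cv) {
    v <- matrix(dat$stack$center[cv], 12, 12)
    covariate_raster(v, 1000, geom$xll, geom$yll, name = cv)
  })
  names(const) <- covs
  # neutralize zero inflation by overriding the spline draws
  fit2 <- fit
  bcols <- grep("^(a0|b\\[)", fit2$par_names)
  for (ch in seq_along(fit2$draws)) {
    fit2$draws[[ch]][, "a0"] <- 30       # psi ~ 1
    fit2$draws[[ch]][, grep("^b\\[", fit2$par_names)] <- 0
  }
  surf <- predict_density_map(fit2, const, year = 2008,
                              bcr = dat$bcr_levels[1],
                              qa_quantiles = c(0, 1))
  v <- surf$density$values
  inner <- v[!is.na(v)]
  expect_gt(length(inner), 0)
  expect_lt(diff(range(inner)), 1e-8)   # constant surface
  m <- posterior_matrix(fit2)
  lam <- exp(m[, paste0("beta0[", dat$bcr_levels[1], "]")])
  expect_equal(inner[1], density_from_prediction(median(lam), dat$maxd),
               tolerance = 1e-6)
})

test_that("QA mask flags covariates outside the training quantiles", {
  st <- tiny_study()
  dat <- tiny_model_data()
  fit <- tiny_fit()
  geom <- st$rasters[[1]]
  covs <- c(dat$config$fixed_covariates, dat$config$scaled_covariates)
  const <- lapply(covs, function(cv) {
    v <- matrix(dat$stack$center[cv], 10, 10)
    v[1, 1] <- dat$stack$center[cv] + 100 * dat$stack$scale[cv]  # far out
    covariate_raster(v, 1000, geom$xll, geom$yll, name = cv)
  })
  names(const) <- covs
  surf <- predict_density_map(fit, const, year = 2008,
                              bcr = dat$bcr_levels[1])
  expect_equal(surf$mask_qa$values[1, 1], 1)
  expect_true(is.na(surf$density$values[1, 1]))
  expect_error(predict_density_map(fit, const[-1], 2008,
                                   dat$bcr_levels[1]),
               "missing covariate raster")
})

test_that("density is monotone in a positive-coefficient covariate", {
  dat <- tiny_model_data()
  fit <- tiny_fit()
  st <- tiny_study()
  geom <- st$rasters[[1]]
  covs <- c(dat$config$fixed_covariates, dat$config$scaled_covariates)
  cv1 <- dat$config$scaled_covariates[1]
  # force a known positive coefficient for the probe covariate, and pin the
  # window radii well inside the toy raster so the gradient survives
  fit2 <- fit
  for (ch in seq_along(fit2$draws)) {
    fit2$draws[[ch]][, paste0("Gamma[", cv1, "]")] <- 0.8
    for (cv in dat$config$scaled_covariates)
      fit2$draws[[ch]][, paste0("scale[", cv, "]")] <- 1000
  }
  grad <- lapply(covs, function(cv) {
    v <- matrix(dat$stack$center[cv], 8, 8)
    if (cv == cv1)
      v <- v + matrix(rep(seq(-0.5, 0.5, length.out = 8) *
                            dat$stack$scale[cv], each = 8), 8, 8)
    covariate_raster(v, 1000, geom$xll, geom$yll, name = cv)
  })
  names(grad) <- covs
  fit2$draws <- lapply(fit2$draws, function(m) {
    m[, "a0"] <- 30
    m[, grep("^b\\[", colnames(m))] <- 0
    m
  })
  surf <- predict_density_map(fit2, grad, year = 2008,
                              bcr = dat$bcr_levels[1],
                              qa_quantiles = c(0, 1))
  rowvals <- surf$density$values[4, ]
  expect_true(all(diff(rowvals[!is.na(rowvals)]) > 0))
})

test_that("toy landscape pixels match a per-pixel brute-force posterior loop", {
  dat <- tiny_model_data()
  fit <- tiny_fit()
  st <- tiny_study()
  geom <- st$rasters[[1]]
  covs <- c(dat$config$fixed_covariates, dat$config$scaled_covariates)
  set.seed(34)
  rast <- lapply(covs, function(cv) {
    v <- matrix(dat$stack$center[cv] +
                  rnorm(25, 0, 0.2 * dat$stack$scale[cv]), 5, 5)
    covariate_raster(v, 1000, geom$xll, geom$yll, name = cv)
  })
  names(rast) <- covs
  surf <- predict_density_map(fit, rast, year = 2009,
                              bcr = dat$bcr_levels[2],
                              qa_quantiles = c(0, 1))
  m <- posterior_matrix(fit)
  modes <- surf$scale_modes
  # brute force one interior pixel
  px <- c(3, 3)
  cc <- songscape:::cell_centers(rast[[1]])
  vals <- vapply(covs, function(cv) {
    mw <- moving_window_mean(rast[[cv]], modes[cv])
    (mw$values[px[1], px[2]] - dat$stack$center[cv]) / dat$stack$scale[cv]
  }, 1)
  lam <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    eta <- m[i, paste0("beta0[", dat$bcr_levels[2], "]")] +
      m[i, paste0("mu[", dat$bcr_levels[2], "]")] * (2009 - 2008) +
      sum(m[i, paste0("beta[", colnames(dat$x), "]")] *
            vals[dat$config$fixed_covariates]) +
      sum(m[i, paste0("Gamma[", dat$config$scaled_covariates, "]")] *
            vals[dat$config$scaled_covariates])
    Zp <- tps_eval(dat$basis, cbind(cc$x[px[2]], cc$y[px[1]]))
    psi <- plogis(m[i, "a0"] +
                    sum(Zp * m[i, paste0("b[", seq_len(ncol(dat$basis$Z)),
                                         "]")]))
    lam[i] <- exp(eta) * psi
  }
  manual <- density_from_prediction(median(lam), dat$maxd)
  expect_equal(surf$density$values[px[1], px[2]], manual, tolerance = 1e-8)
})

test_that("density surface writes three ASCII bands that read back", {
  dat <- tiny_model_data()
  fit <- tiny_fit()
  st <- tiny_study()
  covs <- c(dat$config$fixed_covariates, dat$config$scaled_covariates)
  rast <- lapply(covs, function(cv)
    covariate_raster(matrix(dat$stack$center[cv], 6, 6), 1000,
                     0, 0, name = cv))
  names(rast) <- covs
  surf <- predict_density_map(fit, rast, 2008, dat$bcr_levels[1])
  pre <- file.path(withr::local_tempdir(), "surf")
  paths <- write_density_surface(surf, pre)
  expect_true(all(file.exists(paths)))
  back <- read_ascii_grid(paths[1])
  expect_equal(back$values, surf$density$values, tolerance = 1e-6)
})
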