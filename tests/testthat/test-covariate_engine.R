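test_that("buffer means of a constant field equal the constant at all radii", {
  r <- covariate_raster(matrix(7, 30, 30), 100, 0, 0, name = "const")
  cent <- data.frame(grid_id = "g1", easting = 1500, northing = 1500)
  out <- summarize_buffers(r, cent, radii = c(0, 100, 300, 700, 1000))
  expect_equal(unname(out[1, ]), rep(7, 5))
})

test_that("radius 0 returns the centroid's own cell value", {
  r <- checkerboard_raster()
  # centroid in cell (row from top = 14, col = 6): value (14+6) %% 2 = 0
  cent <- data.frame(grid_id = "g1", easting = 550, northing = 650)
  out <- summarize_buffers(r, cent, radii = 0)
  i <- 20 - ceiling(650 / 100) + 1  # row from top
  j <- ceiling(550 / 100)
  expect_identical(unname(out[1, 1]), r$values[i, j])
})

test_that("checkerboard buffer mean matches the exhaustive pixel-loop oracle", {
  r <- checkerboard_raster()
  cent <- data.frame(grid_id = "g1", easting = 1000, northing = 1000)
  for (rad in c(150, 300, 450, 800)) {
    got <- summarize_buffers(r, cent, radii = rad)[1, 1]
    expect_equal(unname(got), brute_buffer_mean(r, 1000, 1000, rad),
                 tolerance = 1e-12, label = paste("radius", rad))
  }
})

test_that("buffer means are invariant to joint translation", {
  set.seed(1)
  v <- matrix(rnorm(400), 20, 20)
  r1 <- covariate_raster(v, 100, 0, 0, name = "f")
  r2 <- covariate_raster(v, 100, 5000, -3000, name = "f")
  radii <- c(0, 200, 500)
  a <- summarize_buffers(r1, data.frame(grid_id = 1, easting = 900,
                                        northing = 1100), radii)
  b <- summarize_buffers(r2, data.frame(grid_id = 1, easting = 5900,
                                        northing = -1900), radii)
  expect_equal(a, b)
})

test_that("pixel sets nest monotonically in radius", {
  r <- checkerboard_raster()
  bi <- songscape:::buffer_index(r, data.frame(grid_id = 1, easting = 1000,
                                               northing = 1000),
                                 radii = seq(0, 900, by = 100))
  counts <- bi$per_grid[[1]]$k
  expect_true(all(diff(counts) >= 0))
})

test_that("centroid outside the raster errors naming the grid", {
  r <- checkerboard_raster()
  cent <- data.frame(grid_id = "far_away", easting = 99999, northing = 0)
  expect_error(summarize_buffers(r, cent, radii = c(0, 100)), "far_away")
})

test_that("all-nodata buffers are flagged as missing", {
  v <- matrix(NA_real_, 20, 20)
  v[1, 1] <- 5  # keep one finite value far away
  r <- covariate_raster(v, 100, 0, 0, name = "gappy", nodata = -9999)
  cent <- data.frame(grid_id = "g1", easting = 1500, northing = 500)
  expect_warning(out <- summarize_buffers(r, cent, radii = c(100, 300)),
                 "nodata")
  expect_true(all(is.na(out)))
})

test_that("interpolation at tabulated radii reproduces stored values exactly", {
  set.seed(2)
  radii <- seq(0, 1000, by = 100)
  vals <- array(rnorm(4 * 2 * 1 * 11), c(4, 2, 1, 11))
  stk <- stack_from_values(vals, radii, "cov", years = c(2019, 2020))
  for (s in c(0, 500, 1000))
    expect_identical(interpolate_at_scale(stk, "cov", "g2", 2020, s),
                     vals[2, 2, 1, which(radii == s)])
})

test_that("linear interpolation midpoint rule holds", {
  vals <- array(0, c(1, 1, 1, 3))
  vals[1, 1, 1, ] <- c(0, 2, 4)
  stk <- stack_from_values(vals, c(0, 100, 200), "cov")
  expect_equal(interpolate_at_scale(stk, "cov", "g1", 2020, 150), 3)
  expect_error(interpolate_at_scale(stk, "cov", "g1", 2020, 250), "outside")
})

test_that("interpolated value tracks a fresh brute-force buffer mean", {
  # smooth field: buffer means vary smoothly in radius, so a linear
  # interpolation between 100-m knots should sit within 2% of the direct
  # mean at an off-knot radius
  n <- 60
  v <- outer(seq_len(n), seq_len(n),
             function(i, j) 10 + 3 * sin(i / 9) + 2 * cos(j / 7))
  r <- covariate_raster(v, 100, 0, 0, name = "smooth")
  cent <- data.frame(grid_id = "g1", easting = 3000, northing = 3000)
  radii <- seq(0, 1500, by = 100)
  stk <- build_buffer_stack(list(r), cent, radii = radii, years = 2020)
  set.seed(3)
  for (s in runif(4, 200, 1400)) {
    direct <- brute_buffer_mean(r, 3000, 3000, s)
    interp <- interpolate_at_scale(stk, "smooth", "g1", 2020, s)
    expect_lt(abs(interp - direct) / abs(direct), 0.02)
  }
})

test_that("standardization round-trips to machine precision", {
  st <- tiny_study()
  back <- destandardize_stack(st$stack_std)
  expect_equal(back$values, st$stack$values, tolerance = 1e-12)
  # standardized values have mean ~0, sd ~1 per covariate
  for (ci in seq_along(st$stack_std$covariates)) {
    x <- st$stack_std$values[, , ci, ]
    expect_lt(abs(mean(x, na.rm = TRUE)), 1e-10)
    expect_equal(sd(x, na.rm = TRUE), 1, tolerance = 1e-10)
  }
})

test_that("stack CSV round-trips", {
  st <- tiny_study()
  p <- withr::local_tempfile(fileext = ".csv")
  write_stack_csv(st$stack, p)
  back <- read_stack_csv(p)
  expect_equal(back$values, st$stack$values, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a duplicated covariate is flagged at all scales and proposed for removal", {
  set.seed(4)
  radii <- seq(0, 10000, by = 100)
  ng <- 50
  base <- matrix(rnorm(ng * length(radii)), ng)
  vals <- array(NA_real_, c(ng, 1, 3, length(radii)))
  vals[, 1, 1, ] <- base
  vals[, 1, 2, ] <- base            # exact duplicate
  vals[, 1, 3, ] <- matrix(rnorm(ng * length(radii)), ng)
  stk <- stack_from_values(vals, radii, c("a", "a_copy", "c"))
  scr <- correlation_screen(stk)
  expect_true("a_copy" %in% scr$drop)
  row <- scr$pairs[scr$pairs$cov1 == "a" & scr$pairs$cov2 == "a_copy", ]
  expect_equal(row$n_scales_flagged, 3)
})

test_that("independent covariates are not flagged at n = 10,000", {
  set.seed(5)
  ng <- 10000
  radii <- c(200, 5000, 10000)
  vals <- array(rnorm(ng * 3 * 3), c(ng, 1, 3, 3))
  stk <- stack_from_values(vals, radii, c("a", "b", "c"))
  scr <- correlation_screen(stk)
  expect_equal(nrow(scr$pairs), 0)
  expect_length(scr$drop, 0)
})

test_that("a pair correlated at exactly one scale is retained", {
  set.seed(6)
  ng <- 400
  radii <- c(200, 5000, 10000)
  a <- array(rnorm(ng * 3), c(ng, 1, 1, 3))
  b <- a
  b[, 1, 1, 2:3] <- rnorm(ng * 2)       # decorrelate at 5000 and 10000 m
  vals <- array(NA_real_, c(ng, 1, 2, 3))
  vals[, 1, 1, ] <- a[, 1, 1, ]
  vals[, 1, 2, ] <- b[, 1, 1, ]
  stk <- stack_from_values(vals, radii, c("a", "b"))
  scr <- correlation_screen(stk)
  expect_equal(scr$pairs$n_scales_flagged, 1)
  expect_length(scr$drop, 0)
})

test_that("zero-variance covariates are excluded with a warning", {
  vals <- array(rnorm(20 * 2 * 3), c(20, 1, 2, 3))
  vals[, , 2, ] <- 1
  stk <- stack_from_values(vals, c(200, 5000, 10000), c("a", "flat"))
  expect_warning(scr <- correlation_screen(stk), "zero-variance")
  expect_equal(scr$zero_variance, "flat")
})

test_that("VIF: orthogonal columns give 1; correlated pair gives closed form", {
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(x)), c(1, 1))

  # correlation exactly 0.5 -> VIF = 1 / (1 - 0.25) = 4/3
  n <- 2000
  set.seed(7)
  z1 <- rnorm(n); z2 <- rnorm(n)
  a <- z1
  b <- 0.5 * z1 + sqrt(0.75) * z2
  a <- (a - mean(a)); b <- b - mean(b)
  # orthogonalize to exact sample correlation 0.5
  b <- 0.5 * a / sd(a) * sd(b) + sqrt(0.75) * resid(lm(b ~ a)) /
    sd(resid(lm(b ~ a))) * sd(b)
  r <- cor(a, b)
  expect_equal(unname(vif(cbind(a, b))), rep(1 / (1 - r^2), 2),
               tolerance = 1e-8)
})

test_that("VIF matches a brute-force regression oracle on a random matrix", {
  set.seed(8)
  X <- matrix(rnorm(200 * 5), 200, 5) %*%
    (diag(5) + 0.4 * matrix(1, 5, 5))
  got <- vif(X)
  for (j in 1:5) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(got[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("exact collinearity reports infinite VIF", {
  set.seed(9)
  a <- rnorm(50)
  expect_equal(unname(vif(cbind(a, 2 * a, rnorm(50)))[1]), Inf)
})
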