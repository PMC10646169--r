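test_that("R-hat: well-mixed chains near 1, separated chains far above 1.1", {
  set.seed(40)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(rhat(good) - 1), 0.01)
  bad <- good + rep(c(0, 10, 0, 10), each = 1000) * 1
  bad <- matrix(rnorm(4000), 1000, 4) +
    matrix(rep(c(0, 10, -10, 5), each = 1000), 1000, 4)
  expect_gt(rhat(bad), 3)
})

test_that("R-hat matches the textbook formula on a hand-sized instance", {
  x <- cbind(c(1, 2, 3, 4), c(2, 2, 4, 6))
  # split into 4 half-chains of length 2 and apply the formula by hand
  h <- cbind(c(1, 2), c(3, 4), c(2, 2), c(4, 6))
  mns <- colMeans(h); vars <- apply(h, 2, var)
  W <- mean(vars); B <- 2 * var(mns)
  manual <- sqrt(((2 - 1) / 2 * W + B / 2) / W)
  expect_equal(rhat(x), manual, tolerance = 1e-12)
  expect_error(rhat(matrix(1:10, 10, 1)), "2 chains")
})

test_that("zero-variance draws give a degenerate R-hat, not 1", {
  expect_warning(r <- rhat(matrix(5, 50, 3)), "degenerate")
  expect_true(is.na(r))
})

test_that("ESS is near the draw count for independent draws", {
  set.seed(41)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_gt(ess(x), 2500)
  expect_lt(ess(x), 6000)
})

test_that("same seed and config give bitwise-identical draws", {
  dat <- tiny_model_data()
  f1 <- run_mcmc(dat, iter = 40, warmup = 60, chains = 2, thin = 1,
                 seed = 123)
  f2 <- run_mcmc(dat, iter = 40, warmup = 60, chains = 2, thin = 1,
                 seed = 123)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_mcmc(dat, iter = 40, warmup = 60, chains = 2, thin = 1,
                 seed = 124)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("log-posterior is finite at retained draws", {
  fit <- tiny_fit()
  dat <- fit$dat
  for (i in c(1, 75, 150)) {
    par <- songscape:::par_from_draw(fit, 1, i)
    expect_true(is.finite(log_posterior(par, dat)))
  }
})

test_that("degenerate conjugate case matches the Gamma-Poisson closed form", {
  # psi = 1, sd.survey = 0, one BCR, no covariates, observation parameters
  # fixed at truth: the posterior of lambda = exp(beta0) under the ~flat
  # intercept prior is Gamma(sum d, sum effort * p)
  cfg <- sim_config(n_grids = 40, n_years = 2, n_bcrs = 1,
                    cell_size = 1000, radii = c(0, 500, 1000),
                    spline = FALSE, survey_effect = FALSE, seed = 60,
                    truth = list(beta0 = c("1" = -0.4), mu = c("1" = 0),
                                 A = c(0, 0), tau = c(log(65), 0, 0),
                                 beta = c(elevation = 0),
                                 Gamma = c(sagebrush = 0,
                                           pinyon_juniper = 0),
                                 sd_survey = 0))
  st <- simulate_study(cfg)
  mc <- model_config(trend = FALSE,
                     fixed = list(alpha = st$truth$alpha, A = st$truth$A,
                                  tau = st$truth$tau, psi = 1,
                                  sd_survey = 0))
  dat <- suppressMessages(
    prepare_model_data(st$surveys, st$detections, st$stack_std, mc))
  fit <- run_mcmc(dat, iter = 1000, warmup = 400, chains = 4, thin = 1,
                  seed = 61)
  lam_draws <- exp(posterior_matrix(fit)[, "beta0[1]"])

  av <- songscape:::avail_quantities(st$truth$alpha, st$truth$A, dat)
  de <- songscape:::detect_quantities(st$truth$tau, dat)
  p <- av$pa * de$pd
  shape <- sum(dat$d); rate <- sum(exp(dat$offset) * p)
  expect_equal(mean(lam_draws), shape / rate, tolerance = 0.02)
  expect_equal(sd(lam_draws), sqrt(shape) / rate, tolerance = 0.1)
})

test_that("marginalized and latent-N samplers agree on a small instance", {
  # configuration without scale selection, whose (scale, Gamma) posterior
  # is too diffuse at this size for a clean two-run comparison; the point
  # here is the equivalence of the N/Active marginalization
  st <- tiny_study()
  mc <- model_config(fixed_covariates = "elevation", spline = TRUE, K = 8,
                     survey_effect = TRUE, trend = TRUE)
  dat <- suppressMessages(
    prepare_model_data(st$surveys, st$detections, st$stack_std, mc))
  fm <- run_mcmc(dat, iter = 400, warmup = 500, chains = 2, thin = 1,
                 seed = 70, method = "marginal")
  fl <- run_mcmc(dat, iter = 400, warmup = 500, chains = 2, thin = 1,
                 seed = 170, method = "latent")
  pars <- c("alpha", "tau[1]", "beta0[1]", "beta[elevation]", "mu[1]")
  for (p in pars) {
    mm <- posterior_matrix(fm)[, p]; ml <- posterior_matrix(fl)[, p]
    tol <- 3 * sqrt(var(mm) / ess(sapply(fm$draws, function(x) x[, p])) +
                      var(ml) / ess(sapply(fl$draws, function(x) x[, p]))) +
      0.05 * max(sd(mm), sd(ml))
    expect_lt(abs(mean(mm) - mean(ml)), max(tol, 0.08), label = p)
  }
})

test_that("gross overprediction pushes the Bayesian p-value to an extreme", {
  st <- tiny_study()
  # all parameters held fixed, intercepts inflated ~10x over truth
  mc <- model_config(trend = FALSE,
                     fixed = list(alpha = st$truth$alpha, A = st$truth$A,
                                  tau = st$truth$tau, psi = 1,
                                  sd_survey = 0,
                                  beta0 = unname(st$truth$beta0) + log(10)))
  dat <- suppressMessages(
    prepare_model_data(st$surveys, st$detections, st$stack_std, mc))
  fit <- run_mcmc(dat, iter = 100, warmup = 50, chains = 2, thin = 1,
                  seed = 71)
  pv <- bayes_pvalue_chisq(fit, n_draws = 100)
  expect_lt(min(pv$p, 1 - pv$p), 0.01)
})

test_that("more data shrinks the posterior sd of regression coefficients", {
  small <- tiny_model_data()
  cfg2 <- sim_config(n_grids = 100, n_years = 3, n_bcrs = 2,
                     cell_size = 500, seed = 42)
  st2 <- simulate_study(cfg2)
  mc2 <- model_config_from_sim(st2, K = 8)
  big <- suppressMessages(
    prepare_model_data(st2$surveys, st2$detections, st2$stack_std, mc2))
  fs <- run_mcmc(small, iter = 250, warmup = 350, chains = 2, thin = 1,
                 seed = 80)
  fb <- run_mcmc(big, iter = 250, warmup = 350, chains = 2, thin = 1,
                 seed = 80)
  sd_s <- sd(posterior_matrix(fs)[, "beta[elevation]"])
  sd_b <- sd(posterior_matrix(fb)[, "beta[elevation]"])
  expect_lt(sd_b, sd_s)
})
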