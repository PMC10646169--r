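# songscape

Hierarchical Bayesian density-habitat models for songbird point-count
monitoring data.

## The problem

Large avian monitoring programs survey 1-km² grids of up to 16 point-count
stations each morning, recording for every detection its distance (by
rangefinder) and the minute of the count in which it was first heard. Two
observation filters separate what was counted from what was there: some
birds never sing during the count (*availability*), and available birds go
undetected more often the farther they are (*detectability*). `songscape`
fits the joint model that corrects for both while estimating
density-habitat relationships, regional population trends, and the spatial
scale at which each landscape covariate acts — and then turns posteriors
into the standard products: trend classifications and predicted density
maps with quality-assurance masks.

## The model

For grid *g* in year *t*:

```
d_gt  ~ Binomial(N_gt, pa_gt * pd_gt)            # detections
N_gt  ~ Poisson(lambda_gt * Active_g)            # zero-inflated abundance
Active_g ~ Bernoulli(psi_g),  logit(psi_g) = a0 + f(easting_g, northing_g)
log lambda_gt = beta0_r + beta.x_gt + Gamma.w_gt(s) + mu_r (t - 2008)
                + log(points_gt) + eps_gt,   eps_gt ~ N(0, sd.survey)
```

Availability uses the removal-model construction over minute intervals,
`pa = 1 - (1 - a)^M` with logit-linear seasonal effects on `a`;
detectability integrates a half-normal distance kernel over 10 equal bins
inside the 90%-quantile truncation distance, with `log(sigma)` linear in
observer experience and time since sunrise. Landscape covariates `w(s)`
are buffer means interpolated at a continuous scale-of-effect radius `s`
estimated per covariate (tabulated at 0-10,000 m in 100-m steps). BCR
(Bird Conservation Region) intercepts and trends are bivariate-normal
random effects with an inverse-Wishart covariance. Fitting is by an
adaptive Metropolis-within-Gibbs sampler on the marginalized likelihood
(no external MCMC engine required); see the methods vignette
(`vignettes/density-habitat-model.Rmd`) for the sampler and every numerical
convention.

## Worked example

```r
library(songscape)

# a complete synthetic study: rasters, surveys, detections, known truth
cfg   <- sim_config(n_grids = 150, n_years = 4, n_bcrs = 2, seed = 3)
study <- simulate_study(cfg)
study
#> <synthetic_study> 150 grids x 4 years, 2 BCR(s), 1213 detections

dat <- prepare_model_data(study$surveys, study$detections,
                          study$stack_std, model_config_from_sim(study, K = 15))
fit <- run_mcmc(dat, iter = 500, warmup = 1000, chains = 2, seed = 5)
subset(posterior_summary(fit),
       parameter %in% c("Gamma[sagebrush]", "scale[sagebrush]", "mu[1]"))
#>           parameter       mean        sd      q2.5        q50     q97.5
#>    Gamma[sagebrush]    0.49618   0.05322    0.4038    0.49062 5.922e-01
#>               mu[1]   -0.03257   0.03966   -0.1120   -0.03199 4.365e-02
#>    scale[sagebrush] 2969.14787 386.77630 2228.2691 2980.29521 3.702e+03
study$truth$Gamma["sagebrush"]; study$truth$scales["sagebrush"]
#> 0.5       # true effect per covariate sd
#> 3206.8    # true scale of effect, m

trend_table(fit, species = "SIMSP")
#>   species bcr     mean   q2.5  q97.5 pr_increase pr_decrease   label
#> 1   SIMSP   1 -0.03257 -0.112 0.0436       0.144       0.732 neither
#> 2   SIMSP   2 -0.00295 -0.088 0.0909       0.360       0.464 neither
```

A population is labelled "increasing" when at least 90% of posterior trend
draws correspond to a ≥ +1% annual change, "decreasing" when at least 90%
fall at or below −1%, and "neither" otherwise — here both simulated BCR
trends (truth −0.059 and −0.010 per year) are correctly indeterminate at
this sample size.

The same pipeline runs from the command line
(`inst/cli/songscape.R`): `simulate`, `summarize`, `fit`, `check`,
`classify-trends`, `predict`. `check` writes R-hat / effective-sample-size
/ Bayesian p-value JSON reports; `predict` writes a density surface in
birds/km² (`N / (pi * maxd²)`) plus disturbance and QA mask bands as
plain-text ASCII grids.

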