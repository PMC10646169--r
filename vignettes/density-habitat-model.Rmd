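---
title: "The songscape density-habitat model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The songscape density-habitat model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`songscape` fits a hierarchical Bayesian density-habitat model to avian
point-count data collected on 1-km^2 survey grids, each holding up to 16
stations counted in a single morning (a *survey* is one grid-year). The
model has three layers.

**Observation process.** The summed count of independent detections on a
survey is

$$d_{gt} \sim \mathrm{Binomial}(N_{gt},\, p^{marg}_{gt}), \qquad
  p^{marg}_{gt} = pa_{gt} \cdot pd_{gt},$$

where availability $pa$ comes from a removal model over 1-minute intervals
($\pi^a_m = a(1-a)^{m-1}$, $pa = 1-(1-a)^M$, with $M = 5$ minutes in the
first two program years and 6 afterwards) and detectability $pd$ from a
half-normal distance function evaluated by the midpoint rectangular rule on
10 equal distance bins inside the truncation distance `maxd` (the 90th
percentile of observed distances, linear-interpolation quantile). The
per-minute availability is logit-linear in standardized ordinal date and
its square; $\log \sigma$ is linear in observer experience and mean minutes
since sunrise. Each detection's minute interval and distance bin contribute
categorical (conditional cell) likelihood terms, which is what identifies
$a$ and $\sigma$ separately from abundance.

**State process.** True abundance is zero-inflated Poisson,
$N_{gt} \sim \mathrm{Poisson}(\lambda_{gt} \cdot \mathrm{Active}_g)$, with
a time-constant range indicator
$\mathrm{Active}_g \sim \mathrm{Bernoulli}(\psi_g)$ whose probability
varies spatially through a two-dimensional thin-plate spline in grid
centroid coordinates. The expected abundance follows a log-linear habitat
model

$$\log \mu^\lambda_{gt} = \beta_{0r} + \beta x_{gt} + \Gamma w_{gt}(s)
  + \mu_r (t - 2008) + \log(\text{points}_{gt}),$$

with BCR-level random intercepts and linear year trends drawn from a
bivariate normal whose covariance gets an inverse-Wishart prior
(scale `diag(500, 1)`, 3 df), and a lognormal survey-level random effect
(`sd.survey`) for overdispersion.

**Scale of effect.** Landscape covariates are summarized as buffer means at
101 radii (0-10,000 m in 100-m steps) around each grid centroid; a
continuous radius parameter per covariate selects the scale by
piecewise-linear interpolation between the tabulated radii, estimated
jointly with its coefficient.

# Parameters that matter

| parameter | meaning | default / prior |
|---|---|---|
| `a` | per-minute availability | logit-linear in date; coefficients N(0, 100^2) |
| `sigma` | half-normal detection scale (m) | log-linear; coefficients N(0, 100^2) |
| `maxd` | truncation distance (m) | 90% type-7 quantile of distances |
| `B` | distance bins | 10 |
| `beta`, `Gamma` | habitat coefficients (per sd of covariate) | N(0, 100^2) |
| `s_j` | scale of effect (m) | Uniform(0, 10,000) |
| `mu_r` | log-scale annual trend per BCR | bivariate normal with `beta0_r` |
| `sd.survey` | lognormal overdispersion sd | Uniform(0, 5) |
| `K` | spline basis dimension | 100 (desk-scale fits use 10-20) |
| `omega` | spline smoothing precision | log(omega) ~ Uniform(-12, 12) |

# Numerical and design choices

**Survey random effect on the log scale.** The source formulation places a
normal error on $\lambda$ itself, which admits negative Poisson means. We
implement it as a normal on $\log \lambda$ (lognormal overdispersion),
which is the standard device in this model family and keeps
$\lambda > 0$ always. `survey_effect()` documents the convention:
$E[\log \lambda] = \log \mu^\lambda$.

**Marginalized likelihood.** The default inference path sums the discrete
latent variables out of the likelihood: $N$ via the thinning identity
(Binomial thinning of a Poisson is Poisson), and `Active` per grid across
that grid's years (the indicator is time-constant, so the mixture is a
grid-level, not survey-level, object). A JAGS-style latent-variable Gibbs
path (`method = "latent"` in `run_mcmc()`) is retained and tested to agree
with the marginal path on posterior means.

**Sampler.** No MCMC engine ships in the runtime environment, so the
package implements an adaptive Metropolis-within-Gibbs sampler (adaptation
during warmup only): Haario-style joint blocks for availability, detection
and the abundance fixed effects plus per-coordinate refreshes; conjugate
Gibbs for the BCR covariance (normal-inverse-Wishart) and for the spline
smoothing precision (Gamma full conditional under the log-uniform prior);
and four non-obvious moves that the posterior geometry makes necessary:

* a *sign-aware rescaled jump* for each scale radius, proposing
  $(s, \Gamma) \to (s', \Gamma \cdot \mathrm{sgn}(\rho) \,
  \mathrm{sd}\,w(s) / \mathrm{sd}\,w(s'))$ with the matching Jacobian.
  Buffer means smooth out as the radius grows, so $\Gamma$ and $s$ ride a
  ridge a plain random walk cannot traverse; occasional global jumps in $s$
  let chains cross between distant radii;
* *interweaving sweeps* shifting a BCR's intercept (or trend slope) against
  the mean (or year-ramp) of its surveys' random effects — the likelihood
  is invariant, so these cost only prior evaluations and break the
  random-effect/intercept ridge;
* a *joint scaling move* on (`sd.survey`, all survey effects) whose prior
  ratio cancels against the Jacobian up to one factor, curing the funnel
  where near-zero effects pin the variance at zero (and the analogous move
  for (`omega`, spline coefficients));
* a *preconditioned Crank-Nicolson* refresh of the penalized spline block,
  whose acceptance depends on the likelihood alone.

Initialization uses dispersed random values inside the prior support but
centred on data-informed locations: pooled one-dimensional ML pilot
estimates of availability and the detection scale (the analog of
initializing a BUGS model from a glm fit), and a crude detection-corrected
rate for the intercepts. Literal draws from the sd-100 priors give
numerically non-finite posteriors, which the module's error contract
treats as a hard failure at initialization.

**Draw budget.** Defaults mirror the convention of reserving 500 samples
from each of four chains (2,000 total): `iter = 2000, thin = 4` after
`warmup = 2000`. The production analyses this package emulates ran
120,000-650,000 iterations; at the desk-scale defaults every structural
parameter (regression, observation, scale, variance and covariance terms)
reaches split-chain R-hat below ~1.03 on the bundled small synthetic
study. The spline coefficients do not: the log-uniform prior on `omega`
makes the implied marginal prior on the penalized coefficients
scale-invariant across twelve decades, and wherever `psi` saturates the
likelihood cannot pin their scale, so their chains wander a log-flat ridge
that no fixed desk-scale budget bounds — the same pathology that forced
the production analyses to raise `K`, drop scale parameters or remove
sparse regions to converge. See Limitations. Acceptance tests use
further-reduced budgets (2 chains, a few hundred retained draws) and say
so inline.

**Buffer semantics.** A cell belongs to a buffer when its center lies
within the radius; radius 0 returns the centroid's cell. Buffers narrower
than the cell spacing fall back to the centroid cell rather than being
flagged missing. Standardization of the covariate stack is per covariate,
jointly across grids, years and radii, so the radius profile keeps its
shape and interpolation across radii stays meaningful (the alternative,
per-radius standardization, would decouple the amplitude of a covariate
from its scale and change the meaning of $\Gamma$).

**Rectangular-rule accuracy.** The 10-bin midpoint rule reproduces the
half-normal cell integral to about one part in a thousand of probability
across $\sigma/\text{maxd} \in [0.1, 10]$, but its *relative* error at the
extreme $\sigma/\text{maxd} = 0.1$ (where $pd \approx 0.02$) is ~3.6% —
a property of the printed rule itself, not of this implementation. Tests
therefore hold the discretization to one percentage point of probability
everywhere and 1% relative error for $\sigma/\text{maxd} \ge 0.25$.

**Fixed-radius covariates** (elevation, ruggedness at 564 m; drought index
at the centroid) are stored as radius-degenerate stacks so one code path
serves all covariates; the collinearity screen takes their single value at
every benchmark scale.

# The synthetic-data generator

`sim_config()` / `simulate_study()` generate complete studies with the
structure the analysis assumes: 1-km lattice grid placement (non-overlapping
1-km^2 cells), spatially coherent BCR bands, 5-minute counts in the first
two program years, variable effort (a fraction of surveys complete fewer
than 16 points), observer-experience mixing, and detections produced by
simulating every individual explicitly through the removal and distance
process — so `d <= N` holds structurally, and minute/distance histograms
are testable against the cell probabilities.

True parameter values are drawn once per seed and recorded in the fixture
manifest (never hard-coded in tests). The drawn defaults describe a
moderately common songbird: per-minute availability ~0.35 peaked in
mid-season, sigma ~70 m, BCR intercepts around log-density -1 with trends
of a few percent per year, habitat effects of +-0.5 per covariate sd,
`sd.survey` = 0.25, and mean range-membership probability ~0.8.

**Covariate fields are Gaussian-smoothed white noise at mixed correlation
ranges (600 m, 2 km, 6 km) plus a white-noise floor**, not sums of cosine
surfaces. The disk mean of a periodic surface carries a Bessel-type factor
that flips sign with radius, so buffer means at distant radii become
strongly *anti*-correlated with the truth and the scale posterior develops
a mirror mode with opposite-sign $\Gamma$ — making the scale of effect
non-identifiable by construction. A positive-definite monotone covariance
keeps cross-radius correlations positive and smoothly decaying, which is
the property that makes the continuous scale parameter estimable at all.

What the generator does *not* emulate: real landcover autocorrelation
structure (RCMAP-like patchiness), spatially balanced GRTS sampling (grid
placement is uniform on a lattice), observer turnover within a season,
double-counting or misidentification, and year-varying covariate change
(fields are year-constant; year signal enters through the trend). A green
recovery test therefore establishes that the estimator works when its
assumptions hold — not that those assumptions hold in field data.

# Limitations

* The scale posterior can be diffuse when the covariate field is smooth
  relative to the candidate radii; the reported posterior-mode radius (100-m
  histogram bins) is then a summary of a wide distribution.
* With few BCRs the inverse-Wishart covariance is prior-dominated; its
  posterior should not be over-interpreted.
* The density conversion treats predicted individuals as per point-count
  effective area ($\pi \cdot \text{maxd}^2$); whether an additional
  division by the 16 points per grid is wanted depends on the intended
  map units, and the per-point convention is adopted here.
* Prediction surfaces exclude the survey-level random effect (median of a
  mean surface) and apply the zero-inflation probability at the pixel's
  location; pixels outside the training covariate range are masked rather
  than extrapolated.
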