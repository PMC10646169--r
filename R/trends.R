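#' Percent annual change from a log-scale trend
#'
#' A log-linear trend slope `mu` corresponds to a population multiplying by
#' `exp(mu)` each year, i.e. `100 * (exp(mu) - 1)` percent annual change.
#'
#' @param mu_r Trend draw(s) on the log scale.
#' @return Percent change per year.
#' @export
percent_change <- function(mu_r) 100 * expm1(mu_r)

#' Classify a population trend from posterior draws
#'
#' The decision rule: a population is *increasing* when at least
#' `prob` (90%) of posterior trend draws correspond to a >= +`threshold_pct`
#' (1%) annual change, *decreasing* when at least 90% correspond to a
#' <= -1% change, and *neither* otherwise. A population can never qualify
#' for both labels when `prob > 0.5`.
#'
#' @param draws Posterior draws of the log-scale trend `mu_r` (>= 100).
#' @param threshold_pct Percent-per-year threshold (default 1).
#' @param prob Required posterior probability (default 0.90).
#' @return Data frame with posterior mean, 2.5/97.5% quantiles,
#'   `pr_increase`, `pr_decrease` and `label`.
#' @export
classify_trend <- function(draws, threshold_pct = 1, prob = 0.90) {
  if (length(draws) < 100) stop("need at least 100 trend draws")
  pc <- percent_change(draws)
  pr_inc <- mean(pc >= threshold_pct)
  pr_dec <- mean(pc <= -threshold_pct)
  label <- if (pr_inc >= prob) "increasing"
           else if (pr_dec >= prob) "decreasing" else "neither"
  data.frame(mean = mean(draws),
             q2.5 = unname(stats::quantile(draws, 0.025)),
             q97.5 = unname(stats::quantile(draws, 0.975)),
             pr_increase = pr_inc, pr_decrease = pr_dec, label = label)
}

#' Apply the trend decision rule to published posterior summaries
#'
#' Reporting utility for trend tables that print, per species and region,
#' the posterior mean trend and the posterior probability of a >= 1% annual
#' change in the direction of the mean. A row qualifies as
#' increasing/decreasing when that probability reaches `prob` and the mean
#' is positive/negative.
#'
#' @param mean Posterior mean trend (log scale; only its sign is used).
#' @param pr_change Probability (0-100 or 0-1) of a >= 1% annual change in
#'   the direction of the mean.
#' @param prob Decision threshold (default 0.90).
#' @return Character vector of labels: "increasing", "decreasing",
#'   "neither".
#' @export
classify_trend_summary <- function(mean, pr_change, prob = 0.90) {
  pr <- ifelse(pr_change > 1, pr_change / 100, pr_change)
  ifelse(pr >= prob & mean > 0, "increasing",
         ifelse(pr >= prob & mean < 0, "decreasing", "neither"))
}

#' Published posterior trend summaries
#'
#' Posterior mean, 95% credible interval and probability of a >= 1% annual
#' change for the log-scale population trend of 11 sagebrush- and
#' pinyon-juniper-associated songbird species per Bird Conservation Region
#' (2008-2020), as printed in the monitoring program's published trend
#' table. Ships with the package as the worked-example input for the trend
#' decision rule.
#'
#' @return Data frame: `species`, `bcr`, `mean`, `lcri`, `ucri`,
#'   `pr_change_pct`.
#' @export
load_trend_summaries <- function() {
  path <- system.file("extdata", "trend_summaries.csv",
                      package = "songscape")
  if (path == "")  # during in-source development
    path <- file.path("inst", "extdata", "trend_summaries.csv")
  utils::read.csv(path, comment.char = "#", check.names = TRUE)
}

#' Per-BCR trend classification from a fit
#'
#' @param fit A `songscape_fit` with trend parameters.
#' @param species Optional species label carried into the output.
#' @return Data frame, one row per BCR, as in [classify_trend] plus
#'   `species`, `bcr` and `pct_per_year` (posterior-mean percent change).
#' @export
trend_table <- function(fit, species = NA_character_) {
  stopifnot(fit$dat$config$trend)
  m <- posterior_matrix(fit)
  rows <- lapply(fit$dat$bcr_levels, function(b) {
    dr <- m[, paste0("mu[", b, "]")]
    cbind(species = species, bcr = b, classify_trend(dr),
          pct_per_year = mean(percent_change(dr)))
  })
  do.call(rbind, rows)
}

#' Density from predicted individuals
#'
#' Converts predicted individuals per point count into birds per square
#' kilometer by dividing by the effective sampled area `pi * r^2`, `r` the
#' truncation distance.
#'
#' @param N_pred Predicted number of individuals (per point-count circle).
#' @param r Truncation distance in meters.
#' @return Density in birds per km^2.
#' @export
density_from_prediction <- function(N_pred, r) {
  if (any(r <= 0)) stop("truncation distance must be positive")
  N_pred / (pi * (r / 1000)^2)
}

#' Posterior mode of a scale-of-effect parameter
#'
#' Histogram mode with 100-m bins centered on the tabulated radii, the
#' point estimate used when building moving-window prediction rasters.
#'
#' @param draws Posterior draws of a scale radius (meters).
#' @param bin Bin width in meters (default 100, the knot spacing).
#' @return Mode radius in meters (a multiple of `bin`).
#' @export
scale_posterior_mode <- function(draws, bin = 100) {
  ctr <- round(draws / bin)
  as.numeric(names(which.max(table(ctr)))) * bin
}

#' Expected successional community from coefficient signs
#'
#' Woodland succession from sagebrush shrubland to mature pinyon-juniper
#' raises woodland cover while sagebrush and herbaceous cover decline, so
#' the signs of a species' sagebrush, pinyon-juniper and herbaceous
#' coefficients imply where along that gradient it should reach its highest
#' densities: positive sagebrush with negative pinyon-juniper points to
#' sagebrush ecosystems; positive on both to early-successional (Phase
#' I-II) woodland; positive pinyon-juniper with negative sagebrush or
#' herbaceous to late-successional (Phase III) woodland.
#'
#' @param sagebrush,pinyon_juniper,herbaceous Signed coefficient summaries
#'   (posterior means).
#' @return One of `"sagebrush"`, `"early-successional PJ (Phase I-II)"`,
#'   `"late-successional PJ (Phase III)"`, `"none"`.
#' @export
phase_expectation <- function(sagebrush, pinyon_juniper, herbaceous = 0) {
  if (pinyon_juniper > 0 && sagebrush > 0)
    "early-successional PJ (Phase I-II)"
  else if (pinyon_juniper > 0 && (sagebrush < 0 || herbaceous < 0))
    "late-successional PJ (Phase III)"
  else if (sagebrush > 0 && pinyon_juniper < 0)
    "sagebrush"
  else "none"
}
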