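# Likelihood machinery for the hierarchical density-habitat model.
#
# The sampler keeps a state list of cached quantities so each Metropolis
# block only recomputes what its parameters touch:
#   obs   : availability/detection cells, pa, pd, log pmarg, cell loglik
#   w     : scale-interpolated covariate matrix (linear + quadratic columns)
#   eta   : linear predictor of log mu.lambda (without the survey effect)
#   lp    : per-survey Poisson log-pmf of d at lambda * pmarg
#   gpois : per-grid sums of lp
#   mixll : per-grid count marginal with Active summed out

# per-grid sums over the contiguous grid blocks of the survey table
grid_sum <- function(x, dat) {
  cs <- cumsum(x)[dat$gends]
  cs - c(0, cs[-dat$nG])
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log(exp(a - m) + exp(b - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# availability half of the observation process (alpha, A)
avail_quantities <- function(alpha, A, dat) {
  eta_a <- clamp(alpha + A[1] * dat$E + A[2] * dat$E^2, -30, 30)
  a <- clamp(stats::plogis(eta_a), 1e-12, 1 - 1e-12)
  log_a <- log(a); log_1ma <- log1p(-a)
  pa <- 1 - exp(dat$M * log_1ma)      # survey's own count length
  pa <- clamp(pa, 1e-300, 1)
  log_pa <- log(pa)
  # minute cells (columns beyond a survey's M are never indexed by y_min)
  log_pi_a <- outer(log_1ma, 0:(dat$Mmax - 1)) + log_a
  cell_av <- sum(dat$y_min * log_pi_a[, seq_len(ncol(dat$y_min)),
                                      drop = FALSE]) -
    sum(dat$d * log_pa)
  list(a = a, pa = pa, log_pa = log_pa, log_pi_a = log_pi_a,
       cell_av = cell_av)
}

# distance half of the observation process (tau); log cells are formed
# analytically (hot path) but match distance_cells() exactly
detect_quantities <- function(tau, dat) {
  sigma <- exp(clamp(as.vector(dat$z %*% tau), -30, 30))
  B <- dat$config$B
  delta <- dat$maxd / B
  r_b <- (seq_len(B) - 0.5) * delta
  log_fd <- log(2 * r_b * delta / dat$maxd^2)
  log_pi_d <- outer(-1 / (2 * sigma^2), r_b^2)
  log_pi_d <- sweep(log_pi_d, 2L, log_fd, `+`)
  pd <- rowSums(exp(log_pi_d))
  pd[pd < 1e-300] <- 1e-300
  log_pd <- log(pd)
  cell_det <- sum(dat$y_bin * log_pi_d) - sum(dat$d * log_pd)
  list(sigma = sigma, pd = pd, log_pd = log_pd, log_pi_d = log_pi_d,
       cell_det = cell_det)
}

# combined observation-process quantities (alpha, A, tau)
obs_quantities <- function(alpha, A, tau, dat) {
  av <- avail_quantities(alpha, A, dat)
  de <- detect_quantities(tau, dat)
  c(av, de,
    list(log_pmarg = av$log_pa + de$log_pd,
         cellll = av$cell_av + de$cell_det))
}

# scale-interpolated covariate matrix: linear column per scaled covariate,
# then squared columns for those with quadratic terms
w_matrix <- function(scales, dat) {
  covs <- dat$config$scaled_covariates
  if (!length(covs)) return(matrix(0, dat$nS, 0))
  lin <- vapply(seq_along(covs), function(j)
    interp_radius_matrix(dat$W[[j]], dat$radii, scales[j]), numeric(dat$nS))
  lin <- matrix(lin, nrow = dat$nS)
  colnames(lin) <- covs
  if (length(dat$config$scaled_quad)) {
    q <- lin[, dat$config$scaled_quad, drop = FALSE]^2
    colnames(q) <- paste0(dat$config$scaled_quad, "_sq")
    lin <- cbind(lin, q)
  }
  lin
}

eta_linpred <- function(par, w, dat) {
  eta <- par$beta0[dat$bcr_idx] + dat$offset
  if (dat$config$trend)
    eta <- eta + par$mu[dat$bcr_idx] * (dat$year - dat$config$t0)
  if (length(par$beta)) eta <- eta + as.vector(dat$x %*% par$beta)
  if (length(par$Gamma)) eta <- eta + as.vector(w %*% par$Gamma)
  unname(eta)
}

# per-survey Poisson log-pmf of the thinned count; lgamma(d + 1) is
# precomputed in model data (hot path: called several times per iteration)
count_lp <- function(eta, eps, log_pmarg, dat) {
  llam <- eta + eps + log_pmarg
  lp <- dat$d * llam - exp(llam) - dat$lgamma_d1
  lp[llam > 30] <- -Inf  # overflow guard; counts never warrant exp(30)
  lp
}

# per-grid marginal over Active: grids with any detection are occupied with
# certainty; all-zero grids mix the structural zero with the Poisson zeros
mix_ll <- function(log_psi, log_1mpsi, gpois, anyd) {
  out <- log_psi + gpois
  z <- !anyd
  if (any(z))
    out[z] <- logaddexp(log_1mpsi[z], out[z])
  out
}

psi_from_spline <- function(a0, b, dat) {
  if (!dat$config$spline) {
    p <- dat$config$fixed$psi
    if (is.null(p)) p <- 1
    return(rep(clamp(p, 1e-12, 1), dat$nG))
  }
  clamp(stats::plogis(clamp(a0 + as.vector(dat$basis$Z %*% b), -30, 30)),
        1e-12, 1 - 1e-12)
}

# design columns of the abundance block in sampler order
# (beta0 indicators, x, w, per-BCR year ramps); the Gamma columns must be
# refreshed whenever a scale proposal is accepted
ab_design <- function(dat, w) {
  nB <- length(dat$bcr_levels)
  D <- matrix(0, dat$nS, 0)
  ind <- matrix(0, dat$nS, nB)
  ind[cbind(seq_len(dat$nS), dat$bcr_idx)] <- 1
  D <- cbind(ind, dat$x, w)
  if (dat$config$trend)
    D <- cbind(D, ind * (dat$year - dat$config$t0))
  D
}

# full cache rebuild; used at init and by tests as the reference path
build_state <- function(par, dat) {
  st <- list()
  st$obs <- obs_quantities(par$alpha, par$A, par$tau, dat)
  st$w <- w_matrix(par$scales, dat)
  st$eta <- eta_linpred(par, st$w, dat)
  st$lp <- count_lp(st$eta, par$eps, st$obs$log_pmarg, dat)
  st$gpois <- grid_sum(st$lp, dat)
  st$psi <- psi_from_spline(par$a0, par$b, dat)
  st$log_psi <- log(st$psi); st$log_1mpsi <- log1p(-st$psi)
  st$mixll <- mix_ll(st$log_psi, st$log_1mpsi, st$gpois, dat$anyd)
  st
}

lp_normal <- function(v, sd) sum(stats::dnorm(v, 0, sd, log = TRUE))

# priors that involve the sampled fixed-effect blocks
prior_ab <- function(par, dat) {
  cfg <- dat$config
  lp <- lp_normal(par$beta, cfg$prior_sd) + lp_normal(par$Gamma, cfg$prior_sd)
  if (hier_bcr(dat)) {
    lp <- lp + sum(dmvnorm2(cbind(par$beta0, par$mu), par$mu_wish,
                            par$Sigma_w))
  } else {
    lp <- lp + lp_normal(par$beta0, cfg$prior_sd)
    if (cfg$trend) lp <- lp + lp_normal(par$mu, cfg$prior_sd)
  }
  lp
}

prior_obs <- function(par, dat) {
  lp_normal(c(par$alpha, par$A, par$tau), dat$config$prior_sd)
}

prior_spline <- function(par, dat) {
  if (!dat$config$spline) return(0)
  pen <- dat$basis$penalized
  lp_normal(par$a0, dat$config$prior_sd) +
    lp_normal(par$b[!pen], dat$config$prior_sd) +
    lp_normal(par$b[pen], 1 / sqrt(exp(par$log_omega)))
}

hier_bcr <- function(dat) {
  dat$config$trend && length(dat$bcr_levels) >= 2
}

#' Joint log-posterior of the density-habitat model
#'
#' Evaluates the marginalized log-posterior (latent abundance and range
#' indicator summed out) at a parameter list. Reference implementation used
#' by the sampler at initialization and by the test suite's brute-force
#' cross-checks; the sampler itself updates cached pieces incrementally.
#'
#' @param par Parameter list (see [run_mcmc] for the layout).
#' @param dat A [prepare_model_data] object.
#' @return Scalar log-posterior (up to a constant).
#' @export
log_posterior <- function(par, dat) {
  st <- build_state(par, dat)
  lp <- st$obs$cellll + sum(st$mixll) + prior_obs(par, dat) +
    prior_ab(par, dat) + prior_spline(par, dat)
  if (dat$config$survey_effect)
    lp <- lp + lp_normal(par$eps, max(par$sd_survey, 1e-12))
  if (hier_bcr(dat))
    lp <- lp + lp_normal(par$mu_wish, dat$config$prior_sd) +
      dinvwishart(par$Sigma_w, dat$config$R_wish, dat$config$df_wish)
  lp
}
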