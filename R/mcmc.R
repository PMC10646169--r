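# Adaptive Metropolis-within-Gibbs sampler for the density-habitat model.
# Adaptation (Robbins-Monro step sizes, Haario covariance for the two joint
# blocks) runs during warmup only, so retained draws target the exact
# posterior.

reflect <- function(x, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

init_params <- function(dat, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- dat$config
  nB <- length(dat$bcr_levels)
  nF <- ncol(dat$x)
  nSc <- length(cfg$scaled_covariates)
  nGam <- nSc + length(cfg$scaled_quad)
  jit <- function(n, s) stats::rnorm(n, 0, s)

  # pooled 1-D ML pilot estimates for the observation process (constant a,
  # constant sigma), the analog of initializing from a glm fit; chains are
  # jittered around them
  a_hat <- 0.35
  ls_hat <- log(dat$maxd / 2)
  if (sum(dat$d) > 0) {
    a_hat <- stats::optimize(function(a)
      -avail_quantities(stats::qlogis(a), c(0, 0), dat)$cell_av,
      c(0.02, 0.98))$minimum
    ls_hat <- stats::optimize(function(ls)
      -detect_quantities(c(ls, 0, 0), dat)$cell_det,
      log(dat$maxd) + c(-3, 1))$minimum
  }
  p_guess <- 0.4
  rate0 <- max(mean(dat$d), 0.05) / (mean(exp(dat$offset)) * p_guess)
  par <- list(
    alpha = stats::qlogis(a_hat) + jit(1, 0.15),
    A = jit(2, 0.05),
    tau = c(ls_hat + jit(1, 0.1), jit(2, 0.05)),
    beta0 = stats::setNames(log(rate0) + jit(nB, 0.3), dat$bcr_levels),
    beta = stats::setNames(jit(nF, 0.1),
                           if (nF) colnames(dat$x) else character()),
    Gamma = stats::setNames(jit(nGam, 0.1),
                            c(cfg$scaled_covariates,
                              paste0(cfg$scaled_quad, "_sq",
                                     recycle0 = TRUE))),
    mu = stats::setNames(jit(nB, 0.02), dat$bcr_levels),
    scales = stats::setNames(
      stats::runif(nSc, cfg$scale_range[1] + 0.1 * diff(cfg$scale_range),
                   cfg$scale_range[2] - 0.1 * diff(cfg$scale_range)),
      cfg$scaled_covariates),
    sd_survey = stats::runif(1, 0.05, 0.4),
    eps = numeric(dat$nS),
    a0 = stats::qlogis(0.8) + jit(1, 0.3),
    b = if (cfg$spline) jit(ncol(dat$basis$Z), 0.05) else numeric(),
    log_omega = stats::runif(1, -1, 2),
    mu_wish = c(log(rate0), 0),
    Sigma_w = diag(c(1, 0.01)))
  if (dat$config$survey_effect)
    par$eps <- jit(dat$nS, 0.5 * par$sd_survey)

  fx <- cfg$fixed
  for (nm in intersect(names(fx), c("alpha", "A", "tau", "beta0", "beta",
                                    "Gamma", "mu", "scales", "sd_survey",
                                    "a0", "b", "log_omega"))) {
    v <- fx[[nm]]
    if (nm %in% c("beta0", "mu") && is.null(names(v)))
      v <- stats::setNames(rep_len(v, nB), dat$bcr_levels)
    par[[nm]] <- v
  }
  if (!cfg$survey_effect) { par$eps[] <- 0; par$sd_survey <- 0 }
  par
}

par_names <- function(par, dat) {
  cfg <- dat$config
  nm <- c("alpha", "A[1]", "A[2]", paste0("tau[", 1:3, "]"),
          paste0("beta0[", dat$bcr_levels, "]"))
  if (length(par$beta)) nm <- c(nm, paste0("beta[", names(par$beta), "]"))
  if (length(par$Gamma)) nm <- c(nm, paste0("Gamma[", names(par$Gamma), "]"))
  if (cfg$trend) nm <- c(nm, paste0("mu[", dat$bcr_levels, "]"))
  if (length(par$scales)) nm <- c(nm, paste0("scale[", names(par$scales), "]"))
  if (cfg$survey_effect) nm <- c(nm, "sd_survey")
  if (cfg$spline) nm <- c(nm, "a0", paste0("b[", seq_along(par$b), "]"),
                          "log_omega")
  if (hier_bcr(dat)) nm <- c(nm, "mu_wish[1]", "mu_wish[2]",
                             "Sigma_w[1,1]", "Sigma_w[1,2]", "Sigma_w[2,2]")
  nm
}

flatten_par <- function(par, dat) {
  cfg <- dat$config
  v <- c(par$alpha, par$A, par$tau, par$beta0)
  if (length(par$beta)) v <- c(v, par$beta)
  if (length(par$Gamma)) v <- c(v, par$Gamma)
  if (cfg$trend) v <- c(v, par$mu)
  if (length(par$scales)) v <- c(v, par$scales)
  if (cfg$survey_effect) v <- c(v, par$sd_survey)
  if (cfg$spline) v <- c(v, par$a0, par$b, par$log_omega)
  if (hier_bcr(dat)) v <- c(v, par$mu_wish, par$Sigma_w[1, 1],
                            par$Sigma_w[1, 2], par$Sigma_w[2, 2])
  unname(v)
}

#' Fit the density-habitat model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampler on the marginalized posterior
#' (latent abundance `N` and range indicator `Active` summed out), or the
#' JAGS-style latent-variable Gibbs path (`method = "latent"`) kept for
#' cross-validation of the marginalization. Four chains by default; draws
#' are reproducible given `seed` (chain `c` uses `seed + c - 1`).
#'
#' Defaults mirror the convention of reserving 500 retained samples from
#' each of four chains (2,000 total) for inference: 2,000 post-warmup
#' iterations per chain thinned by 4, after 2,000 adaptation iterations.
#'
#' @param dat A [prepare_model_data] object.
#' @param iter Post-warmup iterations per chain.
#' @param warmup Warmup (adaptation) iterations, discarded.
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param thin Thinning interval for retained draws.
#' @param seed Integer master seed.
#' @param method `"marginal"` (default) or `"latent"`.
#' @return A `songscape_fit`: `draws` (per-chain matrix of monitored
#'   parameters), `eps` (per-chain matrix of survey random effects, when in
#'   the model), `par_names`, timing and seed metadata.
#' @export
run_mcmc <- function(dat, iter = 2000, warmup = 2000, chains = 4, thin = 4,
                     seed = 1, method = c("marginal", "latent")) {
  method <- match.arg(method)
  stopifnot(inherits(dat, "model_data"), iter >= 1, warmup >= 0)
  t0 <- Sys.time()
  out <- vector("list", chains)
  eps_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    r <- run_chain(dat, iter, warmup, thin, seed + ch - 1L, method)
    out[[ch]] <- r$draws
    eps_out[[ch]] <- r$eps
  }
  nm <- colnames(out[[1]])
  structure(list(draws = out,
                 eps = if (dat$config$survey_effect) eps_out else NULL,
                 par_names = nm, dat = dat, method = method,
                 iter = iter, warmup = warmup, chains = chains,
                 thin = thin, seed = seed,
                 runtime_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
            class = "songscape_fit")
}

#' @export
print.songscape_fit <- function(x, ...) {
  cat(sprintf("<songscape_fit> %d chains x %d draws (%s path), %.1f s\n",
              x$chains, nrow(x$draws[[1]]), x$method, x$runtime_s))
  invisible(x)
}

run_chain <- function(dat, iter, warmup, thin, seed, method) {
  set.seed(seed)
  cfg <- dat$config
  par <- init_params(dat, seed)
  st <- build_state(par, dat)

  # error contract: a non-finite posterior at init names the offending term
  terms <- c(cells = st$obs$cellll, counts = sum(st$mixll),
             prior_obs = prior_obs(par, dat), prior_ab = prior_ab(par, dat),
             prior_spline = prior_spline(par, dat))
  if (any(!is.finite(terms)))
    stop("non-finite log-posterior at initialization in term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))

  latent <- method == "latent"
  if (latent) {
    lam_p <- exp(clamp(st$eta + par$eps + st$obs$log_pmarg, -700, 30))
    Active <- ifelse(dat$anyd, 1L,
                     stats::rbinom(dat$nG, 1L, st$psi))
    lam <- exp(clamp(st$eta + par$eps, -700, 30))
    N <- ifelse(Active[dat$gidx] == 1L,
                dat$d + stats::rpois(dat$nS, lam * (1 - exp(st$obs$log_pmarg))),
                0L)
    st <- latent_recache(st, par, N, Active, dat)
  }

  upd <- list(
    obs = !all(c("alpha", "A", "tau") %in% names(cfg$fixed)),
    ab = is.null(cfg$fixed$beta0),
    scales = length(par$scales) > 0 && is.null(cfg$fixed$scales),
    eps = cfg$survey_effect,
    spline = cfg$spline,
    wish = hier_bcr(dat))

  nab <- length(par$beta0) + length(par$beta) + length(par$Gamma) +
    if (cfg$trend) length(par$mu) else 0

  ad <- list(ls_av = log(0.1), ls_de = log(0.1), ls_ab = log(0.1),
             ls_abc = rep(log(0.1), nab),
             ls_scale = rep(log(300), length(par$scales)),
             ls_eps = log(0.5), ls_sd = log(0.2),
             ls_spline = rep(log(0.3), if (cfg$spline) length(par$b) + 1 else 0),
             ls_omega = log(0.8), ls_pcn = log(0.3),
             mean_ab = numeric(nab), cov_ab = diag(nab) * 0.01, n_ab = 0,
             mean_av = numeric(3), cov_av = diag(3) * 0.01, n_av = 0,
             mean_de = numeric(3), cov_de = diag(3) * 0.01, n_de = 0)

  n_save <- floor(iter / thin)
  nm <- par_names(par, dat)
  draws <- matrix(NA_real_, n_save, length(nm), dimnames = list(NULL, nm))
  eps_draws <- if (cfg$survey_effect)
    matrix(NA_real_, n_save, dat$nS) else NULL
  isave <- 0L
  total <- warmup + iter

  for (it in seq_len(total)) {
    adapt <- it <= warmup
    gam <- if (adapt) min(0.5, 5 / sqrt(it)) else 0

    ## -- observation process: availability (alpha, A) then detection (tau),
    ## each a small joint adaptive MH block
    if (upd$obs) {
      for (half in c("avail", "detect", "avail", "detect")) {
        if (half == "avail") {
          v0 <- c(par$alpha, par$A)
          step <- exp(ad$ls_av)
          L <- tryCatch(chol(ad$cov_av + diag(1e-8, 3)),
                        error = function(e) diag(0.05, 3))
          v1 <- v0 + step * as.vector(stats::rnorm(3) %*% L)
          q1 <- avail_quantities(v1[1], v1[2:3], dat)
          obs1 <- st$obs
          obs1[names(q1)] <- q1
          obs1$log_pmarg <- q1$log_pa + st$obs$log_pd
          obs1$cellll <- q1$cell_av + st$obs$cell_det
        } else {
          v0 <- par$tau
          step <- exp(ad$ls_de)
          L <- tryCatch(chol(ad$cov_de + diag(1e-8, 3)),
                        error = function(e) diag(0.05, 3))
          v1 <- v0 + step * as.vector(stats::rnorm(3) %*% L)
          q1 <- detect_quantities(v1, dat)
          obs1 <- st$obs
          obs1[names(q1)] <- q1
          obs1$log_pmarg <- st$obs$log_pa + q1$log_pd
          obs1$cellll <- st$obs$cell_av + q1$cell_det
        }
        if (latent) {
          lbin1 <- lbin_term(dat$d, st$N, obs1$log_pmarg, st$act_s)
          dl <- obs1$cellll + sum(lbin1) - st$obs$cellll - sum(st$lbin) +
            lp_normal(v1, cfg$prior_sd) - lp_normal(v0, cfg$prior_sd)
        } else {
          lp1 <- count_lp(st$eta, par$eps, obs1$log_pmarg, dat)
          gp1 <- grid_sum(lp1, dat)
          mx1 <- mix_ll(st$log_psi, st$log_1mpsi, gp1, dat$anyd)
          dl <- obs1$cellll + sum(mx1) - st$obs$cellll - sum(st$mixll) +
            lp_normal(v1, cfg$prior_sd) - lp_normal(v0, cfg$prior_sd)
        }
        acc <- is.finite(dl) && log(stats::runif(1)) < dl
        if (acc) {
          if (half == "avail") { par$alpha <- v1[1]; par$A <- v1[2:3] }
          else par$tau <- v1
          st$obs <- obs1
          if (latent) st$lbin <- lbin1
          else { st$lp <- lp1; st$gpois <- gp1; st$mixll <- mx1 }
        }
        if (adapt) {
          if (half == "avail") {
            ad$ls_av <- ad$ls_av + gam * ((if (acc) 1 else 0) - 0.3)
            ad$n_av <- ad$n_av + 1
            dlt <- v0 - ad$mean_av
            ad$mean_av <- ad$mean_av + dlt / ad$n_av
            ad$cov_av <- ad$cov_av + (tcrossprod(dlt, v0 - ad$mean_av) -
                                        ad$cov_av) / ad$n_av
            ad$cov_av <- (ad$cov_av + t(ad$cov_av)) / 2
          } else {
            ad$ls_de <- ad$ls_de + gam * ((if (acc) 1 else 0) - 0.3)
            ad$n_de <- ad$n_de + 1
            dlt <- v0 - ad$mean_de
            ad$mean_de <- ad$mean_de + dlt / ad$n_de
            ad$cov_de <- ad$cov_de + (tcrossprod(dlt, v0 - ad$mean_de) -
                                        ad$cov_de) / ad$n_de
            ad$cov_de <- (ad$cov_de + t(ad$cov_de)) / 2
          }
        }
      }
    }

    ## -- abundance fixed effects: joint adaptive MH -----------------------
    if (upd$ab) {
    v0 <- c(par$beta0, par$beta, par$Gamma, if (cfg$trend) par$mu)
    step <- exp(ad$ls_ab)
    L <- tryCatch(chol(ad$cov_ab + diag(1e-8, nab)),
                  error = function(e) diag(0.05, nab))
    v1 <- v0 + step * as.vector(stats::rnorm(nab) %*% L)
    cand <- unflatten_ab(par, v1, dat)
    eta1 <- eta_linpred(cand, st$w, dat)
    if (latent) {
      lpd1 <- lpd_term(st$N, eta1, par$eps, st$act_s)
      dl <- sum(lpd1) - sum(st$lpd) + prior_ab(cand, dat) - prior_ab(par, dat)
    } else {
      lp1 <- count_lp(eta1, par$eps, st$obs$log_pmarg, dat)
      gp1 <- grid_sum(lp1, dat)
      mx1 <- mix_ll(st$log_psi, st$log_1mpsi, gp1, dat$anyd)
      dl <- sum(mx1) - sum(st$mixll) + prior_ab(cand, dat) -
        prior_ab(par, dat)
    }
    acc <- is.finite(dl) && log(stats::runif(1)) < dl
    if (acc) {
      par <- cand; st$eta <- eta1
      if (latent) st$lpd <- lpd1
      else { st$lp <- lp1; st$gpois <- gp1; st$mixll <- mx1 }
    }
    if (adapt) {
      ad$ls_ab <- ad$ls_ab + gam * ((if (acc) 1 else 0) - 0.25)
      ad$n_ab <- ad$n_ab + 1
      dlt <- v0 - ad$mean_ab
      ad$mean_ab <- ad$mean_ab + dlt / ad$n_ab
      ad$cov_ab <- ad$cov_ab + (tcrossprod(dlt, v0 - ad$mean_ab) -
                                  ad$cov_ab) / ad$n_ab
      ad$cov_ab <- (ad$cov_ab + t(ad$cov_ab)) / 2
    }

    # per-coordinate refresh of the same block (individual step sizes);
    # escapes directions the joint covariance has not learned yet
    if (is.null(st$D)) st$D <- ab_design(dat, st$w)
    for (q in seq_len(nab)) {
      v0 <- c(par$beta0, par$beta, par$Gamma, if (cfg$trend) par$mu)
      v1 <- v0
      dlt_q <- exp(ad$ls_abc[q]) * stats::rnorm(1)
      v1[q] <- v1[q] + dlt_q
      cand <- unflatten_ab(par, v1, dat)
      eta1 <- st$eta + dlt_q * st$D[, q]
      if (latent) {
        lpd1 <- lpd_term(st$N, eta1, par$eps, st$act_s)
        dl <- sum(lpd1) - sum(st$lpd) + prior_ab(cand, dat) -
          prior_ab(par, dat)
      } else {
        lp1 <- count_lp(eta1, par$eps, st$obs$log_pmarg, dat)
        gp1 <- grid_sum(lp1, dat)
        mx1 <- mix_ll(st$log_psi, st$log_1mpsi, gp1, dat$anyd)
        dl <- sum(mx1) - sum(st$mixll) + prior_ab(cand, dat) -
          prior_ab(par, dat)
      }
      acc <- is.finite(dl) && log(stats::runif(1)) < dl
      if (acc) {
        par <- cand; st$eta <- eta1
        if (latent) st$lpd <- lpd1
        else { st$lp <- lp1; st$gpois <- gp1; st$mixll <- mx1 }
      }
      if (adapt)
        ad$ls_abc[q] <- ad$ls_abc[q] + gam * ((if (acc) 1 else 0) - 0.44)
    }
    }

    ## -- scale-of-effect radii --------------------------------------------
    # Two alternating moves per radius: a plain reflected random walk in s,
    # and a variance-rescaled jump that moves (s, Gamma) together, scaling
    # Gamma by the ratio of covariate dispersions at the two radii (with
    # the matching Jacobian). Buffer means smooth out as s grows, so s and
    # Gamma ride a ridge the plain walk cannot traverse.
    if (upd$scales) {
      for (rep_sc in 1:2) for (j in seq_along(par$scales)) {
        s0 <- par$scales[j]
        u <- stats::runif(1)
        move <- if (u < 0.4) "rw" else if (u < 0.8) "rescale" else "global"
        s1 <- switch(move,
          rw = reflect(s0 + exp(ad$ls_scale[j]) * stats::rnorm(1),
                       cfg$scale_range[1], cfg$scale_range[2]),
          rescale = reflect(s0 + 3 * exp(ad$ls_scale[j]) * stats::rnorm(1),
                            cfg$scale_range[1], cfg$scale_range[2]),
          global = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]))
        cv <- cfg$scaled_covariates[j]
        cand <- par
        cand$scales[j] <- s1
        w1 <- st$w
        w1[, cv] <- interp_radius_matrix(dat$W[[j]], dat$radii, s1)
        has_quad <- cv %in% cfg$scaled_quad
        if (has_quad) w1[, paste0(cv, "_sq")] <- w1[, cv]^2
        logJ <- 0
        if (move != "rw") {
          # self-inverse sign-aware rescaling: Gamma' = Gamma * sgn * sd0/sd1
          w0c <- st$w[, cv]
          sgn <- if (stats::cor(w0c, w1[, cv]) >= 0) 1 else -1
          fac <- sgn * stats::sd(w0c) / stats::sd(w1[, cv])
          cand$Gamma[cv] <- par$Gamma[cv] * fac
          logJ <- log(abs(fac))
          if (has_quad) {
            q0 <- st$w[, paste0(cv, "_sq")]; q1 <- w1[, paste0(cv, "_sq")]
            sgq <- if (stats::cor(q0, q1) >= 0) 1 else -1
            facq <- sgq * stats::sd(q0) / stats::sd(q1)
            cand$Gamma[paste0(cv, "_sq")] <-
              par$Gamma[paste0(cv, "_sq")] * facq
            logJ <- logJ + log(abs(facq))
          }
        }
        eta1 <- st$eta + (w1[, cv] * cand$Gamma[cv] -
                            st$w[, cv] * par$Gamma[cv])
        if (has_quad) {
          qn <- paste0(cv, "_sq")
          eta1 <- eta1 + (w1[, qn] * cand$Gamma[qn] -
                            st$w[, qn] * par$Gamma[qn])
        }
        if (latent) {
          lpd1 <- lpd_term(st$N, eta1, par$eps, st$act_s)
          dl <- sum(lpd1) - sum(st$lpd)
        } else {
          lp1 <- count_lp(eta1, par$eps, st$obs$log_pmarg, dat)
          gp1 <- grid_sum(lp1, dat)
          mx1 <- mix_ll(st$log_psi, st$log_1mpsi, gp1, dat$anyd)
          dl <- sum(mx1) - sum(st$mixll)
        }
        dl <- dl + logJ +
          lp_normal(cand$Gamma, cfg$prior_sd) -
          lp_normal(par$Gamma, cfg$prior_sd)
        acc <- is.finite(dl) && log(stats::runif(1)) < dl
        if (acc) {
          par <- cand; st$w <- w1; st$eta <- eta1; st$D <- NULL
          if (latent) st$lpd <- lpd1
          else { st$lp <- lp1; st$gpois <- gp1; st$mixll <- mx1 }
        }
        if (adapt && move == "rw")
          ad$ls_scale[j] <- ad$ls_scale[j] +
            gam * ((if (acc) 1 else 0) - 0.44)
      }
    }

    ## -- survey random effects: per-grid vectorized MH --------------------
    if (upd$eps) {
      prop <- par$eps + exp(ad$ls_eps) * stats::rnorm(dat$nS)
      sdv <- max(par$sd_survey, 1e-6)
      if (latent) {
        lpd1 <- lpd_term(st$N, st$eta, prop, st$act_s)
        dsum <- grid_sum(lpd1 - st$lpd, dat)
      } else {
        lp1 <- count_lp(st$eta, prop, st$obs$log_pmarg, dat)
        gp1 <- grid_sum(lp1, dat)
        mx1 <- mix_ll(st$log_psi, st$log_1mpsi, gp1, dat$anyd)
        dsum <- mx1 - st$mixll
      }
      dprior <- grid_sum(
        stats::dnorm(prop, 0, sdv, log = TRUE) -
          stats::dnorm(par$eps, 0, sdv, log = TRUE), dat)
      accg <- log(stats::runif(dat$nG)) < dsum + dprior
      accg[!is.finite(dsum + dprior)] <- FALSE
      keep_s <- accg[dat$gidx]
      if (any(accg)) {
        par$eps[keep_s] <- prop[keep_s]
        if (latent) {
          st$lpd[keep_s] <- lpd1[keep_s]
        } else {
          st$lp[keep_s] <- lp1[keep_s]
          st$gpois[accg] <- gp1[accg]
          st$mixll[accg] <- mx1[accg]
        }
      }
      if (adapt)
        ad$ls_eps <- ad$ls_eps + gam * (mean(accg) - 0.35)

      # interweaving sweeps: shift a BCR's intercept (or trend) against its
      # surveys' random effects. The likelihood is invariant (eta + eps is
      # unchanged), so acceptance depends on the priors alone; this breaks
      # the ridge between beta0/mu and the mean (or year-slope) of eps.
      sdv <- max(par$sd_survey, 1e-6)
      if (upd$ab) for (r in seq_along(dat$bcr_levels)) {
        in_r <- dat$bcr_idx == r
        n_r <- sum(in_r)
        cshift <- stats::rnorm(1, 0, 2 * sdv / sqrt(n_r))
        cand0 <- par$beta0; cand0[r] <- cand0[r] + cshift
        dl <- sum(stats::dnorm(par$eps[in_r] - cshift, 0, sdv, log = TRUE)) -
          sum(stats::dnorm(par$eps[in_r], 0, sdv, log = TRUE))
        if (hier_bcr(dat))
          dl <- dl + sum(dmvnorm2(cbind(cand0, par$mu), par$mu_wish,
                                  par$Sigma_w)) -
            sum(dmvnorm2(cbind(par$beta0, par$mu), par$mu_wish,
                         par$Sigma_w))
        else dl <- dl + stats::dnorm(cand0[r], 0, cfg$prior_sd, log = TRUE) -
          stats::dnorm(par$beta0[r], 0, cfg$prior_sd, log = TRUE)
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          par$beta0 <- cand0
          par$eps[in_r] <- par$eps[in_r] - cshift
          st$eta[in_r] <- st$eta[in_r] + cshift
        }
        if (cfg$trend) {
          tt <- dat$year[in_r] - cfg$t0
          sdt <- max(stats::sd(tt), 0.5)
          dshift <- stats::rnorm(1, 0, 2 * sdv / (sdt * sqrt(n_r)))
          candm <- par$mu; candm[r] <- candm[r] + dshift
          dl <- sum(stats::dnorm(par$eps[in_r] - dshift * tt, 0, sdv,
                                 log = TRUE)) -
            sum(stats::dnorm(par$eps[in_r], 0, sdv, log = TRUE))
          if (hier_bcr(dat))
            dl <- dl + sum(dmvnorm2(cbind(par$beta0, candm), par$mu_wish,
                                    par$Sigma_w)) -
              sum(dmvnorm2(cbind(par$beta0, par$mu), par$mu_wish,
                           par$Sigma_w))
          else dl <- dl + stats::dnorm(candm[r], 0, cfg$prior_sd,
                                       log = TRUE) -
            stats::dnorm(par$mu[r], 0, cfg$prior_sd, log = TRUE)
          if (is.finite(dl) && log(stats::runif(1)) < dl) {
            par$mu <- candm
            par$eps[in_r] <- par$eps[in_r] - dshift * tt
            st$eta[in_r] <- st$eta[in_r] + dshift * tt
          }
        }
      }

      # sd.survey: reflected RW on (0, max], uniform prior
      if (is.null(cfg$fixed$sd_survey)) {
        sd1 <- reflect(par$sd_survey + exp(ad$ls_sd) * stats::rnorm(1),
                       1e-4, cfg$sd_survey_max)
        dl <- sum(stats::dnorm(par$eps, 0, sd1, log = TRUE)) -
          sum(stats::dnorm(par$eps, 0, sdv, log = TRUE))
        acc <- is.finite(dl) && log(stats::runif(1)) < dl
        if (acc) par$sd_survey <- sd1
        if (adapt) ad$ls_sd <- ad$ls_sd + gam * ((if (acc) 1 else 0) - 0.44)

        # joint scaling of (sd.survey, eps): multiplies both by c. The eps
        # prior ratio cancels against the Jacobian up to one factor of c,
        # so acceptance is the count-likelihood change plus log(c). Escapes
        # the funnel where eps ~ 0 pins sd.survey ~ 0.
        lc <- stats::rnorm(1, 0, 0.3)
        csc <- exp(lc)
        sd1 <- par$sd_survey * csc
        if (sd1 > 1e-4 && sd1 < cfg$sd_survey_max) {
          eps1 <- par$eps * csc
          if (latent) {
            lpd1 <- lpd_term(st$N, st$eta, eps1, st$act_s)
            dl <- sum(lpd1) - sum(st$lpd) + lc
          } else {
            lp1 <- count_lp(st$eta, eps1, st$obs$log_pmarg, dat)
            gp1 <- grid_sum(lp1, dat)
            mx1 <- mix_ll(st$log_psi, st$log_1mpsi, gp1, dat$anyd)
            dl <- sum(mx1) - sum(st$mixll) + lc
          }
          if (is.finite(dl) && log(stats::runif(1)) < dl) {
            par$eps <- eps1; par$sd_survey <- sd1
            if (latent) st$lpd <- lpd1
            else { st$lp <- lp1; st$gpois <- gp1; st$mixll <- mx1 }
          }
        }
      }
    }

    ## -- spatial spline on psi (coordinate-wise MH) -----------------------
    if (upd$spline) {
      coefs <- c(par$a0, par$b)
      Zfull <- cbind(1, dat$basis$Z)
      pen <- c(FALSE, dat$basis$penalized)
      psd <- ifelse(pen, 1 / sqrt(exp(par$log_omega)), cfg$prior_sd)
      psi_eta <- stats::qlogis(st$psi)
      for (k in seq_along(coefs)) {
        dck <- exp(ad$ls_spline[k]) * stats::rnorm(1)
        eta1 <- psi_eta + Zfull[, k] * dck
        psi1 <- clamp(stats::plogis(clamp(eta1, -30, 30)), 1e-12, 1 - 1e-12)
        if (latent) {
          dl <- sum(st$Active * (log(psi1) - log(st$psi)) +
                      (1 - st$Active) * (log1p(-psi1) - log1p(-st$psi)))
        } else {
          mx1 <- mix_ll(log(psi1), log1p(-psi1), st$gpois, dat$anyd)
          dl <- sum(mx1) - sum(st$mixll)
        }
        dl <- dl + stats::dnorm(coefs[k] + dck, 0, psd[k], log = TRUE) -
          stats::dnorm(coefs[k], 0, psd[k], log = TRUE)
        acc <- is.finite(dl) && log(stats::runif(1)) < dl
        if (acc) {
          coefs[k] <- coefs[k] + dck
          psi_eta <- eta1; st$psi <- psi1
          st$log_psi <- log(psi1); st$log_1mpsi <- log1p(-psi1)
          if (!latent) st$mixll <- mx1
        }
        if (adapt)
          ad$ls_spline[k] <- ad$ls_spline[k] +
            gam * ((if (acc) 1 else 0) - 0.44)
      }
      par$a0 <- coefs[1]; par$b <- coefs[-1]

      # preconditioned Crank-Nicolson refresh of the penalized block:
      # b' = sqrt(1 - beta^2) b + beta * prior draws. Prior-invariant, so
      # acceptance is the likelihood (psi) change only; mixes the whole
      # field even where single coordinates are weakly identified.
      pen_ix <- which(dat$basis$penalized)
      if (length(pen_ix)) {
        bpcn <- min(exp(ad$ls_pcn), 1)
        sdb <- 1 / sqrt(exp(par$log_omega))
        b1 <- par$b
        b1[pen_ix] <- sqrt(1 - bpcn^2) * b1[pen_ix] +
          bpcn * stats::rnorm(length(pen_ix), 0, sdb)
        psi1 <- psi_from_spline(par$a0, b1, dat)
        if (latent) {
          dl <- sum(st$Active * (log(psi1) - log(st$psi)) +
                      (1 - st$Active) * (log1p(-psi1) - log1p(-st$psi)))
        } else {
          mx1 <- mix_ll(log(psi1), log1p(-psi1), st$gpois, dat$anyd)
          dl <- sum(mx1) - sum(st$mixll)
        }
        acc <- is.finite(dl) && log(stats::runif(1)) < dl
        if (acc) {
          par$b <- b1
          st$psi <- psi1
          st$log_psi <- log(psi1); st$log_1mpsi <- log1p(-psi1)
          if (!latent) st$mixll <- mx1
        }
        if (adapt)
          ad$ls_pcn <- ad$ls_pcn + gam * ((if (acc) 1 else 0) - 0.25)
      }

      # smoothing precision omega: exact Gibbs from its Gamma full
      # conditional (log-uniform prior), truncated to the prior range
      br <- par$b[dat$basis$penalized]
      if (length(br)) {
        for (try_i in 1:20) {
          om <- stats::rgamma(1, shape = length(br) / 2,
                              rate = sum(br^2) / 2 + 1e-12)
          lo1 <- log(om)
          if (lo1 > cfg$log_omega_range[1] &&
              lo1 < cfg$log_omega_range[2]) {
            par$log_omega <- lo1
            break
          }
        }
      }

      # joint scaling of (omega, penalized b): b' = c b, omega' = omega/c^2.
      # Prior ratio and Jacobian cancel exactly; acceptance is the change
      # in the count marginal through psi (plus the omega range check).
      # Occasional large jumps traverse the near-flat scale ridge the
      # log-uniform omega prior creates when psi saturates.
      lc <- stats::rnorm(1, 0, if (stats::runif(1) < 0.5) 0.3 else 2)
      csc <- exp(lc)
      lo1 <- par$log_omega - 2 * lc
      if (lo1 > cfg$log_omega_range[1] && lo1 < cfg$log_omega_range[2]) {
        b1 <- par$b
        b1[dat$basis$penalized] <- b1[dat$basis$penalized] * csc
        psi1 <- psi_from_spline(par$a0, b1, dat)
        if (latent) {
          dl <- sum(st$Active * (log(psi1) - log(st$psi)) +
                      (1 - st$Active) * (log1p(-psi1) - log1p(-st$psi)))
        } else {
          mx1 <- mix_ll(log(psi1), log1p(-psi1), st$gpois, dat$anyd)
          dl <- sum(mx1) - sum(st$mixll)
        }
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          par$b <- b1; par$log_omega <- lo1
          st$psi <- psi1
          st$log_psi <- log(psi1); st$log_1mpsi <- log1p(-psi1)
          if (!latent) st$mixll <- mx1
        }
      }
    }

    ## -- latent N and Active Gibbs ----------------------------------------
    if (latent) {
      lam <- exp(clamp(st$eta + par$eps, -700, 30))
      pm <- exp(st$obs$log_pmarg)
      zg <- which(!dat$anyd)
      if (length(zg)) {
        lam_p_g <- grid_sum(lam * pm, dat)
        lp1g <- st$log_psi[zg] - lam_p_g[zg]
        lp0g <- st$log_1mpsi[zg]
        p1 <- 1 / (1 + exp(lp0g - lp1g))
        st$Active[zg] <- stats::rbinom(length(zg), 1L, p1)
      }
      st$act_s <- st$Active[dat$gidx] == 1L
      st$N <- ifelse(st$act_s,
                     dat$d + stats::rpois(dat$nS, lam * (1 - pm)), 0L)
      st$lpd <- lpd_term(st$N, st$eta, par$eps, st$act_s)
      st$lbin <- lbin_term(dat$d, st$N, st$obs$log_pmarg, st$act_s)
    }

    ## -- BCR hierarchical covariance: conjugate Gibbs ---------------------
    if (upd$wish) {
      pairs <- cbind(par$beta0, par$mu)
      nB <- nrow(pairs)
      Om <- solve(par$Sigma_w)
      prec <- nB * Om + diag(2) / cfg$prior_sd^2
      Vm <- solve(prec)
      mn <- Vm %*% (Om %*% colSums(pairs))
      par$mu_wish <- as.vector(mn + t(chol(Vm)) %*% stats::rnorm(2))
      S <- crossprod(sweep(pairs, 2, par$mu_wish))
      W <- stats::rWishart(1, cfg$df_wish + nB,
                           solve(cfg$R_wish + S))[, , 1]
      par$Sigma_w <- solve(W)
      par$Sigma_w <- (par$Sigma_w + t(par$Sigma_w)) / 2
    }

    ## -- save --------------------------------------------------------------
    if (!adapt && (it - warmup) %% thin == 0) {
      isave <- isave + 1L
      draws[isave, ] <- flatten_par(par, dat)
      if (!is.null(eps_draws)) eps_draws[isave, ] <- par$eps
    }
  }
  list(draws = draws, eps = eps_draws)
}

unflatten_ab <- function(par, v, dat) {
  cfg <- dat$config
  i <- 0L
  take <- function(n) { r <- v[i + seq_len(n)]; i <<- i + n; r }
  par$beta0[] <- take(length(par$beta0))
  if (length(par$beta)) par$beta[] <- take(length(par$beta))
  if (length(par$Gamma)) par$Gamma[] <- take(length(par$Gamma))
  if (cfg$trend) par$mu[] <- take(length(par$mu))
  par
}

# latent-path per-survey terms: Poisson of N at lambda (active surveys) and
# Binomial of d given N and pmarg
lpd_term <- function(N, eta, eps, act_s) {
  out <- numeric(length(N))
  lam <- exp(clamp(eta + eps, -700, 30))
  out[act_s] <- stats::dpois(N[act_s], lam[act_s], log = TRUE)
  out
}

lbin_term <- function(d, N, log_pmarg, act_s) {
  out <- numeric(length(N))
  p <- exp(clamp(log_pmarg, -700, 0))
  out[act_s] <- stats::dbinom(d[act_s], N[act_s], p[act_s], log = TRUE)
  out
}

latent_recache <- function(st, par, N, Active, dat) {
  st$N <- N; st$Active <- Active
  st$act_s <- Active[dat$gidx] == 1L
  st$lpd <- lpd_term(N, st$eta, par$eps, st$act_s)
  st$lbin <- lbin_term(dat$d, N, st$obs$log_pmarg, st$act_s)
  st
}

#' Combine posterior draws across chains
#'
#' @param fit A `songscape_fit`.
#' @return Matrix of all retained draws (rows) by parameter (columns).
#' @export
posterior_matrix <- function(fit) {
  do.call(rbind, fit$draws)
}

#' Posterior summary table
#'
#' @param fit A `songscape_fit`.
#' @param probs Quantiles to report.
#' @return Data frame with mean, sd and quantiles per parameter.
#' @export
posterior_summary <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  m <- posterior_matrix(fit)
  q <- t(apply(m, 2, stats::quantile, probs = probs))
  colnames(q) <- paste0("q", probs * 100)
  data.frame(parameter = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, stats::sd), q, row.names = NULL,
             check.names = FALSE)
}
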