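#' Split-chain Gelman-Rubin statistic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also registers. Values near 1 indicate
#' convergence; the conventional acceptance threshold for this model family
#' is 1.1.
#'
#' @param x Matrix of draws, iterations by chains (>= 2 chains, >= 4
#'   iterations).
#' @return Scalar R-hat; `NA` (degenerate, with a warning) when the total
#'   variance is zero.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 chains for R-hat")
  if (nrow(x) < 4) stop("need at least 4 iterations for R-hat")
  n2 <- floor(nrow(x) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n2), j], x[n2 + seq_len(n2), j])))
  m <- ncol(halves); n <- nrow(halves)
  ch_mean <- colMeans(halves)
  ch_var <- apply(halves, 2, stats::var)
  W <- mean(ch_var)
  B <- n * stats::var(ch_mean)
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance; R-hat degenerate")
    return(NA_real_)
  }
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' R-hat for every monitored parameter of a fit
#'
#' @param fit A `songscape_fit`.
#' @return Named vector of split-chain R-hat values.
#' @export
rhat_all <- function(fit) {
  vapply(seq_along(fit$par_names), function(j)
    rhat(sapply(fit$draws, function(ch) ch[, j])),
    numeric(1)) |> stats::setNames(fit$par_names)
}

#' Effective sample size
#'
#' Crude autocorrelation-based ESS: chains are pooled after centering, and
#' the integrated autocorrelation time is truncated at the first negative
#' autocorrelation estimate.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return Scalar effective sample size.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (stats::sd(x) == 0) return(NA_real_)
  rho <- rowMeans(sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = min(n - 1, 200), plot = FALSE,
                    demean = TRUE)$acf[-1]
    a
  }))
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  max(1, m * n / (1 + 2 * sum(rho)))
}

# rebuild a parameter list from one stored draw (plus its survey effects)
par_from_draw <- function(fit, chain, i) {
  dat <- fit$dat
  v <- fit$draws[[chain]][i, ]
  par <- init_params(dat)  # template for shapes (RNG state untouched
                           # except for the template jitters, overwritten
                           # below)
  nm <- fit$par_names
  g <- function(p) unname(v[startsWith(nm, p)])
  par$alpha <- v[["alpha"]]
  par$A <- c(v[["A[1]"]], v[["A[2]"]])
  par$tau <- g("tau[")
  par$beta0[] <- g("beta0[")
  if (length(par$beta)) par$beta[] <- g("beta[")
  if (length(par$Gamma)) par$Gamma[] <- g("Gamma[")
  if (dat$config$trend) par$mu[] <- g("mu[")
  if (length(par$scales)) par$scales[] <- g("scale[")
  if (dat$config$survey_effect) {
    par$sd_survey <- v[["sd_survey"]]
    par$eps <- fit$eps[[chain]][i, ]
  } else par$eps <- numeric(dat$nS)
  if (dat$config$spline) {
    par$a0 <- v[["a0"]]
    par$b[] <- g("b[")
    par$log_omega <- v[["log_omega"]]
  }
  for (nmf in intersect(names(dat$config$fixed),
                        c("alpha", "A", "tau", "sd_survey")))
    par[[nmf]] <- dat$config$fixed[[nmf]]
  par
}

#' Chi-square discrepancy posterior predictive check
#'
#' Bayesian p-value: for each retained draw, the range indicator `Active`
#' is sampled from its conditional given the data, expected survey counts
#' `E = Active * lambda * pmarg` are formed, replicate counts are drawn from
#' the fitted observation model, and the discrepancy
#' `T = sum (obs - E)^2 / (E + eps)` (with `eps = 0.5` guarding small
#' expectations) is compared between replicate and observed data:
#' `p = Pr[T(rep) >= T(obs)]`. Values near 0.5 indicate adequate fit.
#'
#' @param fit A `songscape_fit`.
#' @param n_draws Number of posterior draws to use (default: all).
#' @param eps Stabilizing constant added to expected counts.
#' @param seed Seed for the replicate draws.
#' @return List `p` (the Bayesian p-value), `T_obs`, `T_rep` (vectors).
#' @export
bayes_pvalue_chisq <- function(fit, n_draws = NULL, eps = 0.5, seed = 1L) {
  dat <- fit$dat
  per_ch <- nrow(fit$draws[[1]])
  total <- per_ch * fit$chains
  if (is.null(n_draws)) n_draws <- total
  n_draws <- min(n_draws, total)
  idx <- unique(round(seq(1, total, length.out = n_draws)))
  set.seed(seed)
  T_obs <- T_rep <- numeric(length(idx))
  for (k in seq_along(idx)) {
    chain <- (idx[k] - 1) %/% per_ch + 1L
    i <- (idx[k] - 1) %% per_ch + 1L
    par <- par_from_draw(fit, chain, i)
    st <- build_state(par, dat)
    lamp <- exp(clamp(st$eta + par$eps + st$obs$log_pmarg, -700, 30))
    # Active | data, theta
    gp <- st$gpois
    p1 <- ifelse(dat$anyd, 1,
                 1 / (1 + exp(st$log_1mpsi - (st$log_psi + gp))))
    A <- stats::rbinom(dat$nG, 1, p1)
    ex <- A[dat$gidx] * lamp
    y_rep <- stats::rpois(dat$nS, ex)
    T_obs[k] <- sum((dat$d - ex)^2 / (ex + eps))
    T_rep[k] <- sum((y_rep - ex)^2 / (ex + eps))
  }
  list(p = mean(T_rep >= T_obs), T_obs = T_obs, T_rep = T_rep)
}

#' Convergence and fit report
#'
#' @param fit A `songscape_fit`.
#' @param pvalue_draws Draws for the posterior predictive check (default
#'   200, for speed; pass `NULL` for all).
#' @param seed Seed for the predictive replicates.
#' @return A `fit_report` list: per-parameter R-hat and ESS, the Bayesian
#'   p-value, and runtime metadata.
#' @export
fit_report <- function(fit, pvalue_draws = 200, seed = 1L) {
  rh <- rhat_all(fit)
  es <- vapply(seq_along(fit$par_names), function(j)
    ess(sapply(fit$draws, function(ch) ch[, j])), numeric(1))
  names(es) <- fit$par_names
  pv <- bayes_pvalue_chisq(fit, n_draws = pvalue_draws, seed = seed)
  structure(list(rhat = rh, ess = es, bayes_p = pv$p,
                 max_rhat = max(rh, na.rm = TRUE),
                 runtime_s = fit$runtime_s, chains = fit$chains,
                 draws_per_chain = nrow(fit$draws[[1]]),
                 method = fit$method, seed = fit$seed),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> max R-hat %.3f | Bayesian p %.3f | %d x %d draws | %.1f s\n",
              x$max_rhat, x$bayes_p, x$chains, x$draws_per_chain,
              x$runtime_s))
  invisible(x)
}

#' Write a fit report as JSON
#'
#' @param report A `fit_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write JSON reports")
  jsonlite::write_json(
    list(max_rhat = report$max_rhat, bayes_p = report$bayes_p,
         rhat = as.list(report$rhat), ess = as.list(report$ess),
         chains = report$chains, draws_per_chain = report$draws_per_chain,
         method = report$method, seed = report$seed,
         runtime_s = report$runtime_s),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export posterior draws as tidy CSV
#'
#' Long format: chain, iteration, parameter, value.
#'
#' @param fit A `songscape_fit`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  rows <- lapply(seq_along(fit$draws), function(ch) {
    m <- fit$draws[[ch]]
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  write_csv_prov(do.call(rbind, rows), path, seed = fit$seed)
}

#' Read posterior draws from tidy CSV
#'
#' @param path CSV written by [write_draws_csv].
#' @return List of per-chain draw matrices (as in a `songscape_fit`).
#' @export
read_draws_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  lapply(split(d, d$chain), function(ch) {
    pars <- unique(ch$parameter)
    m <- sapply(pars, function(p) ch$value[ch$parameter == p])
    colnames(m) <- pars
    m
  })
}
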