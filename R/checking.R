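#' Posterior predictive draws and band coverage
#'
#' Simulates replicated observation sets by drawing a posterior sample of the
#' parameters and then data from the observation model: independent normals
#' around the sigmoid for the sigmoid family, the GP-marginalized correlated
#' normal `N(S, C + sigma^2 I)` for the semi-parametric family. Returns
#' pointwise 50%/95% predictive intervals and the fraction of observed points
#' each contains; observed data falling outside the bands indicates model
#' insufficiency.
#'
#' @param samples a `posterior_samples` object.
#' @param protein the fitted [protein_melting_data].
#' @param n_rep number of replicated datasets.
#' @param seed integer seed.
#' @return list with `y_rep` (`n_rep x n` matrix), `y_obs`, `T`, `condition`,
#'   `bands` (pointwise median and 50/95 interval bounds), `coverage_50`,
#'   `coverage_95`.
#' @export
posterior_predictive_draws <- function(samples, protein, n_rep = 200L, seed = 1L) {
  stopifnot(inherits(samples, "posterior_samples"))
  spec <- samples$spec
  set.seed(as.integer(seed %% .Machine$integer.max))
  S_total <- nrow(samples$blocks[[1L]]$draws)
  pick <- sample.int(S_total, n_rep, replace = n_rep > S_total)

  conds <- if (spec$hypothesis == "M0") list(NULL) else as.list(protein$conditions)
  block_reps <- vector("list", length(conds))
  y_obs <- T_all <- cond_all <- NULL
  for (bi in seq_along(conds)) {
    d <- block_data(protein, conds[[bi]])
    theta <- constrain_block(samples$blocks[[bi]]$draws[pick, , drop = FALSE])
    n <- length(d$y)
    yr <- matrix(NA_real_, n_rep, n)
    for (s in seq_len(n_rep)) {
      a <- theta[s, 1L]; b <- theta[s, 2L]; p <- theta[s, 3L]; sg <- theta[s, 4L]
      mu <- sigmoid(d$T, a, b, p)
      if (spec$family == "semiparametric") {
        K <- se_covariance(d$T, theta[s, 5L], theta[s, 6L]) + sg^2 * diag(n)
        R <- chol_jitter(K, theta[s, 5L])
        yr[s, ] <- mu + as.vector(t(R) %*% rnorm(n))
      } else {
        yr[s, ] <- mu + rnorm(n, 0, sg)
      }
    }
    block_reps[[bi]] <- yr
    y_obs <- c(y_obs, d$y)
    T_all <- c(T_all, d$T)
    cond_all <- c(cond_all, rep(if (is.null(conds[[bi]])) "pooled" else conds[[bi]],
                                length(d$y)))
  }
  y_rep <- do.call(cbind, block_reps)

  qs <- apply(y_rep, 2L, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
              names = FALSE)
  bands <- list(median = qs[3L, ], lower_50 = qs[2L, ], upper_50 = qs[4L, ],
                lower_95 = qs[1L, ], upper_95 = qs[5L, ])
  list(y_rep = y_rep, y_obs = y_obs, T = T_all, condition = cond_all,
       bands = bands,
       coverage_50 = mean(y_obs >= bands$lower_50 & y_obs <= bands$upper_50),
       coverage_95 = mean(y_obs >= bands$lower_95 & y_obs <= bands$upper_95))
}

#' Pointwise log-likelihood matrix
#'
#' Per-draw, per-observation log predictive densities used by
#' [psis_loo_elpd()]. For the sigmoid family observations are independent
#' given the parameters. For the semi-parametric family, where observations
#' are correlated through the marginalized GP, each observation's
#' contribution is its leave-one-out conditional density
#' `p(y_i | y_{-i}, theta)` - exact for a multivariate normal via the
#' precision matrix - which is the correct pointwise term for LOO with
#' correlated data.
#'
#' @param samples a `posterior_samples` object.
#' @param protein the fitted [protein_melting_data].
#' @param max_draws cap on the number of draws used (evenly subsampled).
#' @return `S x n` matrix of log densities.
#' @export
pointwise_loglik <- function(samples, protein, max_draws = 1000L) {
  stopifnot(inherits(samples, "posterior_samples"))
  spec <- samples$spec
  S_total <- nrow(samples$blocks[[1L]]$draws)
  keep <- unique(round(seq(1L, S_total, length.out = min(max_draws, S_total))))
  conds <- if (spec$hypothesis == "M0") list(NULL) else as.list(protein$conditions)
  mats <- vector("list", length(conds))
  for (bi in seq_along(conds)) {
    d <- block_data(protein, conds[[bi]])
    theta <- constrain_block(samples$blocks[[bi]]$draws[keep, , drop = FALSE])
    n <- length(d$y)
    ll <- matrix(NA_real_, length(keep), n)
    for (s in seq_along(keep)) {
      a <- theta[s, 1L]; b <- theta[s, 2L]; p <- theta[s, 3L]; sg <- theta[s, 4L]
      mu <- sigmoid(d$T, a, b, p)
      if (spec$family == "sigmoid") {
        ll[s, ] <- dnorm(d$y, mu, sg, log = TRUE)
      } else {
        K <- se_covariance(d$T, theta[s, 5L], theta[s, 6L]) + sg^2 * diag(n)
        R <- chol_jitter(K, theta[s, 5L])
        Rinv <- backsolve(R, diag(n))
        Q <- Rinv %*% t(Rinv)
        r <- d$y - mu
        qr_ <- as.vector(Q %*% r)
        cond_sd <- sqrt(1 / diag(Q))
        cond_mean <- d$y - qr_ / diag(Q)
        ll[s, ] <- dnorm(d$y, cond_mean, cond_sd, log = TRUE)
      }
    }
    mats[[bi]] <- ll
  }
  do.call(cbind, mats)
}

# generalized Pareto fit to tail exceedances (Zhang & Stephens 2009 profile
# posterior-mean estimator, with the standard weak prior pulling k towards 0.5)
gpd_fit <- function(x) {
  n <- length(x)
  x <- sort(x)
  if (n < 5L || x[n] <= 0 || sd(x) == 0)
    return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(floor(n / 4 + 0.5), 1L)]
  if (xstar <= 0) xstar <- x[x > 0][1L]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_theta <- vapply(theta, function(t) mean(log1p(-t * x)), numeric(1))
  l_theta <- n * (log(-theta / k_theta) - k_theta - 1)
  ok <- is.finite(l_theta)
  if (!any(ok)) return(list(k = Inf, sigma = NA_real_))
  l_theta[!ok] <- -Inf
  w <- exp(l_theta - max(l_theta))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (k * n + 0.5 * 10) / (n + 10)
  list(k = k, sigma = sigma)
}

# smooth one observation's log importance ratios; returns shifted log weights
# and the Pareto shape diagnostic
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L) return(list(lw = lw, khat = Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1L):S]
  cutoff_lw <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff_lw)
  fit <- gpd_fit(exceed)
  if (is.finite(fit$k) && is.finite(fit$sigma) && fit$sigma > 0) {
    pr <- (seq_len(M) - 0.5) / M
    q <- if (abs(fit$k) < 1e-12) -fit$sigma * log1p(-pr)
         else fit$sigma * expm1(-fit$k * log1p(-pr)) / fit$k
    sm <- log(exp(cutoff_lw) + q)
    sm <- pmin(sm, 0)  # truncate at the maximum raw weight
    lw[tail_ids] <- sm  # tail_ids and sm are both in increasing order
  }
  list(lw = lw, khat = fit$k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Estimates leave-one-out cross-validated predictive performance from
#' posterior draws by importance sampling, with the largest importance
#' ratios per observation smoothed by a generalized-Pareto fit (tail
#' fraction `min(0.2 S, 3 sqrt(S)) / S`). The Pareto shape `k` diagnoses
#' reliability; observations with `k > 0.7` are counted in `n_high_k` and
#' reported, not refit.
#'
#' @param loglik `S x n` matrix of pointwise log likelihoods
#'   `log p(y_i | theta_s)` (see [pointwise_loglik()]).
#' @return object of class `loo_result`: `elpd_loo`, `se_elpd`, `pointwise`,
#'   `pareto_k`, `n_high_k`.
#' @export
psis_loo_elpd <- function(loglik) {
  if (!is.matrix(loglik)) stop("loglik must be an S x n matrix")
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood entries")
  n <- ncol(loglik)
  pointwise <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-loglik[, i])
    pointwise[i] <- log_sum_exp(loglik[, i] + sm$lw) - log_sum_exp(sm$lw)
    khat[i] <- sm$khat
  }
  structure(list(elpd_loo = sum(pointwise),
                 se_elpd = sqrt(n) * sd(pointwise),
                 pointwise = pointwise, pareto_k = khat,
                 n_high_k = sum(!is.finite(khat) | khat > 0.7)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> elpd_loo = %.1f +/- %.1f (SE), %d/%d observations with Pareto k > 0.7\n",
              x$elpd_loo, x$se_elpd, x$n_high_k, length(x$pointwise)))
  invisible(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Variance explained by fitted melting curves
#'
#' `R^2 = 1 - RSS / TSS`, pooled over conditions and replicates: `RSS` uses
#' the supplied fitted curve per condition (typically the posterior-median
#' curve of a condition-specific fit), `TSS` is around each condition's own
#' mean.
#'
#' @param protein a [protein_melting_data].
#' @param fitted_curves named list (per condition) of fitted values at the
#'   protein's observed temperatures.
#' @return scalar `R^2`.
#' @export
variance_explained <- function(protein, fitted_curves) {
  rss <- tss <- 0
  for (cc in protein$conditions) {
    m <- protein$observations[[cc]]
    curve <- fitted_curves[[cc]]
    if (is.null(curve) || length(curve) != length(protein$temperatures))
      stop("fitted_curves must supply one value per temperature per condition")
    res <- sweep(m, 2L, curve)
    rss <- rss + sum(res^2, na.rm = TRUE)
    tss <- tss + sum((m - mean(m, na.rm = TRUE))^2, na.rm = TRUE)
  }
  if (tss == 0) stop("zero total sum of squares")
  1 - rss / tss
}

#' Flag non-sigmoid melting behaviour
#'
#' A protein is flagged when the semi-parametric model explains at least
#' `threshold` (default 5%) more variance than the sigmoid model alone.
#' The boundary is inclusive.
#'
#' @param delta_r2 `R^2(semi-parametric) - R^2(sigmoid)`.
#' @param threshold flag threshold (default 0.05).
#' @return logical.
#' @export
flag_non_sigmoid <- function(delta_r2, threshold = 0.05) {
  if (any(!is.finite(delta_r2))) stop("delta_r2 must be finite")
  delta_r2 >= threshold
}
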