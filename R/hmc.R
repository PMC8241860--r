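#' Sampler settings
#'
#' Defaults: 4 chains of 1000 warmup + 1000 retained draws with target
#' acceptance 0.9. Refits of divergence-flagged proteins raise the target
#' acceptance to 0.99. `max_L` bounds the jittered trajectory length.
#'
#' @param chains,warmup,draws chain count and per-chain iteration counts.
#' @param target_accept dual-averaging acceptance target in (0, 1).
#' @param max_L maximum leapfrog steps per trajectory.
#' @return list of settings.
#' @export
sampler_settings <- function(chains = 4L, warmup = 1000L, draws = 1000L,
                             target_accept = 0.9, max_L = 32L) {
  stopifnot(chains >= 1, warmup >= 100, draws >= 1,
            target_accept > 0, target_accept < 1, max_L >= 1)
  list(chains = as.integer(chains), warmup = as.integer(warmup),
       draws = as.integer(draws), target_accept = target_accept,
       max_L = as.integer(max_L))
}

#' Adaptive Hamiltonian Monte Carlo on an arbitrary target
#'
#' Runs the package's sampler (dual-averaging step size, dense metric adapted
#' during warmup, jittered trajectory lengths, divergence detection) on a
#' user-supplied log density with gradient. Used internally for the built-in
#' melting models through a compiled fast path; this entry point accepts any
#' target and is convenient for toy and calibration studies.
#'
#' @param lp_grad function of the parameter vector returning
#'   `list(lp = scalar, grad = vector)`.
#' @param init numeric vector (single start) or list of per-chain starts.
#' @param seed integer seed; chains use `seed + chain index`.
#' @param settings a [sampler_settings()] list.
#' @return list with `draws` (matrix, chains stacked), `lp`, `chain`
#'   (chain label per draw) and `diagnostics` (split R-hat, bulk ESS per
#'   parameter, divergence count, mean acceptance).
#' @export
hmc_sample <- function(lp_grad, init, seed = 1L, settings = sampler_settings()) {
  inits <- if (is.list(init)) init else rep(list(init), settings$chains)
  if (length(inits) != settings$chains)
    inits <- rep(inits, length.out = settings$chains)
  chains <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(as.integer((seed + ch - 1L) %% .Machine$integer.max))
    chains[[ch]] <- hmc_chain_cpp(0L, numeric(0), numeric(0), numeric(0),
                                  inits[[ch]], settings$warmup, settings$draws,
                                  settings$target_accept, settings$max_L,
                                  lp_grad)
  }
  combine_chains(chains, param_names = names(inits[[1L]]))
}

# run the compiled fast path for one model block
hmc_sample_block <- function(model_code, y, T, prior_vec, inits, seed, settings) {
  chains <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(as.integer((seed + ch - 1L) %% .Machine$integer.max))
    chains[[ch]] <- hmc_chain_cpp(model_code, y, T, prior_vec, inits[[ch]],
                                  settings$warmup, settings$draws,
                                  settings$target_accept, settings$max_L, NULL)
  }
  combine_chains(chains)
}

combine_chains <- function(chains, param_names = NULL) {
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  if (!is.null(param_names)) colnames(draws) <- param_names
  lp <- unlist(lapply(chains, `[[`, "lp"), use.names = FALSE)
  chain_id <- rep(seq_along(chains), each = nrow(chains[[1L]]$draws))
  per_chain <- lapply(chains, `[[`, "draws")
  diag <- list(
    rhat = apply_over_params(per_chain, split_rhat),
    ess_bulk = apply_over_params(per_chain, bulk_ess),
    divergences = sum(vapply(chains, `[[`, numeric(1), "divergences")),
    accept_stat = mean(vapply(chains, `[[`, numeric(1), "accept_stat")),
    stepsize = vapply(chains, `[[`, numeric(1), "stepsize"))
  list(draws = draws, lp = lp, chain = chain_id, diagnostics = diag)
}

apply_over_params <- function(per_chain, f) {
  P <- ncol(per_chain[[1L]])
  vapply(seq_len(P), function(j)
    f(rank_normalize(lapply(per_chain, function(m) m[, j]))), numeric(1))
}

# rank-normalization across pooled chains (fractional ranks mapped through the
# normal quantile function), the standard robustification of R-hat/ESS against
# heavy-tailed posteriors such as the plateau's logit scale
rank_normalize <- function(chain_vecs) {
  n <- lengths(chain_vecs)
  pooled <- unlist(chain_vecs, use.names = FALSE)
  z <- qnorm((rank(pooled, ties.method = "average") - 3 / 8) /
             (length(pooled) + 1 / 4))
  split(z, rep(seq_along(chain_vecs), n))
}

# split R-hat (each chain halved) on one parameter
split_rhat <- function(chain_vecs) {
  halves <- unlist(lapply(chain_vecs, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  n <- length(halves[[1L]])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(if (B <= 1e-300) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# bulk ESS via Geyer's initial monotone positive sequence on pooled chains
bulk_ess <- function(chain_vecs) {
  m <- length(chain_vecs)
  n <- length(chain_vecs[[1L]])
  if (n < 4L) return(NA_real_)
  acovs <- lapply(chain_vecs, function(x) {
    x <- x - mean(x)
    stats::acf(x, lag.max = n - 1L, plot = FALSE, type = "covariance",
               demean = FALSE)$acf[, 1L, 1L]
  })
  mean_var <- mean(vapply(chain_vecs, var, numeric(1)))
  if (!is.finite(mean_var) || mean_var <= 0) return(m * n)
  rho <- Reduce(`+`, acovs) / (m * mean_var)
  # paired sums; stop at first negative, enforce monotone decrease
  tau <- 1
  prev <- Inf
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
    k <- k + 2L
  }
  max(m * n / tau, 1)
}

# Chain initialization. The melting posteriors can carry minor secondary
# modes (the sigmoid and GP terms can partially explain each other), so
# diffuse starts occasionally trap a chain. Chains are therefore started at
# the least-squares sigmoid fit - the dominant mode - with multiplicative
# jitter, falling back to prior draws filtered to finite log posterior
# (up to 20 retries) when no least-squares anchor is available.
init_chains <- function(spec, lp_fun, n_chains, y = NULL, T = NULL,
                        max_tries = 20L) {
  anchor <- NULL
  if (!is.null(y)) {
    ls <- fit_sigmoid_block_ls(T, y)
    if (ls$converged) {
      sigma_hat <- min(max(sqrt(ls$rss / max(ls$n_obs - 3, 1)), 0.01), 0.3)
      anchor <- c(a = max(ls$params["a"], 1), b = max(ls$params["b"], 0.1),
                  p = min(max(ls$params["p"], 0.005), 0.95), sigma = sigma_hat)
      if (spec$family == "semiparametric")
        anchor <- c(anchor, v = sigma_hat / 2, l = exp(spec$priors$l$meanlog))
      if (!is.finite(lp_fun(unconstrain_block(anchor)))) anchor <- NULL
    }
  }
  pr <- spec$priors
  inits <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      if (!is.null(anchor)) {
        u <- unconstrain_block(anchor) + rnorm(length(anchor), 0, 0.15)
      } else {
        theta <- c(a = rgamma(1, pr$a$shape, rate = pr$a$rate),
                   b = rgamma(1, pr$b$shape, rate = pr$b$rate),
                   p = rbeta(1, pr$p$alpha, pr$p$beta),
                   sigma = max(abs(rnorm(1, 0, pr$sigma$scale)), 1e-3))
        if (spec$family == "semiparametric")
          theta <- c(theta,
                     v = max(abs(pr$v$scale * rt(1, pr$v$df)), 1e-3),
                     l = rlnorm(1, pr$l$meanlog, pr$l$sdlog))
        u <- unconstrain_block(theta)
      }
      if (is.finite(lp_fun(u))) {
        inits[[ch]] <- u
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
  }
  inits
}

#' Sample the posterior of a melting model for one protein
#'
#' Runs adaptive HMC on the chosen model variant. Under `M1` the two
#' conditions are fitted as independent single-condition blocks (exact, since
#' the `M1` posterior factorizes across conditions) and the per-block draws,
#' log posteriors and diagnostics are kept separate so marginal likelihoods
#' add across blocks. A fit is flagged unreliable when any split R-hat
#' exceeds 1.01 or divergences exceed 0.1% of retained draws; flagged fits
#' are refit once with target acceptance 0.99 before the flag sticks.
#'
#' @param spec a [model_spec].
#' @param protein a complete [protein_melting_data].
#' @param seed integer seed (reproducible for fixed seed).
#' @param settings a [sampler_settings()] list.
#' @param refit_on_flag refit once with target acceptance 0.99 if flagged.
#' @return an object of class `posterior_samples`: per-block draws on the
#'   unconstrained and constrained scales, per-draw log posterior, sampler
#'   diagnostics, and the flag.
#' @export
sample_posterior <- function(spec, protein, seed = 1L,
                             settings = sampler_settings(),
                             refit_on_flag = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(protein, "protein_melting_data"))
  pv <- prior_vector(spec$priors)
  conds <- if (spec$hypothesis == "M0") list(NULL) else as.list(protein$conditions)

  run_once <- function(settings) {
    blocks <- vector("list", length(conds))
    for (bi in seq_along(conds)) {
      d <- block_data(protein, conds[[bi]])
      lp_fun <- function(u) lp_grad_cpp(spec$model_code, u, d$y, d$T, pv)$lp
      set.seed(as.integer((seed + 7919L * bi) %% .Machine$integer.max))
      inits <- init_chains(spec, lp_fun, settings$chains, y = d$y, T = d$T)
      if (is.null(inits)) return(NULL)
      fit <- hmc_sample_block(spec$model_code, d$y, d$T, pv, inits,
                              seed + 104729L * bi, settings)
      colnames(fit$draws) <- paste0(spec$block_names,
                                    if (!is.null(conds[[bi]])) paste0("_", bi) else "")
      blocks[[bi]] <- fit
    }
    blocks
  }

  total_draws <- settings$draws * settings$chains
  blocks <- run_once(settings)
  flagged <- is.null(blocks) || any(vapply(blocks, block_flagged, logical(1),
                                           total_draws))
  if (flagged && refit_on_flag) {
    has_div <- !is.null(blocks) &&
      any(vapply(blocks, function(b) b$diagnostics$divergences, numeric(1)) >
            0.001 * total_draws)
    settings2 <- settings
    if (has_div) {
      settings2$target_accept <- 0.99
    } else {
      # an R-hat flag without divergences means slow mixing: run longer
      settings2$warmup <- 2L * settings$warmup
      settings2$draws <- 2L * settings$draws
    }
    blocks2 <- run_once(settings2)
    if (!is.null(blocks2)) {
      flagged2 <- any(vapply(blocks2, block_flagged, logical(1),
                             settings2$draws * settings2$chains))
      adopt <- is.null(blocks) || !flagged2 ||
        (max_rhat_of(blocks2) < max_rhat_of(blocks))
      if (adopt) {
        blocks <- blocks2
        flagged <- flagged2
      }
    }
  }
  if (is.null(blocks))
    stop(sprintf("sampler initialization failed for protein %s", protein$protein_id))

  structure(
    list(spec = spec, protein_id = protein$protein_id,
         conditions = protein$conditions, blocks = blocks,
         unreliable = flagged, seed = seed, settings = settings),
    class = "posterior_samples")
}

max_rhat_of <- function(blocks) {
  max(unlist(lapply(blocks, function(b) b$diagnostics$rhat)))
}

block_flagged <- function(block, n_total_draws) {
  any(!is.finite(block$diagnostics$rhat)) ||
    any(block$diagnostics$rhat > 1.01) ||
    block$diagnostics$divergences > 0.001 * n_total_draws
}

#' @export
print.posterior_samples <- function(x, ...) {
  rh <- unlist(lapply(x$blocks, function(b) b$diagnostics$rhat))
  cat(sprintf("<posterior_samples> %s %s/%s: %d draws x %d params, max R-hat %.3f, %d divergences%s\n",
              x$protein_id, x$spec$family, x$spec$hypothesis,
              nrow(x$blocks[[1L]]$draws), x$spec$n_params, max(rh),
              sum(vapply(x$blocks, function(b) b$diagnostics$divergences, numeric(1))),
              if (x$unreliable) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Constrained-scale draws from a fit
#'
#' @param samples a `posterior_samples` object.
#' @return matrix of posterior draws on the natural parameter scale, columns
#'   named per parameter (suffixed `_1`/`_2` per condition under `M1`).
#' @export
constrained_draws <- function(samples) {
  mats <- lapply(samples$blocks, function(b) {
    m <- constrain_block(b$draws)
    colnames(m) <- colnames(b$draws)
    m
  })
  do.call(cbind, mats)
}
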