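# iid normal toy with known sigma and conjugate mean prior: exact LOO
# predictive densities are available for the refit oracle
loo_toy <- function(n = 20, sigma = 0.7, tau = 3, seed = 5) {
  set.seed(seed)
  y <- rnorm(n, 1, sigma)
  list(y = y, sigma = sigma, tau = tau)
}

exact_loo <- function(toy) {
  # refit leaving each observation out; predictive is normal with inflated sd
  vapply(seq_along(toy$y), function(i) {
    y_i <- toy$y[-i]
    post_var <- 1 / (length(y_i) / toy$sigma^2 + 1 / toy$tau^2)
    post_mean <- post_var * sum(y_i) / toy$sigma^2
    dnorm(toy$y[i], post_mean, sqrt(post_var + toy$sigma^2), log = TRUE)
  }, numeric(1))
}

toy_loglik_matrix <- function(toy, S = 4000, seed = 31) {
  set.seed(seed)
  n <- length(toy$y)
  post_var <- 1 / (n / toy$sigma^2 + 1 / toy$tau^2)
  post_mean <- post_var * sum(toy$y) / toy$sigma^2
  draws <- rnorm(S, post_mean, sqrt(post_var))
  t(vapply(draws, function(th) dnorm(toy$y, th, toy$sigma, log = TRUE),
           numeric(n)))
}

test_that("PSIS-LOO matches exact refit LOO on the conjugate toy", {
  toy <- loo_toy()
  res <- psis_loo_elpd(toy_loglik_matrix(toy))
  exact <- sum(exact_loo(toy))
  expect_lt(abs(res$elpd_loo - exact), 2 * res$se_elpd)
  expect_true(all(res$pareto_k < 0.7))
  expect_equal(res$n_high_k, 0L)
})

test_that("LOO result invariants hold", {
  toy <- loo_toy(seed = 9)
  ll <- toy_loglik_matrix(toy, seed = 10)
  res <- psis_loo_elpd(ll)
  expect_equal(res$elpd_loo, sum(res$pointwise))
  expect_equal(res$se_elpd, sqrt(ncol(ll)) * sd(res$pointwise))
  # permuting draws leaves the estimate unchanged; permuting observations
  # permutes the pointwise terms
  set.seed(2)
  res_r <- psis_loo_elpd(ll[sample(nrow(ll)), ])
  expect_equal(res_r$elpd_loo, res$elpd_loo, tolerance = 1e-10)
  perm <- sample(ncol(ll))
  res_c <- psis_loo_elpd(ll[, perm])
  expect_equal(res_c$pointwise, res$pointwise[perm], tolerance = 1e-10)
})

test_that("degenerate draws reduce to the plug-in predictive density", {
  toy <- loo_toy(seed = 12)
  one <- dnorm(toy$y, 0.8, toy$sigma, log = TRUE)
  ll <- matrix(one, nrow = 500, ncol = length(toy$y), byrow = TRUE)
  res <- psis_loo_elpd(ll)
  expect_equal(res$elpd_loo, sum(one), tolerance = 1e-10)
  expect_equal(res$n_high_k, length(toy$y))  # flagged, not silently trusted
  expect_error(psis_loo_elpd(ll * NA), "non-finite")
})

test_that("pointwise log-likelihoods: sigmoid iid vs semi-parametric conditional", {
  p <- make_protein(sigma = 0.05, seed = 51)
  st <- sampler_settings(chains = 2, warmup = 300, draws = 200)
  fit <- sample_posterior(model_spec("sigmoid", "M0"), p, seed = 3, settings = st)
  ll <- pointwise_loglik(fit, p, max_draws = 100)
  expect_equal(dim(ll), c(100L, 40L))
  # reproduce one entry by hand
  th <- tppbayes:::constrain_block(fit$blocks[[1]]$draws[1, , drop = FALSE])
  d <- tppbayes:::block_data(p)
  expect_equal(ll[1, 7],
               dnorm(d$y[7], sigmoid(d$T[7], th[1], th[2], th[3]), th[4], log = TRUE))
  # semi-parametric terms are leave-one-out conditionals: with v ~ 0 they
  # coincide with the iid terms
  fit_sp <- sample_posterior(model_spec("semiparametric", "M0"), p, seed = 4,
                             settings = st)
  fit_sp$blocks[[1]]$draws[, 5] <- log(1e-8)  # force v -> 0 at all draws
  ll_sp <- pointwise_loglik(fit_sp, p, max_draws = 50)
  th_sp <- tppbayes:::constrain_block(fit_sp$blocks[[1]]$draws[1, , drop = FALSE])
  expect_equal(ll_sp[1, ],
               dnorm(d$y, sigmoid(d$T, th_sp[1], th_sp[2], th_sp[3]), th_sp[4],
                     log = TRUE),
               tolerance = 1e-6)
})

test_that("posterior predictive bands cover well-specified data and collapse when degenerate", {
  p <- make_protein(sigma = 0.05, seed = 52)
  st <- sampler_settings(chains = 2, warmup = 300, draws = 300)
  fit <- sample_posterior(model_spec("sigmoid", "M0"), p, seed = 6, settings = st)
  ppc <- posterior_predictive_draws(fit, p, n_rep = 300, seed = 7)
  expect_true(all(ppc$bands$lower_95 <= ppc$bands$lower_50))
  expect_true(all(ppc$bands$upper_50 <= ppc$bands$upper_95))
  expect_gte(ppc$coverage_95, ppc$coverage_50)
  expect_gt(ppc$coverage_95, 0.8)
  # degenerate posterior with tiny noise: replicates equal the fitted curve
  fit$blocks[[1]]$draws <- fit$blocks[[1]]$draws[rep(1L, 200L), ]
  fit$blocks[[1]]$draws[, 4] <- log(1e-8)
  fit$blocks[[1]]$lp <- rep(fit$blocks[[1]]$lp[1L], 200L)
  ppc0 <- posterior_predictive_draws(fit, p, n_rep = 100, seed = 8)
  th <- tppbayes:::constrain_block(fit$blocks[[1]]$draws[1, , drop = FALSE])
  d <- tppbayes:::block_data(p)
  expect_equal(ppc0$bands$median, sigmoid(d$T, th[1], th[2], th[3]),
               tolerance = 1e-6)
  expect_lt(max(ppc0$bands$upper_95 - ppc0$bands$lower_95), 1e-6)
})

test_that("variance explained: exact fit, mean fit, and errors", {
  p <- make_protein(sigma = 0.04, seed = 53)
  curves_mean <- lapply(p$observations, function(m) rep(mean(m), ncol(m)))
  names(curves_mean) <- p$conditions
  expect_equal(variance_explained(p, curves_mean), 0, tolerance = 1e-12)
  curves_exact <- lapply(p$conditions, function(cc) colMeans(p$observations[[cc]]))
  names(curves_exact) <- p$conditions
  expect_gt(variance_explained(p, curves_exact), 0.9)
  # a single-replicate protein fitted exactly gives R^2 = 1
  p1 <- make_protein(sigma = 0.03, n_reps = 1, seed = 54)
  curves1 <- lapply(p$conditions, function(cc) p1$observations[[cc]][1, ])
  names(curves1) <- p1$conditions
  expect_equal(variance_explained(p1, curves1), 1)
  flat <- protein_melting_data("F", c(37, 40, 43, 46), c("a", "b"),
                               list(matrix(0.5, 1, 4), matrix(0.5, 1, 4)))
  expect_error(variance_explained(flat, list(a = rep(0.5, 4), b = rep(0.5, 4))),
               "zero total sum of squares")
})

test_that("non-sigmoid flag boundary is inclusive at the threshold", {
  expect_true(flag_non_sigmoid(0.05))
  expect_false(flag_non_sigmoid(0.049))
  expect_false(flag_non_sigmoid(-0.1))
  expect_true(flag_non_sigmoid(0.2, threshold = 0.1))
  expect_error(flag_non_sigmoid(NaN), "finite")
})
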