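# conjugate normal-mean toy: y_i ~ N(theta, s2 known), theta ~ N(0, tau2);
# log evidence available in closed form
conjugate_toy <- function(n = 20, s2 = 1, tau2 = 4, seed = 17) {
  set.seed(seed)
  y <- rnorm(n, 1, sqrt(s2))
  post_var <- 1 / (n / s2 + 1 / tau2)
  post_mean <- post_var * sum(y) / s2
  logml <- sum(dnorm(y, 0, sqrt(s2), log = TRUE)) +
    0.5 * log(post_var / tau2) + 0.5 * post_mean^2 / post_var
  list(y = y, s2 = s2, tau2 = tau2, post_mean = post_mean,
       post_var = post_var, logml = logml)
}

toy_lp <- function(toy, th) {
  sum(dnorm(toy$y, th, sqrt(toy$s2), log = TRUE)) +
    dnorm(th, 0, sqrt(toy$tau2), log = TRUE)
}

test_that("Laplace-Metropolis evidence matches the conjugate closed form", {
  toy <- conjugate_toy()
  set.seed(3)
  draws <- matrix(rnorm(4000, toy$post_mean, sqrt(toy$post_var)), ncol = 1)
  lp <- vapply(draws[, 1], function(t) toy_lp(toy, t), numeric(1))
  est <- laplace_metropolis_logml(list(draws = draws, lp = lp))
  expect_lt(abs(est - toy$logml), 0.1)
})

test_that("evidence estimator is exact for a Gaussian posterior up to MC error", {
  # unnormalized target = N(mu, Sigma) density + known log normalizer
  set.seed(8)
  P <- 3
  A <- matrix(rnorm(P * P), P)
  Sigma <- crossprod(A) + diag(P)
  mu <- c(1, -2, 0.5)
  logZ <- 5.3
  L <- t(chol(Sigma))
  draws <- t(mu + L %*% matrix(rnorm(P * 4000), P))
  Sinv <- solve(Sigma)
  lp <- apply(draws, 1, function(th) {
    d <- th - mu
    logZ - 0.5 * P * log(2 * pi) - 0.5 * determinant(Sigma)$modulus[1] -
      0.5 * sum(d * (Sinv %*% d))
  })
  est <- laplace_metropolis_logml(list(draws = draws, lp = lp))
  # exact apart from sampling error in the covariance and the max-lp draw
  expect_lt(abs(est - logZ), 0.1)
})

test_that("doubling the draws leaves the estimate stable", {
  toy <- conjugate_toy(seed = 23)
  ests <- sapply(c(2000, 4000, 8000), function(S) {
    set.seed(91)
    draws <- matrix(rnorm(S, toy$post_mean, sqrt(toy$post_var)), ncol = 1)
    lp <- vapply(draws[, 1], function(t) toy_lp(toy, t), numeric(1))
    laplace_metropolis_logml(list(draws = draws, lp = lp))
  })
  expect_lt(max(ests) - min(ests), 0.1)
})

test_that("evidence is invariant to the choice of unconstrained transform", {
  # same positive-parameter toy model expressed on log and sqrt scales:
  # y_i ~ N(0, theta), theta ~ Gamma(3, 2)
  set.seed(12)
  y <- rnorm(30, 0, sqrt(1.5))
  base_lp <- function(theta) sum(dnorm(y, 0, sqrt(theta), log = TRUE)) +
    dgamma(theta, 3, rate = 2, log = TRUE)
  # draws via a fine grid (the toy is 1-D) to avoid sampler noise
  grid <- seq(0.2, 6, length.out = 4e4)
  w <- exp(vapply(grid, base_lp, numeric(1)))
  set.seed(13)
  theta_draws <- sample(grid, 4000, replace = TRUE, prob = w)
  # log transform: u = log(theta), Jacobian theta
  est_log <- laplace_metropolis_logml(list(
    draws = matrix(log(theta_draws), ncol = 1),
    lp = vapply(theta_draws, function(t) base_lp(t) + log(t), numeric(1))))
  # sqrt transform: u = sqrt(theta), Jacobian 2u
  est_sqrt <- laplace_metropolis_logml(list(
    draws = matrix(sqrt(theta_draws), ncol = 1),
    lp = vapply(theta_draws, function(t) base_lp(t) + log(2 * sqrt(t)), numeric(1))))
  expect_lt(abs(est_log - est_sqrt), 0.1)
})

test_that("evidence adds across independent condition blocks", {
  p <- make_protein(shift = 3, seed = 41)
  fit <- sample_posterior(model_spec("sigmoid", "M1"), p, seed = 14,
                          settings = test_settings())
  total <- laplace_metropolis_logml(fit)
  parts <- vapply(fit$blocks, function(b)
    laplace_metropolis_logml(list(draws = b$draws, lp = b$lp)), numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-10)
})

test_that("evidence estimation refuses too few draws", {
  expect_error(laplace_metropolis_logml(list(draws = matrix(rnorm(100), ncol = 1),
                                             lp = rnorm(100))),
               "at least 200")
})

test_that("posterior model probabilities follow the prior odds formula", {
  ev <- posterior_model_prob(-10, -10)
  expect_equal(ev$posterior_prob_M1, 0.01)
  ev2 <- posterior_model_prob(0, log(99))
  expect_equal(ev2$posterior_prob_M1, 0.5)
  ev3 <- posterior_model_prob(-5, -5, prior_prob_M0 = 0.5)
  expect_equal(ev3$posterior_prob_M1, 0.5)
  # extreme gaps neither overflow nor NaN
  expect_equal(posterior_model_prob(-1e6, 0)$posterior_prob_M1, 1)
  expect_equal(posterior_model_prob(0, -1e6)$posterior_prob_M1, 0)
  expect_equal(posterior_model_prob(-Inf, 0)$posterior_prob_M1, 1)
  # monotone in the Bayes factor
  probs <- sapply(seq(-5, 15, by = 1), function(g)
    posterior_model_prob(0, g)$posterior_prob_M1)
  expect_true(all(diff(probs) > 0))
})

test_that("hit calling uses a strict threshold and reports flags separately", {
  res <- data.frame(protein_id = c("A", "B", "C"),
                    posterior_prob_M1 = c(0.999, 0.99, 0.5),
                    unreliable = c(FALSE, FALSE, TRUE))
  out <- classify_hits(res)
  expect_equal(out$hits, "A")
  expect_equal(out$flagged, "C")
  empty <- classify_hits(res[0, ])
  expect_equal(empty$hits, character(0))
})

test_that("sensitivity is the recovered fraction of the positive set", {
  expect_equal(sensitivity(c("a", "b"), c("a", "b")), 1)
  expect_equal(sensitivity(c("x"), c("a", "b")), 0)
  expect_equal(sensitivity(c("a", "c"), c("a", "b", "d", "e")), 0.25)
  expect_equal(sensitivity(c("a", "b"), c("a", "b", "c", "d")), 0.5)
  expect_error(sensitivity("a", character(0)), "non-empty")
})
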