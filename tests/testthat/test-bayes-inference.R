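# independent R-side reference for the unconstrained-scale log posterior
reference_lp <- function(family, theta, y, T, priors = prior_defaults()) {
  a <- theta[1]; b <- theta[2]; p <- theta[3]; sg <- theta[4]
  mu <- sigmoid(T, a, b, p)
  ll <- if (family == "sigmoid") {
    sum(dnorm(y, mu, sg, log = TRUE))
  } else {
    gp_marginal_loglik(y, mu, T, theta[5], theta[6], sg)
  }
  lp <- ll +
    log_pdf("gamma", priors$a, a) + log_pdf("gamma", priors$b, b) +
    log_pdf("beta", priors$p, p) + log_pdf("folded_normal", priors$sigma, sg)
  jac <- log(a) + log(b) + log(p) + log(1 - p) + log(sg)
  if (family == "semiparametric") {
    lp <- lp + log_pdf("folded_student_t", priors$v, theta[5]) +
      log_pdf("log_normal", priors$l, theta[6])
    jac <- jac + log(theta[5]) + log(theta[6])
  }
  unname(lp + jac)
}

u_of <- function(theta) {
  u <- log(theta)
  u[3] <- qlogis(theta[3])
  u
}

test_that("log posterior equals the independent prior + likelihood reference", {
  p <- make_protein(sigma = 0.04, seed = 31)
  d <- tppbayes:::block_data(p)
  for (family in c("sigmoid", "semiparametric")) {
    spec <- model_spec(family, "M0")
    set.seed(1)
    for (i in 1:5) {
      theta <- c(a = runif(1, 300, 900), b = runif(1, 5, 20),
                 p = runif(1, 0.01, 0.3), sigma = runif(1, 0.02, 0.2))
      if (family == "semiparametric")
        theta <- c(theta, v = runif(1, 0.01, 0.4), l = runif(1, 0.3, 3))
      lp <- log_posterior(spec, p, u_of(theta))$lp
      expect_equal(lp, reference_lp(family, theta, d$y, d$T), tolerance = 1e-8)
    }
  }
})

test_that("noiseless data at the truth: likelihood term is the analytic iid value", {
  truth <- c(a = 550, b = 10, p = 0.1, sigma = 0.05)
  p <- make_protein(a = 550, b = 10, p = 0.1, sigma = 1e-9, seed = 32)
  d <- tppbayes:::block_data(p)
  lp <- log_posterior(model_spec("sigmoid", "M0"), p, u_of(truth))$lp
  # subtract the prior and Jacobian computed independently: what remains is
  # the likelihood of zero residuals at sigma = 0.05
  pri <- reference_lp("sigmoid", truth, d$y, d$T) -
    sum(dnorm(d$y, sigmoid(d$T, 550, 10, 0.1), 0.05, log = TRUE))
  expect_equal(unname(lp - pri), 40 * dnorm(0, 0, 0.05, log = TRUE), tolerance = 1e-6)
})

test_that("semi-parametric posterior approaches the sigmoid one as v -> 0", {
  p <- make_protein(seed = 33)
  theta_s <- c(550, 10, 0.1, 0.05)
  for (l in c(0.5, 2)) {
    theta_sp <- c(theta_s, 1e-9, l)
    lp_sp <- log_posterior(model_spec("semiparametric", "M0"), p, u_of(theta_sp))$lp
    lp_s <- log_posterior(model_spec("sigmoid", "M0"), p, u_of(theta_s))$lp
    extra <- log_pdf("folded_student_t", prior_defaults()$v, 1e-9) +
      log_pdf("log_normal", prior_defaults()$l, l) + log(1e-9) + log(l)
    expect_equal(lp_sp, lp_s + extra, tolerance = 1e-6)
  }
})

test_that("analytic gradients match central finite differences", {
  p <- make_protein(sigma = 0.05, seed = 34)
  h <- 1e-6
  for (family in c("sigmoid", "semiparametric")) {
    spec <- model_spec(family, "M0")
    P <- spec$block_size
    set.seed(7)
    for (i in 1:10) {
      u <- rnorm(P, mean = c(6.3, 2.3, -2.5, -3, -2.5, -0.5)[1:P], sd = 0.3)
      g <- log_posterior(spec, p, u)$grad
      fd <- vapply(seq_len(P), function(j) {
        up <- u; um <- u
        up[j] <- u[j] + h; um[j] <- u[j] - h
        (log_posterior(spec, p, up)$lp - log_posterior(spec, p, um)$lp) / (2 * h)
      }, numeric(1))
      expect_equal(as.vector(g), fd, tolerance = 1e-5)
    }
  }
})

test_that("M1 log posterior is the sum of independent condition blocks", {
  p <- make_protein(shift = 3, seed = 35)
  spec1 <- model_spec("sigmoid", "M1")
  u1 <- u_of(c(550, 10, 0.1, 0.05))
  u2 <- u_of(c(580, 10, 0.12, 0.06))
  joint <- log_posterior(spec1, p, c(u1, u2))$lp
  spec0 <- model_spec("sigmoid", "M0")
  cond <- function(cc, u) {
    q <- protein_melting_data(p$protein_id, p$temperatures, p$conditions,
                              list(p$observations[[1]], p$observations[[2]]))
    d <- tppbayes:::block_data(p, cc)
    tppbayes:::lp_grad_cpp(1L, u, d$y, d$T, tppbayes:::prior_vector(prior_defaults()))$lp
  }
  expect_equal(joint, cond("vehicle", u1) + cond("treatment", u2), tolerance = 1e-10)
})

test_that("sampler reproduces a conjugate posterior and is seed-stable", {
  set.seed(13)
  yobs <- rnorm(20, 1.5, 1)
  tau2 <- 100
  post_var <- 1 / (20 + 1 / tau2)
  post_mean <- post_var * sum(yobs)
  lpg <- function(th) list(lp = -0.5 * sum((yobs - th)^2) - 0.5 * th^2 / tau2,
                           grad = sum(yobs - th) - th / tau2)
  fit <- hmc_sample(lpg, init = 0, seed = 5,
                    settings = sampler_settings(chains = 2, warmup = 400, draws = 1000))
  ess <- fit$diagnostics$ess_bulk
  mc_se <- sd(fit$draws) / sqrt(ess)
  expect_lt(abs(mean(fit$draws) - post_mean), 3 * mc_se)
  expect_equal(sd(fit$draws), sqrt(post_var), tolerance = 0.1)
  fit2 <- hmc_sample(lpg, init = 0, seed = 5,
                     settings = sampler_settings(chains = 2, warmup = 400, draws = 1000))
  expect_identical(fit$draws, fit2$draws)
})

test_that("posterior fits are reproducible under a fixed seed", {
  p <- make_protein(seed = 36)
  st <- sampler_settings(chains = 2, warmup = 300, draws = 200)
  s1 <- sample_posterior(model_spec("sigmoid", "M0"), p, seed = 9, settings = st)
  s2 <- sample_posterior(model_spec("sigmoid", "M0"), p, seed = 9, settings = st)
  expect_identical(s1$blocks[[1]]$draws, s2$blocks[[1]]$draws)
  expect_identical(s1$blocks[[1]]$lp, s2$blocks[[1]]$lp)
})

test_that("marginal credible intervals cover simulated truths", {
  # 50 simulated proteins from the sigmoid observation model; the 95%
  # marginal intervals for (a, b, p, sigma) should cover the truth at
  # roughly nominal rate
  st <- sampler_settings(chains = 2, warmup = 300, draws = 300)
  n_sim <- 50
  covered <- matrix(NA, n_sim, 4)
  set.seed(44)
  truths <- data.frame(a = runif(n_sim, 400, 900), b = runif(n_sim, 8, 16),
                       p = runif(n_sim, 0.03, 0.2), sigma = 0.05)
  truths$a <- truths$b * runif(n_sim, 46, 56)  # keep midpoints on the grid
  for (i in seq_len(n_sim)) {
    pr <- make_protein(a = truths$a[i], b = truths$b[i], p = truths$p[i],
                       sigma = truths$sigma[i], seed = 1000 + i)
    fit <- sample_posterior(model_spec("sigmoid", "M0"), pr, seed = 2000 + i,
                            settings = st, refit_on_flag = FALSE)
    th <- constrained_draws(fit)
    for (j in 1:4) {
      ci <- quantile(th[, j], c(0.025, 0.975))
      covered[i, j] <- truths[i, j] >= ci[1] && truths[i, j] <= ci[2]
    }
  }
  expect_gte(mean(covered), 0.9)
})

test_that("mean function bands are nested and degenerate draws collapse them", {
  p <- make_protein(seed = 37)
  st <- sampler_settings(chains = 2, warmup = 300, draws = 200)
  fit <- sample_posterior(model_spec("sigmoid", "M1"), p, seed = 11, settings = st)
  bands <- mean_function_bands(fit, p)
  for (cc in p$conditions) {
    b <- bands$bands[[cc]]
    expect_true(all(b$lower_95 <= b$lower_5 + 1e-12))
    expect_true(all(b$upper_5 <= b$upper_95 + 1e-12))
    expect_true(all(b$lower_5 <= b$median + 1e-12 & b$median <= b$upper_5 + 1e-12))
  }
  # degenerate: replicate a single draw
  fit$blocks <- lapply(fit$blocks, function(bl) {
    bl$draws <- bl$draws[rep(1L, 50L), , drop = FALSE]
    bl$lp <- rep(bl$lp[1L], 50L)
    bl
  })
  flat <- mean_function_bands(fit, p)
  for (cc in p$conditions) {
    b <- flat$bands[[cc]]
    expect_equal(b$lower_95, b$upper_95, tolerance = 1e-12)
    th <- tppbayes:::constrain_block(fit$blocks[[match(cc, p$conditions)]]$draws[1, , drop = FALSE])
    expect_equal(b$median, sigmoid(flat$T_grid, th[1], th[2], th[3]),
                 tolerance = 1e-10)
  }
})
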