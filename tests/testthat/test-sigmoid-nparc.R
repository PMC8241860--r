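test_that("sigmoid curve has the advertised shape", {
  # at T = a/b the exponent vanishes and S = (1+p)/2
  expect_equal(sigmoid(55, 550, 10, 0.1), 0.55)
  expect_equal(sigmoid(40, 400, 10, 0.2), 0.6)
  # T -> 0+ approaches 1
  expect_equal(sigmoid(1e-4, 550, 10, 0.1), 1, tolerance = 1e-12)
  # strictly decreasing in T for a > 0, values in (p, 1)
  Tg <- seq(20, 90, by = 0.5)
  s <- sigmoid(Tg, 1000, 20, 0.05)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0.05 & s < 1))
  # direct high-precision evaluation of the closed form
  a <- 1000; b <- 20; p <- 0.05; T <- 60
  expect_equal(sigmoid(T, a, b, p), (1 - p) / (1 + exp(b - a / T)) + p,
               tolerance = 1e-15)
  expect_error(sigmoid(c(50, -3), 550, 10, 0.1), "positive")
})

test_that("least-squares fit recovers noiseless sigmoid parameters", {
  p <- make_protein(a = 620, b = 12, p = 0.08, sigma = 1e-12, seed = 3)
  fit <- fit_sigmoid_ls(p, "M0")
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-12)
  expect_equal(unname(fit$params), c(620, 12, 0.08), tolerance = 1e-4)
})

test_that("identical conditions make the nested fits equivalent", {
  p <- make_protein(shift = 0, sigma = 0.03, seed = 4)
  f0 <- fit_sigmoid_ls(p, "M0")
  f1 <- fit_sigmoid_ls(p, "M1")
  expect_equal(f1$rss, f0$rss, tolerance = 0.05)
  expect_lte(f1$rss, f0$rss + 1e-8)
})

test_that("a shifted curve separates the nested residual sums", {
  p <- make_protein(shift = 4, sigma = 0.03, seed = 5)
  f0 <- fit_sigmoid_ls(p, "M0")
  f1 <- fit_sigmoid_ls(p, "M1")
  # improvement well beyond the noise floor (3 x n sigma^2)
  expect_gt(f0$rss - f1$rss, 3 * 40 * 0.03^2)
})

test_that("nesting inequality holds across simulated proteins", {
  sim <- simulate_dataset(10, c(null_sigmoid = 0.5, shifted_sigmoid = 0.3,
                                biphasic = 0.2), seed = 8)
  for (p in sim$dataset$proteins) {
    f0 <- fit_sigmoid_ls(p, "M0")
    f1 <- fit_sigmoid_ls(p, "M1")
    if (f0$converged && f1$converged) expect_lte(f1$rss, f0$rss + 1e-6)
  }
})

test_that("F statistic arithmetic", {
  expect_equal(nparc_f_statistic(1, 1, 2, 4), 0)
  expect_equal(nparc_f_statistic(3, 1, 2, 4), 4)
  expect_equal(nparc_f_statistic(2, 1, 5, 5), 1)
  expect_error(nparc_f_statistic(3, 0, 2, 4), "degenerate")
  expect_error(nparc_f_statistic(3, 1, 0, 4), "positive")
})

test_that("effective degrees of freedom are recovered from true F samples", {
  for (dof in list(c(4, 32), c(2, 10))) {
    set.seed(2 * dof[1])
    x <- rf(5000, dof[1], dof[2])
    est <- estimate_effective_dof(x, trim = 0)
    expect_equal(est$d1_eff, dof[1], tolerance = 0.2)
    # the denominator dof is weakly identified by the tail; require the
    # fitted null to be correct where it matters - the p-values it implies
    expect_gt(est$d2_eff, dof[2] / 2)
    expect_lt(est$d2_eff, dof[2] * 2)
    pv <- nparc_pvalues(x, est$d1_eff, est$d2_eff)$p_values
    expect_lt(suppressWarnings(ks.test(pv, "punif"))$statistic, 0.02)
  }
})

test_that("effective-dof fit rejects unusable input", {
  expect_error(estimate_effective_dof(rf(50, 3, 10)), "at least 100")
  expect_error(estimate_effective_dof(rep(2, 500)), "identical")
})

test_that("p-values and BH adjustment behave", {
  pv <- nparc_pvalues(0, 3, 30)
  expect_equal(pv$p_values, 1)
  # hand-computed step-up values for a 5-element vector
  d <- c(2, 3)
  F5 <- qf(1 - c(0.005, 0.011, 0.02, 0.04, 0.9), d[1], d[2])
  adj <- nparc_pvalues(F5, d[1], d[2])$p_adjusted
  expect_equal(adj, c(0.025, 0.0275, 1 / 30, 0.05, 0.9), tolerance = 1e-6)
  # equal p in, equal adjusted out
  same <- nparc_pvalues(rep(2.5, 4), 3, 30)$p_adjusted
  expect_true(all(same == same[1]))
})

test_that("residual correlations: diagonal, symmetry, null and AR(1) structure", {
  set.seed(101)
  D <- 10
  iid <- matrix(rnorm(1000 * D), 1000, D)
  R <- residual_correlation_matrix(iid)
  expect_equal(diag(R), rep(1, D), ignore_attr = TRUE)
  expect_equal(R, t(R))
  expect_lt(max(abs(R[upper.tri(R)])), 0.1)

  ar1 <- t(replicate(1000, as.vector(arima.sim(list(ar = 0.8), D))))
  Rar <- residual_correlation_matrix(ar1)
  adj <- mean(Rar[cbind(1:(D - 1), 2:D)])
  lag3 <- mean(Rar[cbind(1:(D - 3), 4:D)])
  expect_gt(adj, lag3)
  expect_error(residual_correlation_matrix(iid[1:2, ]), "fewer than 3")
})

test_that("residual matrix from fits feeds the correlation analysis", {
  sim <- simulate_dataset(8, c(null_sigmoid = 1), seed = 12)
  rm <- residual_matrix(sim$dataset)
  expect_equal(ncol(rm), 10L)
  expect_equal(nrow(rm), 16L)  # protein x condition rows
  R <- residual_correlation_matrix(rm)
  expect_equal(dim(R), c(10L, 10L))
  expect_true(all(abs(R) <= 1 + 1e-12))
})

test_that("dataset-level NPARC analysis returns calibrated null p-values", {
  sim <- simulate_dataset(120, c(null_sigmoid = 0.9, shifted_sigmoid = 0.1),
                          seed = 31)
  res <- nparc_analysis(sim$dataset)
  expect_equal(nrow(res), 120L)
  m <- merge(res, sim$truth, by = "protein_id")
  # p-values of null proteins roughly uniform: median near 0.5
  pnull <- m$nparc_p[!m$treatment_affected]
  expect_gt(median(pnull, na.rm = TRUE), 0.2)
  expect_lt(median(pnull, na.rm = TRUE), 0.8)
  # affected proteins rank lower in p than nulls on average
  expect_lt(median(m$nparc_p[m$treatment_affected], na.rm = TRUE),
            median(pnull, na.rm = TRUE))
})
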