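#' Squared-exponential covariance matrix
#'
#' `C[i, j] = v^2 * exp(-(T_i - T_j)^2 / (2 l^2))`. `T_vec` is typically the
#' concatenation of each replicate's temperature grid, so replicate copies at
#' equal temperatures share the full covariance `v^2`: the GP deviation term
#' is one function realization per condition, shared across replicates.
#'
#' @param T_vec finite numeric vector of temperatures (degrees Celsius).
#' @param v marginal standard deviation (solubility units), `>= 0`.
#' @param l length-scale (degrees Celsius), `> 0`.
#' @return symmetric positive semi-definite matrix with diagonal `v^2`.
#' @export
se_covariance <- function(T_vec, v, l) {
  if (l <= 0) stop("length-scale must be positive")
  if (v < 0) stop("marginal standard deviation must be non-negative")
  if (any(!is.finite(T_vec))) stop("temperatures must be finite")
  d <- outer(T_vec, T_vec, "-")
  v^2 * exp(-d^2 / (2 * l^2))
}

# Cholesky with the escalating jitter policy: add 1e-10 * v^2 to the diagonal,
# escalating x10 at most 3 times; failures raise.
chol_jitter <- function(K, v) {
  R <- tryCatch(chol(K), error = function(e) NULL)
  jit <- 1e-10 * max(v^2, 1e-12)
  tries <- 0L
  while (is.null(R) && tries < 3L) {
    R <- tryCatch(chol(K + jit * diag(nrow(K))), error = function(e) NULL)
    if (is.null(R)) {
      jit <- jit * 10
      tries <- tries + 1L
    } else {
      message(sprintf("covariance factorization needed jitter %.1e", jit))
    }
  }
  if (is.null(R)) stop("covariance matrix not positive definite after jitter escalation")
  R
}

#' GP-marginalized Gaussian log-likelihood
#'
#' Log density of `y ~ N(mean, C + sigma^2 I)` with `C` the
#' squared-exponential covariance over `T_vec`: the likelihood of the
#' semi-parametric melting model after marginalizing the GP deviation term.
#' With `v = 0` it reduces to the sum of independent normal log densities.
#'
#' @param y observations (concatenated replicates).
#' @param mean_vec mean (the sigmoid curve evaluated at `T_vec`).
#' @param T_vec temperatures, same length as `y`.
#' @param v,l GP hyperparameters (see [se_covariance()]).
#' @param sigma residual standard deviation, `> 0`.
#' @return scalar log density.
#' @export
gp_marginal_loglik <- function(y, mean_vec, T_vec, v, l, sigma) {
  n <- length(y)
  stopifnot(length(mean_vec) == n, length(T_vec) == n, sigma > 0)
  K <- se_covariance(T_vec, v, l) + sigma^2 * diag(n)
  R <- chol_jitter(K, v)
  r <- y - mean_vec
  alpha <- backsolve(R, forwardsolve(t(R), r))
  -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(r * alpha)
}

#' Posterior conditional mean of the GP deviation term
#'
#' `E[mu(T_grid) | y] = C(T_grid, T) (C + sigma^2 I)^{-1} (y - mean)`: the
#' inferred non-parametric deviation from the sigmoid, evaluated on a grid.
#' Zero everywhere when `v = 0` or when the residuals vanish.
#'
#' @inheritParams gp_marginal_loglik
#' @param T_grid temperatures at which to evaluate the conditional mean.
#' @return numeric vector of length `length(T_grid)`.
#' @export
gp_conditional_mean <- function(y, mean_vec, T_vec, v, l, sigma, T_grid = T_vec) {
  n <- length(y)
  stopifnot(length(mean_vec) == n, length(T_vec) == n, sigma > 0)
  if (v == 0) return(rep(0, length(T_grid)))
  K <- se_covariance(T_vec, v, l) + sigma^2 * diag(n)
  R <- chol_jitter(K, v)
  alpha <- backsolve(R, forwardsolve(t(R), y - mean_vec))
  Kx <- v^2 * exp(-outer(T_grid, T_vec, "-")^2 / (2 * l^2))
  as.vector(Kx %*% alpha)
}

#' Reduced-rank GP marginal log-likelihood
#'
#' Hilbert-space basis approximation of [gp_marginal_loglik()]: the
#' squared-exponential kernel is approximated by `m_basis` Laplacian
#' eigenfunctions on a symmetric domain extending `boundary_factor` times the
#' centred data half-range, weighted by the kernel's spectral density. The
#' approximation converges to the dense value as `m_basis` grows. Provided as
#' an optional backend; the dense path is exact and cheap at per-protein sizes.
#'
#' @inheritParams gp_marginal_loglik
#' @param m_basis number of basis functions, `>= 4`.
#' @param boundary_factor domain expansion factor, `> 1`.
#' @return scalar approximate log density.
#' @export
reduced_rank_loglik <- function(y, mean_vec, T_vec, v, l, sigma,
                                m_basis = 32L, boundary_factor = 2) {
  if (m_basis < 4L) stop("m_basis must be at least 4")
  if (boundary_factor <= 1) stop("boundary_factor must exceed 1")
  n <- length(y)
  stopifnot(length(mean_vec) == n, length(T_vec) == n, sigma > 0)
  ctr <- mean(range(T_vec))
  L <- boundary_factor * max(max(abs(T_vec - ctr)), 1e-6)
  x <- T_vec - ctr
  j <- seq_len(m_basis)
  sqrt_lambda <- pi * j / (2 * L)
  Phi <- sapply(j, function(jj) sin(pi * jj * (x + L) / (2 * L)) / sqrt(L))
  # spectral density of the squared-exponential kernel at the eigenfrequencies
  s_j <- v^2 * l * sqrt(2 * pi) * exp(-0.5 * (l * sqrt_lambda)^2)
  K <- Phi %*% (s_j * t(Phi)) + sigma^2 * diag(n)
  R <- chol_jitter(K, v)
  r <- y - mean_vec
  alpha <- backsolve(R, forwardsolve(t(R), r))
  -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(r * alpha)
}
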