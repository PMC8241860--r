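#' Prior families used by the melting-curve models
#'
#' The Bayesian sigmoid and semi-parametric models use five prior families:
#' gamma (shape/rate) for the sigmoid shape parameters, beta for the plateau,
#' a folded normal for the residual standard deviation, a folded Student-t for
#' the GP marginal standard deviation and a log-normal for the GP length-scale.
#' `log_pdf()` evaluates the normalized log density of any of these families;
#' `sample_prior()` draws from them.
#'
#' Parameter conventions: the gamma family is parameterized by `shape` and
#' `rate` (so `Gamma(7, 0.01)` has mean 700); the folded normal and folded
#' Student-t take a `location` and a standard-deviation-like `scale` (plus `df`
#' for the t); the log-normal takes `meanlog`/`sdlog`.
#'
#' @param family one of `"gamma"`, `"beta"`, `"folded_normal"`,
#'   `"folded_student_t"`, `"log_normal"`.
#' @param params named list of parameters for the family (see Details).
#' @param x numeric vector of evaluation points.
#' @return `log_pdf()`: numeric vector of log densities; points outside the
#'   support evaluate to `-Inf` rather than raising an error, so samplers can
#'   treat them as rejections.
#'
#' @details Required parameters per family:
#' \describe{
#'   \item{gamma}{`shape`, `rate`}
#'   \item{beta}{`alpha`, `beta`}
#'   \item{folded_normal}{`location`, `scale`}
#'   \item{folded_student_t}{`df`, `location`, `scale`}
#'   \item{log_normal}{`meanlog`, `sdlog`}
#' }
#'
#' @examples
#' log_pdf("beta", list(alpha = 1, beta = 20), 0)    # log(20)
#' log_pdf("folded_normal", list(location = 0, scale = 0.05), 0)
#' @export
log_pdf <- function(family, params, x) {
  family <- match.arg(family, prior_families())
  pr <- function(name) {
    val <- params[[name]]
    if (is.null(val)) stop(sprintf("missing parameter '%s' for family '%s'", name, family))
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop(sprintf("parameter '%s' must be a finite number", name))
    val
  }
  out <- rep(-Inf, length(x))
  switch(family,
    gamma = {
      shape <- pr("shape"); rate <- pr("rate")
      if (shape <= 0 || rate <= 0) stop("gamma shape and rate must be positive")
      ok <- x > 0
      out[ok] <- dgamma(x[ok], shape = shape, rate = rate, log = TRUE)
    },
    beta = {
      a <- pr("alpha"); b <- pr("beta")
      if (a <= 0 || b <= 0) stop("beta parameters must be positive")
      ok <- x > 0 & x < 1
      out[ok] <- dbeta(x[ok], a, b, log = TRUE)
      # dbeta(0; 1, b) is finite; keep the closed boundary where defined
      if (a >= 1) {
        z <- x == 0
        out[z] <- dbeta(0, a, b, log = TRUE)
      }
      if (b >= 1) {
        z <- x == 1
        out[z] <- dbeta(1, a, b, log = TRUE)
      }
    },
    folded_normal = {
      m <- pr("location"); s <- pr("scale")
      if (s <= 0) stop("folded normal scale must be positive")
      ok <- x >= 0
      out[ok] <- log(dnorm(x[ok], m, s) + dnorm(x[ok], -m, s))
    },
    folded_student_t = {
      nu <- pr("df"); m <- pr("location"); s <- pr("scale")
      if (s <= 0 || nu <= 0) stop("folded t scale and df must be positive")
      ok <- x >= 0
      out[ok] <- log(dt((x[ok] - m) / s, nu) / s + dt((x[ok] + m) / s, nu) / s)
    },
    log_normal = {
      mu <- pr("meanlog"); s <- pr("sdlog")
      if (s <= 0) stop("log-normal sdlog must be positive")
      ok <- x > 0
      out[ok] <- dlnorm(x[ok], mu, s, log = TRUE)
    }
  )
  out
}

#' @rdname log_pdf
#' @param n number of draws.
#' @param seed optional integer seed; if supplied the draw is reproducible.
#' @return `sample_prior()`: numeric vector of `n` draws.
#' @export
sample_prior <- function(family, params, n, seed = NULL) {
  family <- match.arg(family, prior_families())
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  # parameter validation shared with the density
  invisible(log_pdf(family, params, numeric(0)))
  switch(family,
    gamma = rgamma(n, shape = params$shape, rate = params$rate),
    beta = rbeta(n, params$alpha, params$beta),
    folded_normal = abs(rnorm(n, params$location, params$scale)),
    folded_student_t = abs(params$location + params$scale * rt(n, params$df)),
    log_normal = rlnorm(n, params$meanlog, params$sdlog)
  )
}

prior_families <- function() {
  c("gamma", "beta", "folded_normal", "folded_student_t", "log_normal")
}
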