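#' Default priors for the melting-curve models
#'
#' Gamma(7, rate 0.01) on `a` and Gamma(7, rate 0.4) on `b` keep the sigmoid
#' shape parameters positive with soft upper tails; Beta(1, 20) on the plateau
#' `p` reflects plateaus close to 0; a folded normal with scale 0.05 shrinks
#' the residual standard deviation towards 0; a folded Student-t(3) with
#' scale 0.5 shrinks the GP marginal standard deviation `v` while keeping
#' heavy tails; and a log-normal(-0.5, 0.5) on the length-scale `l`
#' discourages both data-interpolating short and uninformative long
#' length-scales. The gamma rate convention means `a` has prior mean 700.
#'
#' @return named list of prior specifications (one per parameter), each a
#'   list with a `family` and its parameters, evaluable by [log_pdf()].
#' @export
prior_defaults <- function() {
  list(
    a = list(family = "gamma", shape = 7, rate = 0.01),
    b = list(family = "gamma", shape = 7, rate = 0.4),
    p = list(family = "beta", alpha = 1, beta = 20),
    sigma = list(family = "folded_normal", location = 0, scale = 0.05),
    v = list(family = "folded_student_t", df = 3, location = 0, scale = 0.5),
    l = list(family = "log_normal", meanlog = -0.5, sdlog = 0.5))
}

# hyperparameter vector consumed by the compiled posteriors; families on the
# fast path are fixed to the defaults, values are configurable
prior_vector <- function(priors) {
  fams <- vapply(priors[c("a", "b", "p", "sigma", "v", "l")],
                 function(x) x$family, character(1))
  expected <- c(a = "gamma", b = "gamma", p = "beta", sigma = "folded_normal",
                v = "folded_student_t", l = "log_normal")
  if (!identical(unname(fams), unname(expected)))
    stop("the sampling fast path supports only the default prior families; ",
         "hyperparameter values are configurable")
  if (priors$sigma$location != 0 || priors$v$location != 0)
    stop("folded priors on the fast path must have location 0")
  c(priors$a$shape, priors$a$rate, priors$b$shape, priors$b$rate,
    priors$p$alpha, priors$p$beta, priors$sigma$scale,
    priors$v$df, priors$v$scale, priors$l$meanlog, priors$l$sdlog)
}

#' Model specification
#'
#' Identifies one of the four model variants: sigmoid or semi-parametric
#' family, shared-curve (`"M0"`) or condition-specific (`"M1"`) hypothesis.
#' Parameter blocks: sigmoid `(a, b, p, sigma)`; semi-parametric adds the GP
#' hyperparameters `(v, l)`. Under `M1` each condition carries its own block
#' and the joint posterior factorizes across conditions.
#'
#' @param family `"sigmoid"` or `"semiparametric"`.
#' @param hypothesis `"M0"` or `"M1"`.
#' @param priors prior list as from [prior_defaults()].
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("sigmoid", "semiparametric"),
                       hypothesis = c("M0", "M1"),
                       priors = prior_defaults()) {
  family <- match.arg(family)
  hypothesis <- match.arg(hypothesis)
  block_names <- if (family == "sigmoid") c("a", "b", "p", "sigma")
                 else c("a", "b", "p", "sigma", "v", "l")
  missing_pr <- setdiff(block_names, names(priors))
  if (length(missing_pr) > 0)
    stop("priors missing for: ", paste(missing_pr, collapse = ", "))
  structure(list(family = family, hypothesis = hypothesis, priors = priors,
                 block_names = block_names,
                 block_size = length(block_names),
                 n_params = length(block_names) *
                   (if (hypothesis == "M1") 2L else 1L),
                 model_code = if (family == "sigmoid") 1L else 2L),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s / %s (%d parameters)\n",
              x$family, x$hypothesis, x$n_params))
  invisible(x)
}

# concatenated (y, T) for one condition (or both, condition = NULL),
# replicate-major so replicate copies at equal temperatures are adjacent
block_data <- function(protein, condition = NULL) {
  conds <- if (is.null(condition)) protein$conditions else condition
  ys <- Ts <- list()
  for (cc in conds) {
    m <- protein$observations[[cc]]
    for (k in seq_len(nrow(m))) {
      ys[[length(ys) + 1L]] <- m[k, ]
      Ts[[length(Ts) + 1L]] <- protein$temperatures
    }
  }
  y <- unlist(ys, use.names = FALSE)
  T <- unlist(Ts, use.names = FALSE)
  if (anyNA(y)) stop(sprintf("protein %s has missing cells; excluded from model fitting",
                             protein$protein_id))
  list(y = y, T = T)
}

# unconstrained <-> constrained transforms for one parameter block
constrain_block <- function(U) {
  U <- rbind(U)
  out <- exp(U)
  out[, 3L] <- stats::plogis(U[, 3L])
  out
}

unconstrain_block <- function(theta) {
  u <- log(theta)
  u[3L] <- stats::qlogis(theta[3L])
  u
}

#' Log posterior density and gradient
#'
#' Evaluates the unnormalized log posterior of a model variant on the
#' unconstrained scale (`log` for positive parameters, `logit` for the
#' plateau, change-of-variables terms included) together with its analytic
#' gradient. Under `M1`, `theta_u` is the concatenation of the two condition
#' blocks and the log posterior is the sum of the independent per-condition
#' terms.
#'
#' @param spec a [model_spec].
#' @param protein a complete [protein_melting_data].
#' @param theta_u numeric vector of unconstrained parameters (length
#'   `spec$n_params`).
#' @return list with `lp` (scalar) and `grad` (vector).
#' @export
log_posterior <- function(spec, protein, theta_u) {
  stopifnot(inherits(spec, "model_spec"), length(theta_u) == spec$n_params)
  pv <- prior_vector(spec$priors)
  if (spec$hypothesis == "M0") {
    d <- block_data(protein)
    return(lp_grad_cpp(spec$model_code, theta_u, d$y, d$T, pv))
  }
  P <- spec$block_size
  lp <- 0
  grad <- numeric(2L * P)
  for (i in 1:2) {
    idx <- ((i - 1L) * P + 1L):(i * P)
    d <- block_data(protein, protein$conditions[i])
    r <- lp_grad_cpp(spec$model_code, theta_u[idx], d$y, d$T, pv)
    lp <- lp + r$lp
    grad[idx] <- r$grad
  }
  list(lp = lp, grad = grad)
}
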