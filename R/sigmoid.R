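#' Three-parameter sigmoid melting model
#'
#' `S(T) = (1 - p) / (1 + exp(b - a/T)) + p`. The plateau `p` is the lower
#' asymptote as `T` grows; `a` and `b` are shape parameters, and for `a > 0`
#' the curve decreases strictly in `T`, crossing `(1 + p) / 2` at `T = a / b`.
#'
#' @param T temperatures in degrees Celsius, all `> 0`.
#' @param a,b shape parameters, `> 0`.
#' @param p plateau, in `(0, 1)` (0 allowed for least-squares fits).
#' @return numeric vector of relative solubilities in `(p, 1)`.
#' @export
sigmoid <- function(T, a, b, p) {
  if (any(T <= 0)) stop("temperatures must be positive")
  (1 - p) / (1 + exp(b - a / T)) + p
}

default_ls_starts <- function() {
  starts <- expand.grid(a = c(200, 550, 1200), b = c(5, 10, 20))
  starts$p <- 0.05
  starts
}

# least-squares fit of one parameter set to stacked (T, y) observations
fit_sigmoid_block_ls <- function(T, y, starts = default_ls_starts()) {
  keep <- !is.na(y)
  T <- T[keep]; y <- y[keep]
  if (length(unique(T)) < 4L) {
    return(list(params = c(a = NA, b = NA, p = NA), rss = NA_real_,
                residuals = rep(NA_real_, length(y)), converged = FALSE,
                n_obs = length(y)))
  }
  resid_fun <- function(par) y - sigmoid(T, par[1L], par[2L], par[3L])
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = as.numeric(starts[i, c("a", "b", "p")]), fn = resid_fun,
        lower = c(1e-6, 1e-6, 0), upper = c(1e7, 1e4, 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(params = c(a = fit$par[1L], b = fit$par[2L], p = fit$par[3L]),
                   rss = rss, residuals = -fit$fvec, converged = TRUE,
                   n_obs = length(y))
    }
  }
  if (is.null(best)) {
    return(list(params = c(a = NA, b = NA, p = NA), rss = NA_real_,
                residuals = rep(NA_real_, length(y)), converged = FALSE,
                n_obs = length(y)))
  }
  best
}

#' Least-squares sigmoid fit for a protein
#'
#' Fits the 3-parameter sigmoid by multi-start Levenberg-Marquardt least
#' squares. Under the shared-curve hypothesis (`"M0"`) one parameter set is
#' fit to both conditions' stacked replicates; under the condition-specific
#' hypothesis (`"M1"`) each condition gets its own parameters (the `M0`
#' solution is added to the start grid of each condition, so the nested fit
#' can never do worse than the pooled one up to optimizer tolerance).
#' Non-convergence from every start flags the fit rather than raising.
#'
#' @param protein a [protein_melting_data].
#' @param model `"M0"` (shared curve) or `"M1"` (per-condition curves).
#' @param starts data frame of `(a, b, p)` starting points.
#' @return list with `params` (single vector for M0; per-condition list for
#'   M1), `rss`, `residuals` (per condition, replicate-major), `converged`,
#'   `n_obs`, `n_params`.
#' @export
fit_sigmoid_ls <- function(protein, model = c("M0", "M1"),
                           starts = default_ls_starts()) {
  model <- match.arg(model)
  stopifnot(inherits(protein, "protein_melting_data"))
  stacked <- lapply(protein$conditions, function(cc) {
    m <- protein$observations[[cc]]
    list(T = rep(protein$temperatures, times = nrow(m)), y = as.vector(t(m)))
  })
  names(stacked) <- protein$conditions

  if (model == "M0") {
    fit <- fit_sigmoid_block_ls(do.call(c, lapply(stacked, `[[`, "T")),
                                do.call(c, lapply(stacked, `[[`, "y")), starts)
    n1 <- sum(!is.na(stacked[[1L]]$y))
    res <- list(params = fit$params, rss = fit$rss,
                residuals = list(fit$residuals[seq_len(n1)],
                                 fit$residuals[-seq_len(n1)]),
                converged = fit$converged, n_obs = fit$n_obs, n_params = 3L)
    names(res$residuals) <- protein$conditions
    return(res)
  }

  m0 <- fit_sigmoid_ls(protein, "M0", starts)
  starts1 <- starts
  if (m0$converged)
    starts1 <- rbind(starts, as.data.frame(as.list(m0$params)))
  fits <- lapply(stacked, function(s) fit_sigmoid_block_ls(s$T, s$y, starts1))
  list(params = lapply(fits, `[[`, "params"),
       rss = sum(vapply(fits, `[[`, numeric(1), "rss")),
       residuals = lapply(fits, `[[`, "residuals"),
       converged = all(vapply(fits, `[[`, logical(1), "converged")),
       n_obs = sum(vapply(fits, `[[`, numeric(1), "n_obs")),
       n_params = 6L)
}
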