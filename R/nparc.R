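#' NPARC F statistic
#'
#' Compares the shared-curve and condition-specific least-squares fits:
#' `F = (d2 / d1) * (RSS0 - RSS1) / RSS1`.
#'
#' @param rss0,rss1 residual sums of squares of the null (shared) and
#'   alternative (condition-specific) fits.
#' @param d1,d2 degrees of freedom (numerator, denominator).
#' @return the F statistic.
#' @export
nparc_f_statistic <- function(rss0, rss1, d1, d2) {
  if (any(d1 <= 0) || any(d2 <= 0)) stop("degrees of freedom must be positive")
  if (any(rss1 <= 0)) stop("rss1 must be positive (degenerate perfect fit)")
  (d2 / d1) * (rss0 - rss1) / rss1
}

#' Estimate effective degrees of freedom for the NPARC null
#'
#' TPP residuals are correlated, so the counting degrees of freedom misstate
#' the null distribution of the F statistic. Following the empirical-null
#' idea, an `F(d1_eff, d2_eff)` distribution is fit to the observed statistics
#' by maximum likelihood. Because treatment-affected proteins inflate the
#' upper tail, the likelihood is (by default) truncated at the empirical
#' `1 - trim` quantile and only statistics below it enter, with the proper
#' truncated-density normalization so the estimate stays consistent. This is
#' an approximation to the original NPARC scheme, which is defined in its own
#' reference implementation.
#'
#' @param F_values vector of F statistics (non-finite entries dropped);
#'   at least 100 required.
#' @param trim upper tail fraction excluded from the fit (default 0.05);
#'   0 disables trimming.
#' @return list with `d1_eff`, `d2_eff`, `converged`.
#' @export
estimate_effective_dof <- function(F_values, trim = 0.05) {
  F_values <- F_values[is.finite(F_values)]
  # the F density is supported on (0, inf); exact zeros carry no information
  F_values <- F_values[F_values > 0]
  if (length(F_values) < 100L) stop("need at least 100 finite F statistics")
  if (sd(F_values) == 0) stop("all F statistics identical")
  cutoff <- if (trim > 0) quantile(F_values, 1 - trim, names = FALSE) else Inf
  x <- F_values[F_values <= cutoff]

  negll <- function(logd) {
    d1 <- exp(logd[1L]); d2 <- exp(logd[2L])
    ll <- sum(df(x, d1, d2, log = TRUE))
    if (is.finite(cutoff)) ll <- ll - length(x) * pf(cutoff, d1, d2, log.p = TRUE)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- list(c(log(2), log(10)), c(log(4), log(30)), c(log(8), log(80)))
  lower <- c(log(0.5), log(2))
  upper <- c(log(100), log(1000))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(optim(s, negll, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("effective degrees-of-freedom fit failed")
  list(d1_eff = exp(best$par[1L]), d2_eff = exp(best$par[2L]),
       converged = best$convergence == 0)
}

#' NPARC p-values with Benjamini-Hochberg correction
#'
#' @param F_values F statistics.
#' @param d1_eff,d2_eff effective degrees of freedom (see
#'   [estimate_effective_dof()]).
#' @return list with `p_values` and `p_adjusted` (BH step-up).
#' @export
nparc_pvalues <- function(F_values, d1_eff, d2_eff) {
  if (d1_eff <= 0 || d2_eff <= 0) stop("degrees of freedom must be positive")
  p <- pf(F_values, d1_eff, d2_eff, lower.tail = FALSE)
  list(p_values = p, p_adjusted = p.adjust(p, method = "BH"))
}

#' Per-protein replicate-mean residual matrix
#'
#' Residuals of the condition-specific least-squares sigmoid fits, averaged
#' over replicates at each temperature. Rows are protein-condition pairs,
#' columns temperatures; proteins with flagged (non-converged) fits are
#' excluded.
#'
#' @param ds a [tpp_dataset] on a common temperature grid.
#' @param fits optional named list of `fit_sigmoid_ls(p, "M1")` results keyed
#'   by protein id; computed if missing.
#' @return numeric matrix (protein-condition rows x D temperatures).
#' @export
residual_matrix <- function(ds, fits = NULL) {
  stopifnot(inherits(ds, "tpp_dataset"), !ds$ragged)
  if (is.null(fits))
    fits <- lapply(ds$proteins, fit_sigmoid_ls, model = "M1")
  rows <- list()
  for (id in names(ds$proteins)) {
    p <- ds$proteins[[id]]
    f <- fits[[id]]
    if (is.null(f) || !isTRUE(f$converged)) next
    for (cc in p$conditions) {
      m <- p$observations[[cc]]
      curve <- sigmoid(p$temperatures, f$params[[cc]]["a"], f$params[[cc]]["b"],
                       f$params[[cc]]["p"])
      res <- sweep(m, 2L, curve)
      rows[[paste(id, cc, sep = ".")]] <- colMeans(res, na.rm = TRUE)
    }
  }
  if (length(rows) < 3L) stop("fewer than 3 proteins with converged fits")
  do.call(rbind, rows)
}

#' Spearman correlation matrix of residuals across temperatures
#'
#' Entry `(j, j')` is the Spearman correlation, across proteins, between the
#' replicate-mean residuals at temperatures `j` and `j'`. Correlated residuals
#' at nearby temperatures indicate structure the independent-error sigmoid
#' model does not capture.
#'
#' @param resid_mat matrix from [residual_matrix()] (rows proteins, columns
#'   temperatures), or a [tpp_dataset] (the matrix is then computed).
#' @return symmetric `D x D` correlation matrix with unit diagonal.
#' @export
residual_correlation_matrix <- function(resid_mat) {
  if (inherits(resid_mat, "tpp_dataset")) resid_mat <- residual_matrix(resid_mat)
  if (nrow(resid_mat) < 3L) stop("fewer than 3 proteins")
  cor(resid_mat, method = "spearman", use = "pairwise.complete.obs")
}

#' NPARC analysis of a dataset
#'
#' Fits shared and condition-specific sigmoids to every complete protein,
#' computes the F statistic with counting degrees of freedom
#' (`d1 = 3`, `d2 = n_obs - 6` for the two-condition design), estimates
#' effective degrees of freedom across proteins, and returns p-values with BH
#' correction. With fewer proteins than the effective-dof minimum the
#' counting degrees of freedom are used and flagged.
#'
#' @param ds a [tpp_dataset].
#' @param trim tail fraction passed to [estimate_effective_dof()].
#' @return data frame with columns `protein_id`, `nparc_F`, `nparc_p`,
#'   `nparc_p_adj`, `converged`, plus attributes `d1_eff`, `d2_eff`,
#'   `dof_method`.
#' @export
nparc_analysis <- function(ds, trim = 0.05) {
  stopifnot(inherits(ds, "tpp_dataset"))
  ids <- names(ds$proteins)
  rows <- lapply(ids, function(id) {
    p <- ds$proteins[[id]]
    if (!is_complete(p))
      return(data.frame(protein_id = id, nparc_F = NA_real_, d1 = NA_real_,
                        d2 = NA_real_, converged = FALSE))
    f0 <- fit_sigmoid_ls(p, "M0")
    f1 <- fit_sigmoid_ls(p, "M1")
    if (!f0$converged || !f1$converged || !is.finite(f1$rss) || f1$rss <= 0)
      return(data.frame(protein_id = id, nparc_F = NA_real_, d1 = NA_real_,
                        d2 = NA_real_, converged = FALSE))
    d1 <- f1$n_params - f0$n_params
    d2 <- f0$n_obs - f1$n_params
    Fv <- nparc_f_statistic(max(f0$rss, f1$rss), f1$rss, d1, d2)
    data.frame(protein_id = id, nparc_F = Fv, d1 = d1, d2 = d2,
               converged = TRUE)
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$nparc_F)
  dof_method <- "effective"
  dof <- tryCatch(estimate_effective_dof(tab$nparc_F[ok], trim = trim),
                  error = function(e) NULL)
  if (is.null(dof)) {
    dof <- list(d1_eff = tab$d1[ok][1L], d2_eff = tab$d2[ok][1L])
    dof_method <- "counting"
  }
  pv <- nparc_pvalues(tab$nparc_F[ok], dof$d1_eff, dof$d2_eff)
  tab$nparc_p <- NA_real_
  tab$nparc_p_adj <- NA_real_
  tab$nparc_p[ok] <- pv$p_values
  tab$nparc_p_adj[ok] <- pv$p_adjusted
  tab$d1 <- tab$d2 <- NULL
  attr(tab, "d1_eff") <- dof$d1_eff
  attr(tab, "d2_eff") <- dof$d2_eff
  attr(tab, "dof_method") <- dof_method
  tab
}
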