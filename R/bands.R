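#' Credible bands for the inferred mean melting function
#'
#' Pointwise posterior median and central credible intervals of the mean
#' function on a temperature grid. For the sigmoid family the per-draw curve
#' is the sigmoid itself; for the semi-parametric family it is the sigmoid
#' plus the GP deviation's conditional mean given the data at that draw's
#' hyperparameters (the inferred mean function, not a fresh GP draw).
#'
#' @param samples a `posterior_samples` object.
#' @param protein the fitted [protein_melting_data].
#' @param T_grid temperatures at which to evaluate the bands (default: a
#'   101-point grid spanning the observed range).
#' @param levels credible levels (default 0.5 and 0.95); bands at lower
#'   levels are nested inside higher ones pointwise by construction.
#' @param max_draws curves are computed on at most this many draws,
#'   subsampled evenly.
#' @return object of class `mean_function_bands`: `T_grid`, `levels`, and per
#'   condition a list with `median` and `lower_*`/`upper_*` vectors per
#'   level, plus the draw-level curve matrix.
#' @export
mean_function_bands <- function(samples, protein, T_grid = NULL,
                                levels = c(0.5, 0.95), max_draws = 400L) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(T_grid))
    T_grid <- seq(min(protein$temperatures), max(protein$temperatures),
                  length.out = 101L)
  spec <- samples$spec
  S_total <- nrow(samples$blocks[[1L]]$draws)
  if (S_total == 0L) stop("empty draws")
  keep <- unique(round(seq(1L, S_total, length.out = min(max_draws, S_total))))

  curves_for_block <- function(block, cond) {
    theta <- constrain_block(block$draws[keep, , drop = FALSE])
    d <- block_data(protein, cond)
    out <- matrix(NA_real_, nrow = length(keep), ncol = length(T_grid))
    for (s in seq_along(keep)) {
      a <- theta[s, 1L]; b <- theta[s, 2L]; p <- theta[s, 3L]
      cur <- sigmoid(T_grid, a, b, p)
      if (spec$family == "semiparametric") {
        sg <- theta[s, 4L]; v <- theta[s, 5L]; l <- theta[s, 6L]
        cur <- cur + gp_conditional_mean(d$y, sigmoid(d$T, a, b, p), d$T,
                                         v, l, sg, T_grid)
      }
      out[s, ] <- cur
    }
    out
  }

  bands <- list()
  for (ci in seq_along(protein$conditions)) {
    cc <- protein$conditions[ci]
    block <- if (spec$hypothesis == "M0") samples$blocks[[1L]] else samples$blocks[[ci]]
    cond_arg <- if (spec$hypothesis == "M0") NULL else cc
    curves <- curves_for_block(block, cond_arg)
    b <- list(median = apply(curves, 2L, median), curves = curves)
    for (lev in levels) {
      qs <- apply(curves, 2L, quantile, probs = c((1 - lev) / 2, 1 - (1 - lev) / 2),
                  names = FALSE)
      tag <- sub("^0\\.", "", format(lev))
      b[[paste0("lower_", tag)]] <- qs[1L, ]
      b[[paste0("upper_", tag)]] <- qs[2L, ]
    }
    bands[[cc]] <- b
  }
  structure(list(T_grid = T_grid, levels = levels, conditions = protein$conditions,
                 bands = bands, family = spec$family,
                 hypothesis = spec$hypothesis),
            class = "mean_function_bands")
}

#' @export
print.mean_function_bands <- function(x, ...) {
  cat(sprintf("<mean_function_bands> %s/%s on %d grid points, levels %s\n",
              x$family, x$hypothesis, length(x$T_grid),
              paste(x$levels, collapse = "/")))
  invisible(x)
}
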