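#' Pipeline configuration
#'
#' @param seed master seed; per-protein sampler seeds derive from it and the
#'   protein id, so runs are reproducible and independent of protein order.
#' @param families which Bayesian families to fit.
#' @param priors prior list, see [prior_defaults()].
#' @param settings sampler settings, see [sampler_settings()].
#' @param prior_prob_M0 prior probability of the shared-curve model.
#' @param hit_threshold posterior-probability hit threshold (strict `>`).
#' @param delta_r2_threshold non-sigmoid flag threshold on `delta R^2`.
#' @param band_draws draws used for posterior-median curves (`delta R^2`).
#' @param nparc_trim tail trim for the effective-dof fit.
#' @param proteins optional character vector restricting the analysis.
#' @param output_dir optional directory for the checkpoint file; reruns skip
#'   proteins already present in the checkpoint.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       families = c("sigmoid", "semiparametric"),
                       priors = prior_defaults(),
                       settings = sampler_settings(),
                       prior_prob_M0 = 0.99,
                       hit_threshold = 0.99,
                       delta_r2_threshold = 0.05,
                       band_draws = 200L,
                       nparc_trim = 0.05,
                       proteins = NULL,
                       output_dir = NULL) {
  families <- match.arg(families, c("sigmoid", "semiparametric"),
                        several.ok = TRUE)
  stopifnot(hit_threshold > 0, hit_threshold <= 1,
            delta_r2_threshold > 0, delta_r2_threshold < 1,
            prior_prob_M0 > 0, prior_prob_M0 < 1)
  structure(list(seed = as.integer(seed), families = families, priors = priors,
                 settings = settings, prior_prob_M0 = prior_prob_M0,
                 hit_threshold = hit_threshold,
                 delta_r2_threshold = delta_r2_threshold,
                 band_draws = as.integer(band_draws), nparc_trim = nparc_trim,
                 proteins = proteins, output_dir = output_dir),
            class = "run_config")
}

# median inferred mean curve per condition at the observed temperatures,
# from a condition-specific fit
median_curves <- function(samples, protein, band_draws) {
  bands <- mean_function_bands(samples, protein, T_grid = protein$temperatures,
                               levels = 0.5, max_draws = band_draws)
  curves <- lapply(bands$bands, `[[`, "median")
  names(curves) <- protein$conditions
  curves
}

# fit one family (M0 + M1), returning evidence, probability and extras
fit_family_for_protein <- function(family, protein, config, pseed) {
  spec0 <- model_spec(family, "M0", config$priors)
  spec1 <- model_spec(family, "M1", config$priors)
  s0 <- sample_posterior(spec0, protein, seed = pseed, settings = config$settings)
  s1 <- sample_posterior(spec1, protein, seed = pseed + 1L,
                         settings = config$settings)
  logml0 <- laplace_metropolis_logml(s0)
  logml1 <- laplace_metropolis_logml(s1)
  ev <- posterior_model_prob(logml0, logml1, config$prior_prob_M0)
  curves <- median_curves(s1, protein, config$band_draws)
  list(evidence = ev, r2 = variance_explained(protein, curves),
       unreliable = s0$unreliable || s1$unreliable,
       max_rhat = max(unlist(lapply(c(s0$blocks, s1$blocks),
                                    function(b) b$diagnostics$rhat))),
       divergences = sum(unlist(lapply(c(s0$blocks, s1$blocks),
                                       function(b) b$diagnostics$divergences))))
}

analyse_one_protein <- function(protein, config) {
  pseed <- protein_seed(config$seed, protein$protein_id)
  row <- data.frame(protein_id = protein$protein_id)
  for (family in config$families) {
    tag <- if (family == "sigmoid") "sigmoid" else "semipar"
    res <- tryCatch(fit_family_for_protein(family, protein, config, pseed),
                    error = function(e) e)
    if (inherits(res, "error")) {
      row[[paste0("logml_M0_", tag)]] <- NA_real_
      row[[paste0("logml_M1_", tag)]] <- NA_real_
      row[[paste0("prob_M1_", tag)]] <- NA_real_
      row[[paste0("r2_", tag)]] <- NA_real_
      row[[paste0("unreliable_", tag)]] <- TRUE
      row[[paste0("max_rhat_", tag)]] <- NA_real_
      row[[paste0("error_", tag)]] <- conditionMessage(res)
    } else {
      row[[paste0("logml_M0_", tag)]] <- res$evidence$logml_M0
      row[[paste0("logml_M1_", tag)]] <- res$evidence$logml_M1
      row[[paste0("prob_M1_", tag)]] <- res$evidence$posterior_prob_M1
      row[[paste0("r2_", tag)]] <- res$r2
      row[[paste0("unreliable_", tag)]] <- res$unreliable
      row[[paste0("max_rhat_", tag)]] <- res$max_rhat
      row[[paste0("error_", tag)]] <- ""
    }
  }
  row
}

#' Run the full per-protein analysis
#'
#' For every complete protein: the NPARC F statistic with dataset-level
#' effective degrees of freedom and BH-adjusted p-values; for each requested
#' Bayesian family, shared-curve and condition-specific fits, their
#' Laplace-Metropolis marginal likelihoods and the posterior probability of
#' a treatment effect; and (when both families are fitted) the variance
#' explained by each family's condition-specific median curve, `delta R^2`
#' and the non-sigmoid flag. Proteins with missing cells are excluded from
#' model fitting and listed in the `excluded` attribute; per-protein failures
#' are recorded in the row, never aborting the run. Deterministic given the
#' config seed; with an `output_dir`, completed proteins are checkpointed and
#' skipped on rerun.
#'
#' @param ds a [tpp_dataset], or a path to a long-format table.
#' @param config a [run_config()].
#' @return results data frame, one row per analysed protein, ranked by the
#'   headline (semi-parametric if fitted) posterior probability then log
#'   Bayes factor; attributes `excluded`, `d1_eff`, `d2_eff`, `hits`.
#' @export
run_analysis <- function(ds, config = run_config()) {
  if (is.character(ds)) ds <- read_long_table(ds)
  stopifnot(inherits(ds, "tpp_dataset"), inherits(config, "run_config"))
  proteins <- ds$proteins
  if (!is.null(config$proteins))
    proteins <- proteins[intersect(names(proteins), config$proteins)]
  complete <- vapply(proteins, is_complete, logical(1))
  excluded <- names(proteins)[!complete]
  if (length(excluded) > 0)
    message(sprintf("excluding %d proteins with missing cells", length(excluded)))
  proteins <- proteins[complete]
  if (length(proteins) == 0L) stop("no complete proteins to analyse")

  sub <- tpp_dataset(unname(proteins), metadata = ds$metadata)
  nparc <- nparc_analysis(sub, trim = config$nparc_trim)

  checkpoint_path <- NULL
  done <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    checkpoint_path <- file.path(config$output_dir, "checkpoint.tsv")
    if (file.exists(checkpoint_path)) {
      done <- read.delim(checkpoint_path, stringsAsFactors = FALSE)
      message(sprintf("resuming: %d proteins already in checkpoint", nrow(done)))
    }
  }

  rows <- list()
  for (id in names(proteins)) {
    if (!is.null(done) && id %in% done$protein_id) {
      rows[[id]] <- done[done$protein_id == id, , drop = FALSE]
      next
    }
    row <- analyse_one_protein(proteins[[id]], config)
    rows[[id]] <- row
    if (!is.null(checkpoint_path)) {
      write.table(row, checkpoint_path, sep = "\t", row.names = FALSE,
                  col.names = !file.exists(checkpoint_path),
                  append = file.exists(checkpoint_path), quote = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- merge(nparc, res, by = "protein_id", sort = FALSE)

  both <- all(c("sigmoid", "semiparametric") %in% config$families)
  if (both) {
    res$delta_r2 <- res$r2_semipar - res$r2_sigmoid
    res$non_sigmoid_flag <- ifelse(is.finite(res$delta_r2),
                                   res$delta_r2 >= config$delta_r2_threshold, NA)
  }
  for (tag in intersect(c("sigmoid", "semipar"),
                        c(if ("sigmoid" %in% config$families) "sigmoid",
                          if ("semiparametric" %in% config$families) "semipar"))) {
    pc <- paste0("prob_M1_", tag)
    res[[paste0("hit_", tag)]] <- !is.na(res[[pc]]) &
      res[[pc]] > config$hit_threshold
  }

  head_tag <- if ("semiparametric" %in% config$families) "semipar" else "sigmoid"
  ord <- order(-ifelse(is.na(res[[paste0("prob_M1_", head_tag)]]), -Inf,
                       res[[paste0("prob_M1_", head_tag)]]),
               -(res[[paste0("logml_M1_", head_tag)]] -
                 res[[paste0("logml_M0_", head_tag)]]))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL

  attr(res, "excluded") <- excluded
  attr(res, "d1_eff") <- attr(nparc, "d1_eff")
  attr(res, "d2_eff") <- attr(nparc, "d2_eff")
  attr(res, "config_seed") <- config$seed
  res
}
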