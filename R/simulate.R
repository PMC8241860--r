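#' Experimental design for simulated TPP data
#'
#' Defaults mirror the common TMT10 two-condition design: 10 temperatures
#' evenly spanning 37-67 degrees Celsius, two conditions (vehicle control and
#' treatment) with two replicates each.
#'
#' @param temperatures strictly increasing temperature grid (degC).
#' @param n_replicates integer vector of length 2, replicates per condition.
#' @param conditions length-2 condition labels (control first).
#' @return list describing the design.
#' @export
sim_design <- function(temperatures = seq(37, 67, length.out = 10),
                       n_replicates = c(2L, 2L),
                       conditions = c("vehicle", "treatment")) {
  stopifnot(length(conditions) == 2L, length(n_replicates) == 2L,
            all(n_replicates >= 1L), all(diff(temperatures) > 0))
  list(temperatures = temperatures, n_replicates = as.integer(n_replicates),
       conditions = conditions)
}

sim_scenarios <- function() {
  c("null_sigmoid", "shifted_sigmoid", "gp_deviation", "biphasic",
    "hypersolubilised", "biphasic_shifted")
}

#' Default effect sizes for the generator
#'
#' Midpoints `a/b` are drawn in 44-58 degC with `b` in 8-20 so simulated
#' curves melt in the range seen in real K562 data; plateaus are small; noise
#' levels correspond to quiet and noisy proteins. Treatment shifts move the
#' melting midpoint by 2-5 degC; biphasic/hypersolubilisation deviations are
#' deterministic bump/ramp templates with amplitudes (0.3-0.6 solubility
#' units) comparable to the reproducible non-sigmoid excursions seen in real
#' melting curves, sized so the non-sigmoid signal clearly exceeds the
#' variance-explained flag threshold; GP
#' deviations use a smooth kernel at the residual scale.
#'
#' @return named list of ranges/values consumed by [simulate_dataset()].
#' @export
effect_size_defaults <- function() {
  list(midpoint_degC = c(44, 58), b_range = c(8, 20), p_range = c(0, 0.2),
       sigma_levels = c(0.03, 0.08), shift_degC = c(2, 5),
       bump_amplitude = c(0.3, 0.6), bump_center_degC = c(48, 56),
       bump_width_degC = 5, ramp_amplitude = c(0.3, 0.6),
       gp_v = 0.1, gp_l = 5)
}

runif1 <- function(range) runif(1L, range[1L], range[2L])

# draw one protein's ground truth; uses the current RNG state
draw_simulation_truth <- function(protein_id, scenario, es = effect_size_defaults()) {
  scenario <- match.arg(scenario, sim_scenarios())
  b <- runif1(es$b_range)
  tm <- runif1(es$midpoint_degC)
  a <- b * tm
  p <- runif1(es$p_range)
  sigma <- sample(es$sigma_levels, 1L)
  base <- c(a = a, b = b, p = p, sigma = sigma)
  pars <- list(base, base)

  shift_midpoint <- function(pars) {
    delta <- runif1(es$shift_degC) * sample(c(-1, 1), 1L)
    # keep b, move a so the (1+p)/2 crossing moves by delta
    pars[[2L]]["a"] <- pars[[2L]]["a"] + pars[[2L]]["b"] * delta
    pars
  }

  dev <- list(type = "none")
  affected <- FALSE
  if (scenario == "shifted_sigmoid") {
    pars <- shift_midpoint(pars)
    affected <- TRUE
  } else if (scenario == "gp_deviation") {
    dev <- list(type = "gp", v = es$gp_v, l = es$gp_l)
  } else if (scenario == "biphasic") {
    dev <- list(type = "bump", amplitude = runif1(es$bump_amplitude),
                center = runif1(es$bump_center_degC), width = es$bump_width_degC)
  } else if (scenario == "hypersolubilised") {
    dev <- list(type = "ramp", amplitude = runif1(es$ramp_amplitude))
  } else if (scenario == "biphasic_shifted") {
    pars <- shift_midpoint(pars)
    dev <- list(type = "bump", amplitude = runif1(es$bump_amplitude),
                center = runif1(es$bump_center_degC), width = es$bump_width_degC)
    affected <- TRUE
  }
  list(protein_id = protein_id, scenario = scenario, params = pars,
       deviation = dev, treatment_affected = affected)
}

# deterministic deviation templates (shared by both conditions)
deviation_curve <- function(dev, T) {
  switch(dev$type,
    none = rep(0, length(T)),
    bump = dev$amplitude * exp(-(T - dev$center)^2 / (2 * dev$width^2)),
    ramp = dev$amplitude * (T - min(T)) / (max(T) - min(T)),
    gp = stop("gp deviations are drawn, not deterministic"),
    stop("unknown deviation type"))
}

#' Simulate one protein's melting data
#'
#' `y = S_{a,b,p}(T) + deviation(T) + N(0, sigma^2)` per condition and
#' replicate. Deterministic bump/ramp deviations are shared by both
#' conditions; a GP deviation is drawn once (shared across conditions and
#' replicates) from the squared-exponential kernel. Reproducible under a
#' fixed seed.
#'
#' @param truth a truth record from the generator (see
#'   [simulate_dataset()]), with per-condition `(a, b, p, sigma)`, a
#'   deviation descriptor and the scenario label.
#' @param design a [sim_design()].
#' @param seed integer seed.
#' @return a [protein_melting_data].
#' @export
simulate_protein <- function(truth, design = sim_design(), seed = 1L) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  T <- design$temperatures
  dev <- if (truth$deviation$type == "gp") {
    v <- truth$deviation$v; l <- truth$deviation$l
    if (v < 0 || l <= 0) stop("invalid GP deviation parameters")
    K <- se_covariance(T, v, l) + 1e-10 * max(v^2, 1e-12) * diag(length(T))
    as.vector(t(chol(K)) %*% rnorm(length(T)))
  } else {
    deviation_curve(truth$deviation, T)
  }
  obs <- vector("list", 2L)
  for (ci in 1:2) {
    pp <- truth$params[[ci]]
    if (pp["sigma"] <= 0) stop("sigma must be positive")
    mu <- sigmoid(T, pp["a"], pp["b"], pp["p"]) + dev
    m <- matrix(NA_real_, design$n_replicates[ci], length(T))
    for (k in seq_len(design$n_replicates[ci]))
      m[k, ] <- pmax(mu + rnorm(length(T), 0, pp["sigma"]), 0)
    obs[[ci]] <- m
  }
  protein_melting_data(truth$protein_id, T, design$conditions, obs)
}

protein_seed <- function(master_seed, protein_id) {
  h <- 0
  for (b in utf8ToInt(protein_id)) h <- (h * 31 + b) %% 2147483647
  as.integer((master_seed + h) %% 2147483647)
}

#' Simulate a TPP dataset with known ground truth
#'
#' Draws per-protein scenarios from `scenario_mix`, ground-truth parameters
#' from [effect_size_defaults()]-style ranges, and generates observations
#' with [simulate_protein()]. The output dataset is structurally identical to
#' a real TPP import and round-trips through the long-format reader/writer.
#'
#' @param n_proteins number of proteins.
#' @param scenario_mix named numeric vector of scenario proportions (summing
#'   to 1; scenarios drawn per protein), or of integer counts summing to
#'   `n_proteins` (exact composition, assigned in a shuffled order); names
#'   from `c("null_sigmoid", "shifted_sigmoid", "gp_deviation", "biphasic",
#'   "hypersolubilised", "biphasic_shifted")`.
#' @param effect_sizes effect-size list, see [effect_size_defaults()].
#' @param design a [sim_design()].
#' @param seed master seed; per-protein seeds are derived from it and the
#'   protein id.
#' @return list with `dataset` (a [tpp_dataset]) and `truth` (data frame:
#'   per-protein scenario, parameters, deviation descriptor,
#'   `treatment_affected`).
#' @export
simulate_dataset <- function(n_proteins, scenario_mix = c(null_sigmoid = 1),
                             effect_sizes = effect_size_defaults(),
                             design = sim_design(), seed = 1L) {
  bad <- setdiff(names(scenario_mix), sim_scenarios())
  if (length(bad) > 0) stop("unknown scenarios: ", paste(bad, collapse = ", "))
  counts <- all(scenario_mix == round(scenario_mix)) &&
    abs(sum(scenario_mix) - n_proteins) < 1e-8 && n_proteins > 1
  if (!counts && abs(sum(scenario_mix) - 1) > 1e-8)
    stop("scenario mix must sum to 1 (proportions) or to n_proteins (counts)")
  set.seed(as.integer(seed %% .Machine$integer.max))
  ids <- sprintf("P%04d", seq_len(n_proteins))
  scen <- if (counts) {
    sample(rep(names(scenario_mix), times = scenario_mix))
  } else {
    sample(names(scenario_mix), n_proteins, replace = TRUE,
           prob = scenario_mix)
  }
  truths <- lapply(seq_len(n_proteins), function(i)
    draw_simulation_truth(ids[i], scen[i], effect_sizes))
  proteins <- lapply(truths, function(tr)
    simulate_protein(tr, design, seed = protein_seed(seed, tr$protein_id)))
  truth_df <- do.call(rbind, lapply(truths, function(tr) {
    data.frame(protein_id = tr$protein_id, scenario = tr$scenario,
               treatment_affected = tr$treatment_affected,
               a_1 = tr$params[[1L]]["a"], b_1 = tr$params[[1L]]["b"],
               p_1 = tr$params[[1L]]["p"], sigma_1 = tr$params[[1L]]["sigma"],
               a_2 = tr$params[[2L]]["a"], b_2 = tr$params[[2L]]["b"],
               p_2 = tr$params[[2L]]["p"], sigma_2 = tr$params[[2L]]["sigma"],
               dev_type = tr$deviation$type,
               dev_amplitude = tr$deviation$amplitude %||% NA_real_,
               dev_center = tr$deviation$center %||% NA_real_,
               gp_v = if (tr$deviation$type == "gp") tr$deviation$v else NA_real_,
               gp_l = if (tr$deviation$type == "gp") tr$deviation$l else NA_real_,
               row.names = NULL)
  }))
  list(dataset = tpp_dataset(proteins,
                             metadata = list(treatment = "simulated",
                                             seed = seed)),
       truth = truth_df)
}
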