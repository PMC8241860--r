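# shared fixtures and reduced sampler settings for the test suite

# chain settings sized so a single protein fits in well under a second while
# leaving enough retained draws (800) for stable evidence estimates
test_settings <- function() {
  sampler_settings(chains = 2L, warmup = 400L, draws = 400L)
}

default_prior_vec <- function() {
  c(7, 0.01, 7, 0.4, 1, 20, 0.05, 3, 0.5, -0.5, 0.5)
}

# deterministic sigmoid protein; shift moves the treatment midpoint (degC)
make_protein <- function(a = 550, b = 10, p = 0.1, sigma = 0.05, shift = 0,
                         n_reps = 2, temperatures = seq(37, 67, length.out = 10),
                         seed = 1, deviation = NULL, id = "TEST1") {
  set.seed(seed)
  obs <- list()
  params <- list(c(a = a, b = b, p = p), c(a = a + b * shift, b = b, p = p))
  for (ci in 1:2) {
    pp <- params[[ci]]
    mu <- sigmoid(temperatures, pp["a"], pp["b"], pp["p"])
    if (!is.null(deviation)) mu <- mu + deviation(temperatures)
    m <- matrix(NA_real_, n_reps, length(temperatures))
    for (k in seq_len(n_reps)) m[k, ] <- pmax(mu + rnorm(length(mu), 0, sigma), 0)
    obs[[ci]] <- m
  }
  protein_melting_data(id, temperatures, c("vehicle", "treatment"), obs)
}

# long-format data frame for reader tests
make_long_df <- function(n_prot = 1, n_reps = 2,
                         temps = seq(37, 67, length.out = 10), seed = 7) {
  set.seed(seed)
  rows <- expand.grid(protein_id = sprintf("P%02d", seq_len(n_prot)),
                      condition = c("vehicle", "treatment"),
                      replicate = seq_len(n_reps), temperature_C = temps,
                      stringsAsFactors = FALSE)
  rows$rel_solubility <- round(pmax(
    sigmoid(rows$temperature_C, 550, 10, 0.1) + rnorm(nrow(rows), 0, 0.05), 0), 6)
  rows
}
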