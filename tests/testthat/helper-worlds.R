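# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data.

# A small synthetic world for fast unit tests.
small_world <- function(seed = 1, years = 2, n_per_year = 50,
                        n_species = 10, n_stations = 20, effects = list(),
                        station_sd = 0.5, ...) {
  eff <- true_effect_config(years = years, effects = effects,
                            station_sd = station_sd, seed = seed, ...)
  generate_observations(
    generate_community(n_species, seed = seed + 1),
    generate_stations(n_stations, seed = seed + 2),
    eff, n_per_year = n_per_year, seed = seed + 3
  )
}

# Standardized clean-frequency analysis table + spec for a dataset.
freq_setup <- function(dataset, fixed = NULL) {
  tab <- build_response_table(dataset, "clean_frequency")
  cont <- continuous_factors()
  std <- standardize_predictors(tab, cont)
  fixed <- fixed %||% c(contextual_factors()$factor, "observer_type")
  list(data = std$data,
       spec = cc_model_spec("clean_frequency", fixed = fixed))
}

# Minimal direct binomial-probit dataset with one station intercept; used
# to test the fitter without the full generator in the loop.
direct_probit_data <- function(n = 300, beta = c(0.5, -0.3), intercept = -1,
                               station_sd = 0.5, n_stations = 15,
                               trials = 20, seed = 1) {
  set.seed(seed)
  st <- sample(n_stations, n, replace = TRUE)
  b <- rnorm(n_stations, 0, station_sd)
  X <- matrix(rnorm(n * length(beta)), n)
  colnames(X) <- paste0("x", seq_along(beta))
  eta <- intercept + drop(X %*% beta) + b[st]
  d <- as.data.frame(X)
  d$station_id <- sprintf("s%02d", st)
  d$trials <- trials
  d$successes <- rbinom(n, trials, pnorm(eta))
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent permutation enumerator used as the exhaustive Mantel oracle
# (kept deliberately separate from the package's own internals).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(oracle_perms(n - 1L), function(s) {
    lapply(seq_len(n), function(pos) append(s, n, after = pos - 1L))
  }))
}
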