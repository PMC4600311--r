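# One moderately sized simulated study plus a model-1 fit, built lazily and
# shared by the summary and acceptance tests (several checks read the same
# posterior). Size and MCMC length are the package's documented defaults
# for the recovery scenario.
.fixture_env <- new.env(parent = emptyenv())

fixture_study <- function(seed = 1L) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_study(rows = 20, cols = 20, seed = seed)
  }
  .fixture_env[[key]]
}

fixture_fit <- function(seed = 1L, age_group = "55-74") {
  key <- paste0("fit_", seed, "_", age_group)
  if (is.null(.fixture_env[[key]])) {
    st <- fixture_study(seed)
    rates <- compute_reference_rates(st$deaths, st$population)
    expected <- compute_expected(st$population, rates)
    dg <- aggregate_to_age_groups(st$deaths)
    fit <- sample_posterior(
      dg, expected, st$covariates, st$graph,
      model_spec("poisson", "spatial"),
      config = mcmc_config(chains = 4, iterations = 5000, burn_in = 2500,
                           thin = 10, seed = seed),
      age_group = age_group)
    .fixture_env[[key]] <- list(study = st, expected = expected,
                                deaths_grouped = dg, fit = fit)
  }
  .fixture_env[[key]]
}
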