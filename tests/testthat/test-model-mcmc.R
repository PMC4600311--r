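# minimal one-group tables for direct likelihood evaluation
tiny_tables <- function(y, E, units = sprintf("u%d", seq_along(y))) {
  list(deaths = data.frame(unit_id = units, period = "P1", age_group = "<55",
                           deaths = y),
       expected = data.frame(unit_id = units, period = "P1",
                             age_group = "<55", expected = E),
       covariates = data.frame(
         unit_id = units,
         language = factor("German", c("German", "French", "ItalianRomansh")),
         urbanisation = factor("rural", c("rural", "urban"))))
}

zero_params <- function(T_ = 1) {
  list(alpha = 0, beta_period = rep(0, T_), beta_language = rep(0, 3),
       beta_urban = rep(0, 2))
}

test_that("Poisson log-likelihood matches the closed-form pmf", {
  tt <- tiny_tables(y = 2, E = 2)
  ll <- log_likelihood(tt$deaths, tt$expected, model_spec("poisson"),
                       zero_params(), tt$covariates)
  # oracle: 2 log 2 - 2 - log 2!
  expect_equal(ll, 2 * log(2) - 2 - log(factorial(2)), tolerance = 1e-12)

  # E = 0 with y = 0 contributes nothing
  tt2 <- tiny_tables(y = c(2, 0), E = c(2, 0))
  ll2 <- log_likelihood(tt2$deaths, tt2$expected, model_spec("poisson"),
                        zero_params(), tt2$covariates)
  expect_equal(ll2, ll)

  # E = 0 with y > 0 is impossible under the model
  tt3 <- tiny_tables(y = c(1), E = c(0))
  expect_error(log_likelihood(tt3$deaths, tt3$expected, model_spec("poisson"),
                              zero_params(), tt3$covariates),
               "impossible")
})

test_that("negative binomial likelihood attains its Poisson limit", {
  set.seed(31)
  y <- rpois(50, 6); E <- runif(50, 2, 9)
  tt <- tiny_tables(y, E)
  p <- zero_params(); p$alpha <- 0.3
  ll_p <- log_likelihood(tt$deaths, tt$expected, model_spec("poisson"),
                         p, tt$covariates)
  p$kappa <- 1e8
  ll_nb <- log_likelihood(tt$deaths, tt$expected, model_spec("negbin"),
                          p, tt$covariates)
  expect_lt(abs(ll_nb - ll_p) / 50, 1e-6)  # per-cell agreement
})

test_that("the reference-level constraint breaks shift invariance", {
  st <- simulate_study(rows = 3, cols = 3, seed = 14)
  rates <- compute_reference_rates(st$deaths, st$population)
  ex <- compute_expected(st$population, rates)
  dg <- aggregate_to_age_groups(st$deaths)
  p <- zero_params(T_ = 5)
  ll0 <- log_likelihood(dg, ex, model_spec("poisson"), p, st$covariates,
                        age_group = "55-74")
  # shifting alpha by c and all period effects by -c changes the likelihood
  # because the reference period's coefficient stays pinned at 0
  p2 <- p; p2$alpha <- p$alpha + 1
  p2$beta_period <- p$beta_period - 1; p2$beta_period[1] <- 0
  ll1 <- log_likelihood(dg, ex, model_spec("poisson"), p2, st$covariates,
                        age_group = "55-74")
  expect_gt(abs(ll1 - ll0), 0.5)
  # whereas with a free (unpinned) reference coefficient the same shift
  # leaves the likelihood untouched
  p3 <- p; p3$alpha <- p$alpha + 1; p3$beta_period <- p$beta_period - 1
  ll2 <- log_likelihood(dg, ex, model_spec("poisson"), p3, st$covariates,
                        age_group = "55-74")
  expect_equal(ll2, ll0, tolerance = 1e-9)
})

test_that("CAR full conditionals match the dense multivariate-normal oracle", {
  # 3-node path textbook cases
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  g <- graph_from_adjmat(A)
  fc <- car_full_conditional(2, c(1, 0.2, -1), sigma_phi = 0.5, g)
  expect_equal(fc$mean, 0)
  expect_equal(fc$variance, 0.25 / 2)
  fc_end <- car_full_conditional(1, c(0, 0.7, 0), sigma_phi = 1, g)
  expect_equal(fc_end$mean, 0.7)
  expect_equal(fc_end$variance, 1)

  # every connected graph on <= 5 nodes, random field values
  set.seed(77)
  for (n in 2:5) {
    for (A in enumerate_connected_graphs(n)) {
      g <- graph_from_adjmat(A)
      phi <- rnorm(n)
      sigma <- runif(1, 0.2, 2)
      P <- (diag(rowSums(A)) - A) / sigma^2
      for (i in seq_len(n)) {
        fc <- car_full_conditional(i, phi, sigma, g)
        oracle <- dense_mvn_conditional(P, phi, i)
        expect_equal(fc$mean, oracle$mean, tolerance = 1e-12)
        expect_equal(fc$variance, oracle$variance, tolerance = 1e-12)
      }
    }
  }

  solo <- adjacency_graph(c("a", "b"), list(integer(0), integer(0)))
  expect_error(car_full_conditional(1, c(0, 0), 1, solo), "island")
})

test_that("chains are bit-identical under a fixed seed", {
  st <- simulate_study(rows = 4, cols = 4, seed = 2)
  rates <- compute_reference_rates(st$deaths, st$population)
  ex <- compute_expected(st$population, rates)
  dg <- aggregate_to_age_groups(st$deaths)
  cfg <- mcmc_config(chains = 2, iterations = 700, burn_in = 200, thin = 5,
                     seed = 13)
  f1 <- sample_posterior(dg, ex, st$covariates, st$graph, config = cfg,
                         age_group = "75+")
  f2 <- sample_posterior(dg, ex, st$covariates, st$graph, config = cfg,
                         age_group = "75+")
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  # different seed gives different chains
  cfg2 <- mcmc_config(chains = 2, iterations = 700, burn_in = 200, thin = 5,
                      seed = 14)
  f3 <- sample_posterior(dg, ex, st$covariates, st$graph, config = cfg2,
                         age_group = "75+")
  expect_false(identical(f1$draws, f3$draws))
})

test_that("with the likelihood switched off the sampler reproduces the ICAR prior", {
  skip_if_not_installed("MASS")
  # E = 0 everywhere (all-zero counts): every Metropolis step sees a flat
  # likelihood, so retained phi draws follow the prior. Their covariance
  # must equal E[sigma^2] * pseudoinverse(Q) within Monte-Carlo error.
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  g <- graph_from_adjmat(A, c("u1", "u2", "u3"))
  tt <- tiny_tables(y = rep(0, 3), E = rep(0, 3), units = g$units)
  cfg <- mcmc_config(chains = 2, iterations = 21000, burn_in = 1000,
                     thin = 2, seed = 5)
  fit <- sample_posterior(tt$deaths, tt$expected, tt$covariates, g,
                          model_spec("poisson", "spatial"), config = cfg)
  x <- pooled_draws(fit)
  phi <- x[, sprintf("phi[%s]", g$units)]
  s2 <- mean(x[, "sigma_phi"]^2)
  oracle <- s2 * MASS::ginv(diag(rowSums(A)) - A)
  expect_lt(max(abs(stats::cov(phi) - oracle)), 0.12 * max(1, s2))
})

test_that("the posterior recovers generating effects on a small study", {
  st <- simulate_study(rows = 10, cols = 10,
                       size_range = c(5000, 50000), seed = 4)
  rates <- compute_reference_rates(st$deaths, st$population)
  ex <- compute_expected(st$population, rates)
  dg <- aggregate_to_age_groups(st$deaths)
  fit <- sample_posterior(dg, ex, st$covariates, st$graph,
                          config = mcmc_config(chains = 2, iterations = 3000,
                                               burn_in = 1000, thin = 4,
                                               seed = 6),
                          age_group = "55-74")
  s <- summarize_effects(fit)
  est <- s$effects$smr_ratio[s$effects$effect == "period"]
  expect_lt(max(abs(est - exp(st$truth$beta_period))), 0.15)
  rh <- gelman_rubin(fit)
  expect_lt(max(rh$rhat), 1.15)
})

test_that("persisted chains round-trip through delimited text", {
  st <- simulate_study(rows = 3, cols = 3, seed = 2)
  rates <- compute_reference_rates(st$deaths, st$population)
  ex <- compute_expected(st$population, rates)
  dg <- aggregate_to_age_groups(st$deaths)
  fit <- sample_posterior(dg, ex, st$covariates, st$graph,
                          config = mcmc_config(chains = 2, iterations = 700,
                                               burn_in = 200, thin = 5,
                                               seed = 1),
                          age_group = "55-74")
  dir <- withr::local_tempdir()
  write_chains(fit, dir)
  d1 <- utils::read.delim(file.path(dir, "chain1_draws.tsv"),
                          check.names = FALSE)
  expect_equal(colnames(d1), fit$param_names)
  expect_equal(as.matrix(d1), fit$draws[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
  dev <- utils::read.delim(file.path(dir, "chain2_deviance.tsv"))
  expect_equal(dev$deviance, fit$deviance[[2]], tolerance = 1e-10)
  man <- yaml::read_yaml(file.path(dir, "chains_manifest.yaml"))
  expect_equal(man$config$seed, 1L)
  expect_equal(man$age_group, "55-74")
  expect_equal(man$parameters, fit$param_names)
})

test_that("an NB fit pinned at huge dispersion reproduces the Poisson posterior", {
  st <- simulate_study(rows = 6, cols = 6, size_range = c(5000, 50000),
                       seed = 26)
  rates <- compute_reference_rates(st$deaths, st$population)
  ex <- compute_expected(st$population, rates)
  dg <- aggregate_to_age_groups(st$deaths)
  cfg <- mcmc_config(chains = 2, iterations = 2500, burn_in = 1000, thin = 3,
                     seed = 9)
  fit_p <- sample_posterior(dg, ex, st$covariates, st$graph,
                            model_spec("poisson", "spatial"), config = cfg,
                            age_group = "55-74")
  # prior concentrating log kappa near 20: the NB likelihood is Poisson to
  # numerical precision, so beta posteriors must agree within MC error
  pri <- default_priors(kappa_meanlog = 20, kappa_sdlog = 0.01)
  fit_nb <- sample_posterior(dg, ex, st$covariates, st$graph,
                             model_spec("negbin", "spatial"), priors = pri,
                             config = cfg, age_group = "55-74")
  bp <- colMeans(pooled_draws(fit_p)[, sprintf("beta_period[P%d]", 2:5)])
  bn <- colMeans(pooled_draws(fit_nb)[, sprintf("beta_period[P%d]", 2:5)])
  expect_lt(max(abs(bp - bn)), 0.05)
})

test_that("capturing real spatial structure lowers the posterior mean deviance", {
  # data with a strong spatial field: the spatial model explains signal the
  # non-spatial one must leave in the residual deviance
  st <- simulate_study(rows = 8, cols = 8,
                       truth_args = list(sigma_phi = 0.6), seed = 33)
  rates <- compute_reference_rates(st$deaths, st$population)
  ex <- compute_expected(st$population, rates)
  dg <- aggregate_to_age_groups(st$deaths)
  cfg <- mcmc_config(chains = 2, iterations = 1500, burn_in = 500, thin = 5,
                     seed = 4)
  d_spatial <- compute_dic(sample_posterior(dg, ex, st$covariates, st$graph,
                                            model_spec("poisson", "spatial"),
                                            config = cfg,
                                            age_group = "55-74"))
  d_none <- compute_dic(sample_posterior(dg, ex, st$covariates, st$graph,
                                         model_spec("poisson", "none"),
                                         config = cfg, age_group = "55-74"))
  expect_true(is.finite(d_spatial$dbar) && is.finite(d_none$dbar))
  expect_lt(d_spatial$dbar, d_none$dbar)
})

test_that("Gelman-Rubin behaves on identical, same-distribution and divergent chains", {
  mk <- function(ch) {
    structure(list(draws = ch, deviance = lapply(ch, function(d) rep(0, nrow(d))),
                   param_names = colnames(ch[[1]]),
                   spec = model_spec(), config = NULL, data = NULL,
                   graph = NULL),
              class = "posterior_chains")
  }
  set.seed(12)
  a <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "alpha"))
  same <- mk(list(a, a))
  expect_lte(gelman_rubin(same, "alpha")$rhat, 1 + 1e-6)

  b <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "alpha"))
  indep <- mk(list(a, b))
  expect_lt(abs(gelman_rubin(indep, "alpha")$rhat - 1), 0.05)

  c2 <- matrix(rnorm(10000, 10), ncol = 1, dimnames = list(NULL, "alpha"))
  div <- mk(list(a, c2))
  res <- gelman_rubin(div, "alpha")
  expect_gt(res$rhat, 1.1)
  expect_true(res$flagged)

  expect_error(gelman_rubin(mk(list(a))), "2 chains")
})
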