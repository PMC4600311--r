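#' Model specification for the spatio-temporal count regression
#'
#' The mean of the count in cell (unit i, period t) is `E[i,t] * r[i,t]`
#' with `log r = alpha + beta_period[t] + beta_language[l(i)] +
#' beta_urban[u(i)] + phi_i (+ theta_i)`. The four canonical models of
#' the analysis enumerate family (Poisson / negative binomial) crossed
#' with random effects (spatial only / spatial + unstructured); model
#' numbers follow that order. A non-spatial variant
#' (`random_effects = "none"`) is also available for preliminary,
#' unsmoothed analyses.
#'
#' @param family `"poisson"` or `"negbin"`.
#' @param random_effects `"spatial"`, `"spatial_unstructured"`, or
#'   `"none"`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("poisson", "negbin"),
                       random_effects = c("spatial", "spatial_unstructured",
                                          "none")) {
  family <- match.arg(family)
  random_effects <- match.arg(random_effects)
  structure(list(family = family, random_effects = random_effects),
            class = "model_spec")
}

#' The four canonical models compared by DIC
#'
#' Model 1: Poisson, spatial RE; model 2: negative binomial, spatial RE;
#' model 3: Poisson, spatial + unstructured RE; model 4: negative
#' binomial, spatial + unstructured RE.
#'
#' @return named list of [model_spec()] objects `model1` ... `model4`.
#' @export
canonical_models <- function() {
  list(model1 = model_spec("poisson", "spatial"),
       model2 = model_spec("negbin", "spatial"),
       model3 = model_spec("poisson", "spatial_unstructured"),
       model4 = model_spec("negbin", "spatial_unstructured"))
}

#' Canonical number (1-4) of a model spec, NA for non-canonical specs
#' @param spec a `model_spec`.
#' @return integer.
#' @export
model_number <- function(spec) {
  if (spec$random_effects == "none") return(NA_integer_)
  base <- if (spec$random_effects == "spatial") 1L else 3L
  base + (spec$family == "negbin")
}

#' Weakly informative default priors
#'
#' Gaussian(0, `beta_sd`^2) on the intercept and every regression
#' coefficient; half-normal(scale) on the spatial and unstructured
#' standard deviations; Gaussian on the log of the negative binomial
#' dispersion.
#'
#' @param beta_sd prior sd of alpha and the betas (default 10).
#' @param sigma_phi_scale,sigma_theta_scale half-normal scales (default 1).
#' @param kappa_meanlog,kappa_sdlog log-normal parameters for the NB
#'   dispersion (default 0 and 2).
#' @return named list of class `mcmc_priors`.
#' @export
default_priors <- function(beta_sd = 10, sigma_phi_scale = 1,
                           sigma_theta_scale = 1,
                           kappa_meanlog = 0, kappa_sdlog = 2) {
  stopifnot(beta_sd > 0, sigma_phi_scale > 0, sigma_theta_scale > 0,
            kappa_sdlog > 0)
  structure(list(beta_sd = beta_sd, sigma_phi_scale = sigma_phi_scale,
                 sigma_theta_scale = sigma_theta_scale,
                 kappa_meanlog = kappa_meanlog, kappa_sdlog = kappa_sdlog),
            class = "mcmc_priors")
}

#' MCMC run configuration
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iterations total Metropolis-within-Gibbs sweeps per chain.
#' @param burn_in sweeps discarded (proposal adaptation happens only
#'   here, so the retained kernel is fixed).
#' @param thin keep every `thin`-th post-burn-in sweep; at least 100
#'   retained draws per chain are required.
#' @param seed integer master seed; chain c uses `seed + c`.
#' @param adapt_interval sweeps between proposal-scale updates during
#'   burn-in.
#' @return named list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iterations = 5000, burn_in = 2500,
                        thin = 5, seed = 1, adapt_interval = 50) {
  stopifnot(chains >= 1, burn_in >= 0, burn_in < iterations, thin >= 1,
            adapt_interval >= 1)
  retained <- (iterations - burn_in) %/% thin
  if (retained < 100) {
    stop("configuration retains only ", retained,
         " draws per chain; at least 100 are required for summaries")
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval)),
            class = "mcmc_config")
}

# Assemble the n x T matrices and covariate codes the sampler consumes for
# ONE coarse age group. Unit order is graph order; period order is sorted.
build_model_data <- function(deaths_grouped, expected, covariates, graph,
                             age_group = NULL) {
  groups <- unique(deaths_grouped$age_group)
  if (is.null(age_group)) {
    if (length(groups) > 1L) {
      stop("several age groups present; pass age_group = one of: ",
           paste(groups, collapse = ", "))
    }
    age_group <- groups
  }
  d <- deaths_grouped[deaths_grouped$age_group == age_group, , drop = FALSE]
  e <- expected[expected$age_group == age_group, , drop = FALSE]
  units <- graph$units
  periods <- sort(unique(d$period))
  n <- length(units); T_ <- length(periods)
  key <- function(x) paste(x$unit_id, x$period)
  full <- paste(rep(units, each = T_), rep(periods, n))
  hd <- match(full, key(d)); he <- match(full, key(e))
  if (anyNA(hd) || anyNA(he)) stop("deaths/expected tables do not cover ",
                                   "every unit x period cell for group ",
                                   age_group)
  y <- matrix(d$deaths[hd], n, T_, byrow = TRUE)
  E <- matrix(e$expected[he], n, T_, byrow = TRUE)
  if (any(y > 0 & E == 0)) {
    stop("cell(s) with expected = 0 but deaths > 0: impossible under the model")
  }
  ic <- match(units, covariates$unit_id)
  if (anyNA(ic)) stop("covariates missing for unit(s): ",
                      paste(units[is.na(ic)], collapse = ", "))
  lang <- as.integer(covariates$language[ic]) - 1L
  urb <- as.integer(covariates$urbanisation[ic]) - 1L
  list(y = y, E = E, lang = lang, urb = urb,
       units = units, periods = periods, age_group = age_group)
}

#' Model log-likelihood at one parameter point
#'
#' Sums the Poisson or negative-binomial log probability mass over all
#' (unit, period) cells of one coarse age group, at the linear predictor
#' implied by `params`. Cells with `expected = 0` and `deaths = 0`
#' contribute 0; `expected = 0` with positive deaths is rejected.
#'
#' @param deaths_grouped,expected tables on the (unit, period, age_group)
#'   index, restricted or restrictable to one group.
#' @param spec a [model_spec()].
#' @param params list with elements `alpha`, `beta_period` (one value per
#'   period, first = 0), `beta_language` (length 3, first = 0),
#'   `beta_urban` (length 2, first = 0), `phi` and `theta` (named by unit
#'   id; optional, default 0) and `kappa` (negbin only).
#' @param covariates per-unit covariate table.
#' @param age_group which coarse group, when several are present.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(deaths_grouped, expected, spec, params, covariates,
                           age_group = NULL) {
  graph_like <- list(units = sort(unique(deaths_grouped$unit_id),
                                  method = "radix"))
  md <- build_model_data(deaths_grouped, expected, covariates,
                         structure(graph_like, class = "adjacency_graph"),
                         age_group)
  n <- nrow(md$y); T_ <- ncol(md$y)
  phi <- rep(0, n); theta <- rep(0, n)
  if (!is.null(params$phi)) phi <- unname(params$phi[md$units])
  if (!is.null(params$theta)) theta <- unname(params$theta[md$units])
  stopifnot(length(params$beta_period) == T_)
  eta <- matrix(params$alpha + phi + theta +
                  params$beta_language[md$lang + 1L] +
                  params$beta_urban[md$urb + 1L], n, T_) +
    matrix(params$beta_period, n, T_, byrow = TRUE)
  mu <- md$E * exp(eta)
  ll <- matrix(0, n, T_)
  pos <- md$E > 0
  if (spec$family == "poisson") {
    ll[pos] <- stats::dpois(md$y[pos], mu[pos], log = TRUE)
  } else {
    if (is.null(params$kappa) || params$kappa <= 0) {
      stop("negbin likelihood requires params$kappa > 0")
    }
    ll[pos] <- stats::dnbinom(md$y[pos], size = params$kappa, mu = mu[pos],
                              log = TRUE)
  }
  sum(ll)
}

#' Full conditional of one unit's intrinsic CAR effect
#'
#' Under the ICAR prior the conditional distribution of `phi_i` given the
#' rest of the field is normal with mean the average of the neighbours'
#' values and variance `sigma_phi^2 / n_i`.
#'
#' @param i unit index (into `graph$units`).
#' @param phi current field (numeric, graph order).
#' @param sigma_phi conditional sd scale.
#' @param graph an [adjacency_graph()].
#' @return list with `mean` and `variance`.
#' @export
car_full_conditional <- function(i, phi, sigma_phi, graph) {
  nb <- graph$neighbors[[i]]
  if (length(nb) == 0L) {
    stop("unit ", graph$units[i], " is an island (degree 0); ",
         "its spatial effect has no CAR conditional", call. = FALSE)
  }
  list(mean = mean(phi[nb]), variance = sigma_phi^2 / length(nb))
}

#' Fit the spatio-temporal model by Metropolis-within-Gibbs MCMC
#'
#' Random-walk Metropolis updates on the intercept, every regression
#' coefficient, every spatial and unstructured effect, the log of each
#' standard deviation and (for negative binomial) the log dispersion.
#' Proposal scales adapt toward 0.44 acceptance during burn-in and are
#' frozen afterwards. The spatial field is re-centred to sum to zero
#' within each graph component after every sweep, the removed level being
#' absorbed by the intercept. Chains are exactly reproducible from the
#' seed.
#'
#' @param deaths_grouped deaths on the (unit, period, age_group) index
#'   for one coarse age group.
#' @param expected an `ExpectedCounts` table on the same index.
#' @param covariates per-unit covariate table ([assign_covariates()]
#'   layout).
#' @param graph an [adjacency_graph()].
#' @param spec a [model_spec()].
#' @param priors a [default_priors()] list.
#' @param config an [mcmc_config()].
#' @param age_group coarse group to fit, when several are present.
#' @return an object of class `posterior_chains`: per-chain draw matrices
#'   (named columns), per-draw deviances, and the data/spec/config needed
#'   by the summary functions.
#' @export
sample_posterior <- function(deaths_grouped, expected, covariates, graph,
                             spec = model_spec(), priors = default_priors(),
                             config = mcmc_config(), age_group = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  md <- build_model_data(deaths_grouped, expected, covariates, graph,
                         age_group)
  n <- nrow(md$y); T_ <- ncol(md$y)
  use_phi <- spec$random_effects != "none"
  use_theta <- spec$random_effects == "spatial_unstructured"
  fam <- if (spec$family == "poisson") 0L else 1L
  nbr0 <- lapply(graph$neighbors, function(v) as.integer(v - 1L))

  param_names <- c(
    "alpha",
    sprintf("beta_period[%s]", md$periods[-1]),
    "beta_language[French]", "beta_language[ItalianRomansh]",
    "beta_urban[urban]",
    if (use_phi) c("sigma_phi", sprintf("phi[%s]", md$units)),
    if (use_theta) c("sigma_theta", sprintf("theta[%s]", md$units)),
    if (fam == 1L) "kappa")

  sigma_init <- stats::qnorm(0.75)  # median of a half-normal(1)
  draws <- vector("list", config$chains)
  deviance <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    init <- withr_seed(config$seed + ch, {
      list(alpha = stats::rnorm(1, 0, 0.2),
           beta_t = c(0, stats::rnorm(T_ - 1, 0, 0.2)),
           beta_l = c(0, stats::rnorm(2, 0, 0.2)),
           beta_u = c(0, stats::rnorm(1, 0, 0.2)),
           phi = rep(0, n), theta = rep(0, n),
           log_sigma_phi = log(priors$sigma_phi_scale * sigma_init),
           log_sigma_theta = log(priors$sigma_theta_scale * sigma_init),
           log_kappa = priors$kappa_meanlog)
    })
    ll0 <- log_likelihood(
      deaths_grouped, expected, spec,
      list(alpha = init$alpha, beta_period = init$beta_t,
           beta_language = init$beta_l, beta_urban = init$beta_u,
           kappa = exp(init$log_kappa)),
      covariates, age_group = md$age_group)
    if (!is.finite(ll0)) {
      stop("non-finite log posterior at initialization (chain ", ch, "); ",
           "check for incompatible expected counts")
    }
    res <- withr_seed(config$seed + 1000L + ch, {
      run_chain_cpp(md$y, md$E, md$lang, md$urb, nbr0,
                    graph$component_label, fam, use_phi, use_theta,
                    unclass(priors), init,
                    config$iterations, config$burn_in, config$thin,
                    config$adapt_interval)
    })
    colnames(res$draws) <- param_names
    draws[[ch]] <- res$draws
    deviance[[ch]] <- as.numeric(res$deviance)
    if (any(!is.finite(deviance[[ch]]))) {
      stop("non-finite deviance in retained draws (chain ", ch, ")")
    }
  }
  out <- structure(
    list(draws = draws, deviance = deviance, param_names = param_names,
         spec = spec, priors = priors, config = config, data = md,
         graph = graph),
    class = "posterior_chains")
  check_phi_centering(out)
  out
}

# invariant: phi sums to ~0 within each component at every retained draw
check_phi_centering <- function(chains, tol = 1e-8) {
  if (chains$spec$random_effects == "none") return(invisible(TRUE))
  g <- chains$graph
  deg <- lengths(g$neighbors)
  for (ch in chains$draws) {
    phi <- ch[, grep("^phi\\[", colnames(ch)), drop = FALSE]
    for (c_id in seq_len(g$n_components)) {
      members <- which(g$component_label == c_id & deg > 0L)
      if (length(members) < 2L) next
      s <- rowSums(phi[, members, drop = FALSE])
      if (any(abs(s) > tol * max(1, length(members)))) {
        stop("spatial field not centred within component ", c_id)
      }
    }
  }
  invisible(TRUE)
}

#' Pool retained draws of all chains into one matrix
#' @param chains a `posterior_chains` object.
#' @return numeric matrix, rows = pooled draws, named columns.
#' @export
pooled_draws <- function(chains) {
  do.call(rbind, chains$draws)
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf(
    "posterior_chains: %s / %s, %d chain(s) x %d retained draws, %d parameters\n",
    x$spec$family, x$spec$random_effects, length(x$draws),
    nrow(x$draws[[1]]), length(x$param_names)))
  invisible(x)
}

#' Fit one model to every coarse age group
#'
#' The model is fitted separately per age group; this driver loops over
#' the groups present and returns one `posterior_chains` per group.
#'
#' @inheritParams sample_posterior
#' @return named list of `posterior_chains`, one per age group.
#' @export
fit_age_groups <- function(deaths_grouped, expected, covariates, graph,
                           spec = model_spec(), priors = default_priors(),
                           config = mcmc_config()) {
  groups <- intersect(age_groups(), unique(deaths_grouped$age_group))
  if (!length(groups)) groups <- sort(unique(deaths_grouped$age_group))
  out <- lapply(groups, function(gr) {
    sample_posterior(deaths_grouped, expected, covariates, graph,
                     spec, priors, config, age_group = gr)
  })
  stats::setNames(out, groups)
}

#' Persist posterior chains as delimited text
#'
#' Writes one tab-separated draw matrix per chain
#' (`chain<k>_draws.tsv`, named parameter columns), one deviance file per
#' chain, and a YAML manifest recording the model spec, priors, MCMC
#' configuration (including the seed) and the age group fitted —
#' everything needed to audit or re-run the fit.
#'
#' @param chains a `posterior_chains` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_chains <- function(chains, dir) {
  stopifnot(inherits(chains, "posterior_chains"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in seq_along(chains$draws)) {
    utils::write.table(chains$draws[[ch]],
                       file.path(dir, sprintf("chain%d_draws.tsv", ch)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(deviance = chains$deviance[[ch]]),
      file.path(dir, sprintf("chain%d_deviance.tsv", ch)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(
    list(spec = unclass(chains$spec), priors = unclass(chains$priors),
         config = unclass(chains$config),
         age_group = chains$data$age_group,
         n_chains = length(chains$draws),
         parameters = chains$param_names),
    file.path(dir, "chains_manifest.yaml"))
  invisible(dir)
}

#' Gelman-Rubin potential scale reduction diagnostic
#'
#' Classic (non-split) PSRF per scalar parameter across chains, with the
#' finite-sample variance correction. Values above 1.1 are flagged as
#' not converged.
#'
#' @param chains a `posterior_chains` object with >= 2 chains.
#' @param params character vector of parameter names (default: all fixed
#'   effects and variance parameters; pass e.g. `"phi["` prefixes to
#'   inspect the fields).
#' @return data frame with columns `parameter`, `rhat`, `flagged`.
#' @export
gelman_rubin <- function(chains, params = NULL) {
  m <- length(chains$draws)
  if (m < 2L) stop("Gelman-Rubin diagnostic requires at least 2 chains")
  if (is.null(params)) {
    params <- grep("^(phi|theta)\\[", chains$param_names,
                   value = TRUE, invert = TRUE)
  }
  rhat <- vapply(params, function(p) {
    x <- vapply(chains$draws, function(d) d[, p], numeric(nrow(chains$draws[[1]])))
    n <- nrow(x)
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  data.frame(parameter = params, rhat = unname(rhat),
             flagged = unname(rhat) > 1.1, row.names = NULL,
             stringsAsFactors = FALSE)
}
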