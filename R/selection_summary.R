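#' Deviance Information Criterion of a fitted model
#'
#' `dbar` is the posterior mean of the stored per-draw deviances; `dhat`
#' is the deviance at the plug-in posterior mean of all parameters
#' entering the likelihood (intercept, coefficients, spatial and
#' unstructured effects, dispersion) — the "focused" DIC; `pd = dbar -
#' dhat` is the effective number of parameters and `dic = dbar + pd`.
#' Negative `pd` is reported with a flag rather than hidden.
#'
#' @param chains a `posterior_chains` object from [sample_posterior()].
#' @return list of class `dic_result` with `dbar`, `dhat`, `pd`, `dic`,
#'   `pd_negative`.
#' @export
compute_dic <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  dev <- unlist(chains$deviance)
  if (!length(dev)) stop("chains retain no deviance draws")
  dbar <- mean(dev)
  pm <- colMeans(pooled_draws(chains))
  md <- chains$data
  T_ <- length(md$periods)
  params <- list(
    alpha = pm[["alpha"]],
    beta_period = c(0, pm[sprintf("beta_period[%s]", md$periods[-1])]),
    beta_language = c(0, pm[["beta_language[French]"]],
                      pm[["beta_language[ItalianRomansh]"]]),
    beta_urban = c(0, pm[["beta_urban[urban]"]]))
  if (chains$spec$random_effects != "none") {
    params$phi <- stats::setNames(pm[sprintf("phi[%s]", md$units)], md$units)
  }
  if (chains$spec$random_effects == "spatial_unstructured") {
    params$theta <- stats::setNames(pm[sprintf("theta[%s]", md$units)],
                                    md$units)
  }
  if (chains$spec$family == "negbin") params$kappa <- pm[["kappa"]]
  dhat <- -2 * log_likelihood_md(md, chains$spec, params)
  pd <- dbar - dhat
  structure(list(dbar = dbar, dhat = dhat, pd = pd, dic = dbar + pd,
                 pd_negative = pd < 0),
            class = "dic_result")
}

# likelihood straight from prepared model data (avoids re-deriving tables)
log_likelihood_md <- function(md, spec, params) {
  n <- nrow(md$y); T_ <- ncol(md$y)
  phi <- if (is.null(params$phi)) rep(0, n) else unname(params$phi[md$units])
  theta <- if (is.null(params$theta)) rep(0, n) else unname(params$theta[md$units])
  eta <- matrix(params$alpha + phi + theta +
                  params$beta_language[md$lang + 1L] +
                  params$beta_urban[md$urb + 1L], n, T_) +
    matrix(params$beta_period, n, T_, byrow = TRUE)
  mu <- md$E * exp(eta)
  pos <- md$E > 0
  if (spec$family == "poisson") {
    sum(stats::dpois(md$y[pos], mu[pos], log = TRUE))
  } else {
    sum(stats::dnbinom(md$y[pos], size = params$kappa, mu = mu[pos],
                       log = TRUE))
  }
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC %.1f  (Dbar %.1f, pD %.1f%s)\n", x$dic, x$dbar, x$pd,
              if (x$pd_negative) ", pD NEGATIVE" else ""))
  invisible(x)
}

#' Select the best model by DIC
#'
#' Returns the spec with the lowest DIC. Ties are broken toward the
#' simpler model: fewer random-effect sets first, then Poisson over
#' negative binomial.
#'
#' @param results list of `list(spec = model_spec, dic = dic_result)`
#'   entries (at least two).
#' @return the winning entry, with `$index` added.
#' @export
select_model <- function(results) {
  if (length(results) < 2L) {
    stop("model selection needs at least two fitted models")
  }
  dics <- vapply(results, function(r) r$dic$dic, numeric(1))
  n_re <- vapply(results, function(r) {
    switch(r$spec$random_effects, none = 0L, spatial = 1L,
           spatial_unstructured = 2L)
  }, integer(1))
  fam <- vapply(results, function(r) r$spec$family == "negbin", logical(1))
  best <- order(dics, n_re, fam)[1]
  out <- results[[best]]
  out$index <- best
  out
}

#' Posterior SMR-ratio summaries of the fixed effects
#'
#' Per-draw `exp(beta)` summarized by the posterior median and central
#' 95% credible interval; an effect is significant when its interval
#' excludes 1. Reference levels (first period, German, rural) are exactly
#' 1 by construction. The spatial variation is the posterior median and
#' interval of `sigma_phi` (the standard deviation of the spatial random
#' effects; 0 means no spatial correlation).
#'
#' @param chains a `posterior_chains` object.
#' @param prob credible level (default 0.95).
#' @return object of class `smr_summary`: `effects` data frame (`effect`,
#'   `level`, `smr_ratio`, `ci_low`, `ci_high`, `significant`) and
#'   `spatial_variation` (named numeric: estimate, ci_low, ci_high), plus
#'   `sigma_theta` when present.
#' @export
summarize_effects <- function(chains, prob = 0.95) {
  stopifnot(inherits(chains, "posterior_chains"))
  x <- pooled_draws(chains)
  if (nrow(x) < 100) stop("fewer than 100 retained draws; refusing to summarize")
  a <- (1 - prob) / 2
  md <- chains$data
  ref_row <- function(effect, level) {
    data.frame(effect = effect, level = level, smr_ratio = 1,
               ci_low = 1, ci_high = 1, significant = FALSE,
               stringsAsFactors = FALSE)
  }
  coef_row <- function(effect, level, col) {
    q <- stats::quantile(exp(x[, col]), c(a, 0.5, 1 - a), names = FALSE)
    data.frame(effect = effect, level = level, smr_ratio = q[2],
               ci_low = q[1], ci_high = q[3],
               significant = q[1] > 1 || q[3] < 1,
               stringsAsFactors = FALSE)
  }
  rows <- list(ref_row("period", md$periods[1]))
  for (p in md$periods[-1]) {
    rows[[length(rows) + 1L]] <-
      coef_row("period", p, sprintf("beta_period[%s]", p))
  }
  rows[[length(rows) + 1L]] <- ref_row("language", "German")
  rows[[length(rows) + 1L]] <-
    coef_row("language", "French", "beta_language[French]")
  rows[[length(rows) + 1L]] <-
    coef_row("language", "ItalianRomansh", "beta_language[ItalianRomansh]")
  rows[[length(rows) + 1L]] <- ref_row("urbanisation", "rural")
  rows[[length(rows) + 1L]] <-
    coef_row("urbanisation", "urban", "beta_urban[urban]")
  effects <- do.call(rbind, rows)

  out <- list(effects = effects, age_group = md$age_group)
  if (chains$spec$random_effects != "none") {
    q <- stats::quantile(x[, "sigma_phi"], c(a, 0.5, 1 - a), names = FALSE)
    out$spatial_variation <- c(estimate = q[2], ci_low = q[1], ci_high = q[3])
  }
  if (chains$spec$random_effects == "spatial_unstructured") {
    q <- stats::quantile(x[, "sigma_theta"], c(a, 0.5, 1 - a), names = FALSE)
    out$sigma_theta <- c(estimate = q[2], ci_low = q[1], ci_high = q[3])
  }
  if (chains$spec$family == "negbin") {
    q <- stats::quantile(x[, "kappa"], c(a, 0.5, 1 - a), names = FALSE)
    out$dispersion <- c(estimate = q[2], ci_low = q[1], ci_high = q[3])
  }
  structure(out, class = "smr_summary")
}

#' @export
print.smr_summary <- function(x, ...) {
  cat("SMR ratio summary", if (!is.null(x$age_group))
    sprintf("(age group %s)", x$age_group), "\n")
  df <- x$effects
  df$smr_ratio <- sprintf("%.2f", df$smr_ratio)
  df$ci <- sprintf("(%.2f;%.2f)", df$ci_low, df$ci_high)
  print(df[, c("effect", "level", "smr_ratio", "ci", "significant")],
        row.names = FALSE)
  if (!is.null(x$spatial_variation)) {
    cat(sprintf("Spatial variation %.2f (%.2f;%.2f)\n",
                x$spatial_variation[1], x$spatial_variation[2],
                x$spatial_variation[3]))
  }
  invisible(x)
}

#' Smoothed per-unit SMR estimates
#'
#' For every (unit, period) the per-draw `exp(alpha + beta_period +
#' covariate terms + phi (+ theta))` is summarized by its posterior
#' median and central credible interval. Because the spatial field enters
#' the predictor, small units are shrunk toward their neighbourhood —
#' these are the values mapped in a smoothed SMR choropleth.
#'
#' @param chains a `posterior_chains` object.
#' @param prob credible level (default 0.95).
#' @return data frame with columns `unit_id`, `period`, `age_group`,
#'   `smr`, `ci_low`, `ci_high`.
#' @export
smoothed_unit_smr <- function(chains, prob = 0.95) {
  stopifnot(inherits(chains, "posterior_chains"))
  x <- pooled_draws(chains)
  md <- chains$data
  a <- (1 - prob) / 2
  n <- length(md$units); T_ <- length(md$periods)
  base <- x[, "alpha"] +
    cbind(0, x[, c("beta_language[French]", "beta_language[ItalianRomansh]"),
               drop = FALSE])[, md$lang + 1L, drop = FALSE] +
    cbind(0, x[, "beta_urban[urban]"])[, md$urb + 1L, drop = FALSE]
  if (chains$spec$random_effects != "none") {
    base <- base + x[, sprintf("phi[%s]", md$units), drop = FALSE]
  }
  if (chains$spec$random_effects == "spatial_unstructured") {
    base <- base + x[, sprintf("theta[%s]", md$units), drop = FALSE]
  }
  bt <- cbind(0, x[, sprintf("beta_period[%s]", md$periods[-1]),
                  drop = FALSE])
  out <- vector("list", T_)
  for (t in seq_len(T_)) {
    sm <- exp(base + bt[, t])
    q <- apply(sm, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
    out[[t]] <- data.frame(unit_id = md$units, period = md$periods[t],
                           age_group = md$age_group,
                           smr = q[2, ], ci_low = q[1, ], ci_high = q[3, ],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$unit_id, res$period), ]
  rownames(res) <- NULL
  res
}

#' Compare several models on one dataset by DIC
#'
#' Fits each spec with [sample_posterior()] and tabulates the DIC
#' decomposition; the lowest-DIC model (ties broken toward simplicity) is
#' flagged `best`.
#'
#' @param deaths_grouped,expected,covariates,graph as in
#'   [sample_posterior()].
#' @param specs named list of [model_spec()]s (default the four canonical
#'   models).
#' @param priors,config,age_group as in [sample_posterior()].
#' @return list with `table` (data frame: model, family, random_effects,
#'   dbar, pd, dic, best), `fits` (the `posterior_chains`), and `best`
#'   (name of the winner).
#' @export
compare_models_dic <- function(deaths_grouped, expected, covariates, graph,
                               specs = canonical_models(),
                               priors = default_priors(),
                               config = mcmc_config(), age_group = NULL) {
  fits <- lapply(specs, function(sp) {
    sample_posterior(deaths_grouped, expected, covariates, graph, sp,
                     priors, config, age_group = age_group)
  })
  dics <- lapply(fits, compute_dic)
  results <- Map(function(sp, d) list(spec = sp, dic = d), specs, dics)
  win <- select_model(unname(results))
  tab <- data.frame(
    model = names(specs),
    family = vapply(specs, `[[`, "", "family"),
    random_effects = vapply(specs, `[[`, "", "random_effects"),
    dbar = vapply(dics, `[[`, 0, "dbar"),
    pd = vapply(dics, `[[`, 0, "pd"),
    dic = vapply(dics, `[[`, 0, "dic"),
    best = seq_along(specs) == win$index,
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, fits = fits, best = names(specs)[win$index])
}
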