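#' Five-year age bands used throughout the package
#'
#' The 18 standard demographic 5-year bands `0-4` ... `80-84`, `85+`.
#' Indirect standardization operates on these; model fitting operates on
#' the three coarse groups of [default_age_group_map()].
#'
#' @return character vector of band labels, youngest first.
#' @export
age_bands <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

#' Default mapping of 5-year bands to coarse analysis age groups
#'
#' Three groups: `<55` (bands 0-4 ... 50-54), `55-74` (55-59 ... 70-74)
#' and `75+` (75-79, 80-84, 85+).
#'
#' @return named character vector: names are 5-year bands, values coarse
#'   group labels.
#' @export
default_age_group_map <- function() {
  b <- age_bands()
  stats::setNames(c(rep("<55", 11), rep("55-74", 4), rep("75+", 3)), b)
}

#' Coarse age group labels in their natural order
#' @return character vector `c("<55", "55-74", "75+")`.
#' @export
age_groups <- function() c("<55", "55-74", "75+")

#' Default female population age profile over the 5-year bands
#'
#' A stylized western-European female age pyramid: roughly flat through
#' adulthood with attrition at high ages. Proportions over the 18 bands,
#' summing to one. Any nonnegative vector summing to one may be supplied
#' instead wherever a profile is accepted.
#'
#' @return numeric vector of length 18 summing to 1.
#' @export
default_age_profile <- function() {
  w <- c(5, 5, 5.5, 6, 6.5, 6.5, 6.5, 7, 7.5, 7.5, 7, 6.5,
         6, 5.5, 4.5, 3.5, 2.5, 1.5)
  w / sum(w)
}

#' Default national reference mortality rates per 5-year band
#'
#' Stylized age-specific death rates (deaths per person-year) for a female
#' cancer site: negligible below age 30 and rising steeply with age, with
#' magnitudes comparable to registry crude rates of tens to hundreds of
#' deaths per 100,000 person-years in the older groups.
#'
#' @return named numeric vector over [age_bands()].
#' @export
default_reference_rates <- function() {
  r <- c(1e-6, 1e-6, 2e-6, 5e-6, 1e-5, 2e-5,
         5e-5, 1e-4, 2e-4, 3e-4, 4.5e-4,
         6e-4, 7.5e-4, 9e-4, 1.1e-3,
         1.4e-3, 1.7e-3, 2e-3)
  stats::setNames(r, age_bands())
}

#' Simulate census-style person-years at risk
#'
#' Each unit-period total is drawn log-uniformly within `size_range`
#' (mimicking the very heterogeneous municipality sizes of a real mosaic)
#' and split deterministically across the 5-year age bands according to
#' `age_profile`. The population is treated as constant within each
#' period, as when census counts are carried across a 4-year window.
#'
#' @param graph an [adjacency_graph()] of spatial units.
#' @param n_periods number of calendar periods (labelled `P1`, `P2`, ...).
#' @param size_range length-2 numeric, min and max person-years per
#'   unit-period.
#' @param age_profile proportions over [age_bands()], summing to 1.
#' @param seed integer RNG seed; output is a pure function of the inputs
#'   and the seed.
#' @return a `PopulationTable` data frame with columns `unit_id`,
#'   `period`, `age_band`, `person_years`, dense over the full index.
#' @export
simulate_population <- function(graph, n_periods = 5,
                                size_range = c(500, 50000),
                                age_profile = default_age_profile(),
                                seed = 1L) {
  stopifnot(inherits(graph, "adjacency_graph"), n_periods >= 1)
  if (any(size_range <= 0)) stop("size_range must be positive")
  if (size_range[1] > size_range[2]) stop("size_range must be (min, max) with min <= max")
  if (abs(sum(age_profile) - 1) > 1e-9 || any(age_profile < 0)) {
    stop("age_profile must be nonnegative and sum to 1")
  }
  bands <- age_bands()
  if (length(age_profile) != length(bands)) {
    stop("age_profile must have one entry per 5-year band")
  }
  n <- length(graph$units)
  periods <- sprintf("P%d", seq_len(n_periods))
  withr_seed(seed, {
    totals <- exp(stats::runif(n * n_periods,
                               log(size_range[1]), log(size_range[2])))
  })
  idx <- expand.grid(age_band = bands, period = periods,
                     unit_id = graph$units, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, c("unit_id", "period", "age_band")]
  # totals vary by (unit, period); band split is deterministic
  idx$person_years <- rep(totals, each = length(bands)) *
    rep_len(age_profile, nrow(idx))
  rownames(idx) <- NULL
  idx
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Assign language-region and urbanisation covariates to units
#'
#' Language regions are grown as spatially contiguous blocks by a seeded
#' multi-source breadth-first search from randomly chosen roots, so that
#' language is spatially autocorrelated as in the Swiss mosaic; the
#' largest block is labelled `German`, then `French`, then
#' `ItalianRomansh`. Units unreachable from any root (disconnected
#' components) fall to the majority label. Urban status goes to the
#' `urban_fraction` of units with the largest populations, ties broken by
#' unit id.
#'
#' @param graph an [adjacency_graph()].
#' @param language_blocks integer in 1..3, number of language regions.
#' @param urban_fraction proportion of units classified urban, in `[0, 1]`.
#' @param unit_sizes named numeric vector of per-unit population sizes
#'   (e.g. total person-years), used to rank units for urban status.
#' @param seed integer RNG seed.
#' @return data frame with columns `unit_id`, `language` (factor with
#'   levels German, French, ItalianRomansh) and `urbanisation` (factor
#'   with levels rural, urban), one row per unit in graph order.
#' @export
assign_covariates <- function(graph, language_blocks = 3, urban_fraction = 0.3,
                              unit_sizes, seed = 1L) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- length(graph$units)
  if (language_blocks < 1 || language_blocks > 3) stop("language_blocks must be 1, 2 or 3")
  if (n < language_blocks) stop("graph has fewer units than language blocks")
  if (urban_fraction < 0 || urban_fraction > 1) stop("urban_fraction must be in [0, 1]")
  sizes <- unit_sizes[graph$units]
  if (anyNA(sizes)) stop("unit_sizes must be named and cover every unit")

  lab <- integer(n)
  withr_seed(seed, {
    roots <- sample.int(n, language_blocks)
    lab[roots] <- seq_len(language_blocks)
    frontier <- as.list(roots)
    # multi-source BFS; blocks advance in random order each round
    repeat {
      grew <- FALSE
      for (b in sample.int(language_blocks)) {
        newf <- integer(0)
        for (i in frontier[[b]]) {
          for (j in graph$neighbors[[i]]) {
            if (lab[j] == 0L) { lab[j] <- b; newf <- c(newf, j); grew <- TRUE }
          }
        }
        frontier[[b]] <- newf
      }
      if (!grew) break
    }
  })
  lab[lab == 0L] <- which.max(tabulate(lab[lab > 0L], language_blocks))
  # relabel by block size, largest first
  sizes_per_block <- tabulate(lab, language_blocks)
  new_order <- order(-sizes_per_block, seq_len(language_blocks))
  lab <- match(lab, new_order)
  lang_levels <- c("German", "French", "ItalianRomansh")
  language <- factor(lang_levels[lab], levels = lang_levels)

  n_urban <- round(urban_fraction * n)
  ord <- order(-sizes, graph$units, method = "radix")
  urban <- rep("rural", n)
  if (n_urban > 0) urban[ord[seq_len(n_urban)]] <- "urban"
  data.frame(unit_id = graph$units,
             language = language,
             urbanisation = factor(urban, levels = c("rural", "urban")),
             stringsAsFactors = FALSE)
}

#' Draw a spatial field from the intrinsic CAR prior
#'
#' Forward-simulates the improper intrinsic conditional autoregressive
#' (ICAR) prior with conditional variance `sigma_phi^2 / n_i`: on each
#' connected component the field is drawn as a multivariate normal with
#' covariance `sigma_phi^2 * Q^+` where `Q = diag(n_i) - A` is the ICAR
#' precision and `Q^+` its Moore-Penrose pseudoinverse (realized through
#' the eigendecomposition of `Q`, sampling only along directions of
#' nonzero eigenvalue), then re-centred to sum to zero. Degree-0 units get
#' exactly 0.
#'
#' @param graph an [adjacency_graph()].
#' @param sigma_phi conditional standard deviation scale, `>= 0`.
#' @param seed integer RNG seed.
#' @return named numeric vector of per-unit effects, summing to zero
#'   within each component.
#' @export
sample_car_field <- function(graph, sigma_phi, seed = 1L) {
  stopifnot(inherits(graph, "adjacency_graph"), sigma_phi >= 0)
  n <- length(graph$units)
  phi <- stats::setNames(numeric(n), graph$units)
  if (sigma_phi == 0 || n == 0L) return(phi)
  withr_seed(seed, {
    for (c_id in seq_len(graph$n_components)) {
      members <- which(graph$component_label == c_id)
      m <- length(members)
      if (m < 2L) next  # islands / singletons stay at 0
      A <- matrix(0, m, m)
      for (k in seq_len(m)) {
        nb <- match(intersect(graph$neighbors[[members[k]]], members), members)
        A[k, nb] <- 1
      }
      Q <- diag(rowSums(A)) - A
      eg <- eigen(Q, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      z <- stats::rnorm(sum(pos))
      ph <- eg$vectors[, pos, drop = FALSE] %*% (z / sqrt(eg$values[pos]))
      ph <- as.vector(ph) * sigma_phi
      phi[members] <- ph - mean(ph)
    }
  })
  phi
}

#' Ground-truth parameter set for simulation
#'
#' Bundles the generating values of the spatio-temporal SMR model:
#' baseline log-SMR `alpha`, per-period, language and urbanisation log
#' SMR-ratios (first level of each factor is the reference, coefficient
#' 0), the spatial field `phi` (drawn from the ICAR prior), an optional
#' unstructured field `theta`, and the count family. The defaults are the
#' documented synthetic scenario: period SMR ratios declining from 1.0 to
#' 0.3 across five periods (the magnitude range of a strongly improving
#' cause of death), no language effect, urban SMR ratio 0.85, and
#' `sigma_phi = 0.3`.
#'
#' @param graph an [adjacency_graph()].
#' @param period_smr per-period SMR ratios, first element must be 1.
#' @param language_smr SMR ratios for (German, French, ItalianRomansh);
#'   first element must be 1.
#' @param urban_smr SMR ratio of urban vs rural.
#' @param alpha baseline log-SMR.
#' @param sigma_phi,sigma_theta standard deviations of the spatial and
#'   unstructured effects (`sigma_theta = 0` drops theta).
#' @param family `"poisson"` or `"negbin"`.
#' @param dispersion negative binomial dispersion `kappa` (variance
#'   `mu (1 + mu / kappa)`); required when `family = "negbin"`.
#' @param seed integer RNG seed for the random effect draws.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(graph,
                         period_smr = c(1, 0.8, 0.6, 0.45, 0.3),
                         language_smr = c(1, 1, 1),
                         urban_smr = 0.85,
                         alpha = 0,
                         sigma_phi = 0.3,
                         sigma_theta = 0,
                         family = c("poisson", "negbin"),
                         dispersion = NULL,
                         seed = 1L) {
  family <- match.arg(family)
  stopifnot(period_smr[1] == 1, language_smr[1] == 1,
            sigma_phi >= 0, sigma_theta >= 0)
  if (family == "negbin" && (is.null(dispersion) || dispersion <= 0)) {
    stop("negbin family requires a positive dispersion")
  }
  n <- length(graph$units)
  phi <- sample_car_field(graph, sigma_phi, seed = seed)
  theta <- stats::setNames(numeric(n), graph$units)
  if (sigma_theta > 0) {
    withr_seed(seed + 1L, theta[] <- stats::rnorm(n, 0, sigma_theta))
  }
  structure(
    list(alpha = alpha,
         beta_period = log(period_smr),
         beta_language = stats::setNames(log(language_smr),
                                         c("German", "French", "ItalianRomansh")),
         beta_urban = stats::setNames(c(0, log(urban_smr)), c("rural", "urban")),
         phi = phi, theta = theta,
         sigma_phi = sigma_phi, sigma_theta = sigma_theta,
         family = family,
         dispersion = if (family == "negbin") dispersion else NULL),
    class = "ground_truth")
}

#' Simulate death counts from the spatio-temporal SMR model
#'
#' For each (unit, period, 5-year band) cell, the expected count under the
#' reference schedule is `E = person_years * rate(band)` and the simulated
#' count is Poisson (or negative binomial with the stated dispersion) with
#' mean `E * r`, where the log relative risk
#' `log r = alpha + beta_period + beta_language + beta_urban + phi (+ theta)`
#' depends on the unit's covariates and period but not on age: the model
#' is fitted separately per coarse age group, so one shared set of effects
#' keeps every group's truth identical.
#'
#' For the negative binomial family the stated dispersion `kappa`
#' describes the (unit, period, coarse age group) cells that the models
#' are fitted to: each band's count is drawn with a dispersion share
#' proportional to its expected mean, so the bands share a common success
#' probability and their within-group sum is exactly negative binomial
#' with mean `sum(E r)` and dispersion `kappa`. In a group with a single
#' populated band this reduces to plain NB(`E r`, `kappa`) for that band.
#'
#' @param population a `PopulationTable` from [simulate_population()].
#' @param reference_rates named per-band rates, as
#'   [default_reference_rates()].
#' @param truth a [ground_truth()] object.
#' @param covariates per-unit covariate table from [assign_covariates()].
#' @param age_group_map named band-to-coarse-group map; only used to
#'   allocate negative binomial dispersion across bands.
#' @param seed integer RNG seed.
#' @return a `MortalityTable` data frame with columns `unit_id`, `period`,
#'   `age_band`, `deaths`, on the same index as `population`.
#' @export
simulate_deaths <- function(population, reference_rates, truth, covariates,
                            age_group_map = default_age_group_map(),
                            seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(reference_rates < 0)) stop("reference rates must be nonnegative")
  rate <- reference_rates[population$age_band]
  if (anyNA(rate)) stop("reference rate missing for band(s): ",
                        paste(setdiff(unique(population$age_band),
                                      names(reference_rates)), collapse = ", "))
  periods <- sort(unique(population$period))
  if (length(truth$beta_period) != length(periods)) {
    stop("truth has ", length(truth$beta_period), " period effects but the ",
         "population table has ", length(periods), " periods")
  }
  iu <- match(population$unit_id, covariates$unit_id)
  if (anyNA(iu)) stop("covariates missing for unit(s): ",
                      paste(unique(population$unit_id[is.na(iu)]), collapse = ", "))
  if (anyNA(match(population$unit_id, names(truth$phi)))) {
    stop("truth$phi does not cover the population's units")
  }
  eta <- truth$alpha +
    truth$beta_period[match(population$period, periods)] +
    truth$beta_language[as.character(covariates$language[iu])] +
    truth$beta_urban[as.character(covariates$urbanisation[iu])] +
    truth$phi[population$unit_id] + truth$theta[population$unit_id]
  mu <- population$person_years * as.numeric(rate) * exp(eta)
  withr_seed(seed, {
    deaths <- if (truth$family == "poisson") {
      stats::rpois(length(mu), mu)
    } else {
      miss <- setdiff(unique(population$age_band), names(age_group_map))
      if (length(miss)) stop("age band(s) not mapped to a coarse group: ",
                             paste(miss, collapse = ", "))
      grp_key <- paste(population$unit_id, population$period,
                       age_group_map[population$age_band])
      grp_mu <- tapply(mu, grp_key, sum)[grp_key]
      size <- ifelse(grp_mu > 0, truth$dispersion * mu / grp_mu, 0)
      d <- numeric(length(mu))
      pos <- size > 0 & mu > 0
      d[pos] <- stats::rnbinom(sum(pos), size = size[pos], mu = mu[pos])
      d
    }
  })
  out <- population[, c("unit_id", "period", "age_band")]
  out$deaths <- as.numeric(deaths)
  out$deaths[mu == 0] <- 0
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing the documented fixture in one call: a
#' lattice geography, census-style person-years, spatially blocked
#' covariates, an ICAR ground truth and death counts.
#'
#' @param rows,cols lattice dimensions (default 20 x 20).
#' @param n_periods number of periods.
#' @param size_range per-unit-period person-years range.
#' @param truth_args list of overrides passed to [ground_truth()].
#' @param urban_fraction proportion of urban units.
#' @param seed integer master seed; all stages derive their seeds from it.
#' @return list with elements `graph`, `population`, `covariates`,
#'   `truth`, `deaths`, `reference_rates`.
#' @export
simulate_study <- function(rows = 20, cols = 20, n_periods = 5,
                           size_range = c(500, 50000),
                           truth_args = list(), urban_fraction = 0.3,
                           seed = 1L) {
  seed <- as.integer(seed)
  graph <- lattice_graph(rows, cols)
  pop <- simulate_population(graph, n_periods = n_periods,
                             size_range = size_range, seed = seed)
  sizes <- tapply(pop$person_years, pop$unit_id, sum)
  cov <- assign_covariates(graph, language_blocks = 3,
                           urban_fraction = urban_fraction,
                           unit_sizes = sizes, seed = seed + 101L)
  truth <- do.call(ground_truth,
                   c(list(graph = graph, seed = seed + 202L), truth_args))
  if (length(truth$beta_period) != n_periods) {
    stop("truth_args$period_smr must have one entry per period")
  }
  rates <- default_reference_rates()
  deaths <- simulate_deaths(pop, rates, truth, cov, seed = seed + 303L)
  list(graph = graph, population = pop, covariates = cov, truth = truth,
       deaths = deaths, reference_rates = rates)
}

#' Write / read the tabular simulation outputs
#'
#' Tables are stored as UTF-8 delimited text with a header row, columns
#' `unit_id`, `period`, `age_band`, then the value column
#' (`person_years` or `deaths`); ground truth as a YAML key-value file.
#'
#' @param x table or `ground_truth` to write.
#' @param path file path.
#' @return `path` invisibly (writers); the parsed object (readers).
#' @name synthetic_io
NULL

#' @rdname synthetic_io
#' @export
write_count_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_count_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(unit_id = "character", period = "character",
                                   age_band = "character"),
                    stringsAsFactors = FALSE)
}

#' @rdname synthetic_io
#' @export
write_ground_truth <- function(x, path) {
  stopifnot(inherits(x, "ground_truth"))
  y <- unclass(x)
  y$phi <- as.list(y$phi)
  y$theta <- as.list(y$theta)
  y$beta_language <- as.list(y$beta_language)
  y$beta_urban <- as.list(y$beta_urban)
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

#' @rdname synthetic_io
#' @export
read_ground_truth <- function(path) {
  y <- yaml::read_yaml(path)
  y$phi <- unlist(y$phi)
  y$theta <- unlist(y$theta)
  y$beta_language <- unlist(y$beta_language)
  y$beta_urban <- unlist(y$beta_urban)
  y$beta_period <- as.numeric(y$beta_period)
  structure(y, class = "ground_truth")
}
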