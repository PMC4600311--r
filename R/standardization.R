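#' Default calendar-period windows
#'
#' Five 4-year windows around decennial census years, the aggregation used
#' for the Swiss-style analysis: population is assumed constant within
#' each window.
#'
#' @return named list of `c(first_year, last_year)` integer pairs; names
#'   are the period labels.
#' @export
default_period_windows <- function() {
  list("1969-1972" = c(1969L, 1972L),
       "1979-1982" = c(1979L, 1982L),
       "1989-1992" = c(1989L, 1992L),
       "1999-2002" = c(1999L, 2002L),
       "2008-2011" = c(2008L, 2011L))
}

#' Aggregate annual death counts into calendar periods
#'
#' Sums counts over the years of each window; years outside every window
#' are dropped. The output is dense over (units present) x (periods) x
#' (bands present), with zeros where no record fell.
#'
#' @param annual_deaths data frame with columns `unit_id`, `year`,
#'   `age_band`, `deaths`.
#' @param period_windows named list of `c(first, last)` year pairs; must
#'   not overlap.
#' @return a `MortalityTable` data frame keyed by `period` instead of
#'   `year`.
#' @export
aggregate_periods <- function(annual_deaths,
                              period_windows = default_period_windows()) {
  stopifnot(all(c("unit_id", "year", "age_band", "deaths") %in%
                  names(annual_deaths)))
  w <- period_windows
  if (is.null(names(w)) || any(names(w) == "")) stop("period windows must be named")
  yrs <- unlist(lapply(w, function(p) seq(p[1], p[2])))
  if (anyDuplicated(yrs)) stop("period windows overlap")
  year_to_period <- stats::setNames(
    rep(names(w), vapply(w, function(p) p[2] - p[1] + 1L, 1L)), yrs)

  units <- sort(unique(as.character(annual_deaths$unit_id)), method = "radix")
  bands <- intersect(age_bands(), unique(annual_deaths$age_band))
  if (!length(bands)) bands <- sort(unique(annual_deaths$age_band))
  grid <- expand.grid(age_band = bands, period = names(w), unit_id = units,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("unit_id", "period", "age_band")]
  grid$deaths <- 0

  keep <- as.character(annual_deaths$year) %in% names(year_to_period)
  d <- annual_deaths[keep, , drop = FALSE]
  if (nrow(d)) {
    key <- paste(d$unit_id, year_to_period[as.character(d$year)], d$age_band,
                 sep = "\r")
    sums <- tapply(d$deaths, key, sum)
    gkey <- paste(grid$unit_id, grid$period, grid$age_band, sep = "\r")
    hit <- match(gkey, names(sums))
    grid$deaths[!is.na(hit)] <- as.numeric(sums[hit[!is.na(hit)]])
  }
  rownames(grid) <- NULL
  grid
}

#' Apply coding-change correction factors to death counts
#'
#' Multiplies each cell by a configured positive factor (e.g. to undo a
#' systematic over-count caused by a change in cause-of-death coding
#' priority rules), then rounds half-to-even to an integer so that the
#' count likelihood downstream sees integer data. Rounding can be turned
#' off for sensitivity analysis.
#'
#' Factors are resolved per cell from the most specific matching row of
#' `factors`: exact `(age_band, period)`, then wildcard rows where either
#' key is `"*"`. Cells with no matching row default to 1.0 with a single
#' warning.
#'
#' @param deaths a `MortalityTable` data frame (`unit_id`, `period`,
#'   `age_band`, `deaths`).
#' @param factors data frame with columns `age_band`, `period`, `factor`
#'   (either key may be `"*"`), or the path to a delimited file with that
#'   header.
#' @param round_counts round half-to-even to integers (default TRUE).
#' @return corrected `MortalityTable`.
#' @export
apply_coding_correction <- function(deaths, factors, round_counts = TRUE) {
  if (is.character(factors) && length(factors) == 1L) {
    sep <- if (grepl(",", readLines(factors, n = 1L))) "," else ""
    factors <- utils::read.table(factors, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE)
  }
  stopifnot(all(c("age_band", "period", "factor") %in% names(factors)))
  if (any(factors$factor <= 0)) stop("correction factors must be positive")
  lookup <- function(bands, periods) {
    f <- rep(NA_real_, length(bands))
    keyed <- paste(factors$age_band, factors$period)
    wild <- rep("*", length(bands))
    for (key in list(paste(bands, periods), paste(bands, wild),
                     paste(wild, periods), paste(wild, wild))) {
      hit <- match(key, keyed)
      mask <- is.na(f) & !is.na(hit)
      f[mask] <- factors$factor[hit[mask]]
    }
    f
  }
  f <- lookup(deaths$age_band, deaths$period)
  if (anyNA(f)) {
    warning(sum(is.na(f)), " cell(s) had no matching correction factor; using 1.0")
    f[is.na(f)] <- 1
  }
  out <- deaths
  out$deaths <- deaths$deaths * f
  if (round_counts) out$deaths <- round(out$deaths)  # round() is half-to-even
  out
}

#' Nationwide age-specific reference mortality rates
#'
#' Pools deaths and person-years over all units and all periods (a single
#' all-period reference schedule, which makes the fitted period SMR
#' ratios interpretable as temporal trends) and returns the per-band
#' ratio. Bands with zero person-years get rate 0 by convention so that
#' expected counts stay defined everywhere.
#'
#' @param deaths a `MortalityTable` on the 5-year band index.
#' @param population a `PopulationTable` on the same index.
#' @return named numeric vector of rates per [age_bands()] present.
#' @export
compute_reference_rates <- function(deaths, population) {
  if (any(deaths$deaths < 0)) stop("negative death counts")
  if (any(population$person_years < 0)) stop("negative person-years")
  key <- paste(population$unit_id, population$period, population$age_band)
  hit <- match(paste(deaths$unit_id, deaths$period, deaths$age_band), key)
  if (anyNA(hit) || nrow(deaths) != nrow(population)) {
    stop("death and population tables are not on the same index")
  }
  bands <- intersect(age_bands(), unique(population$age_band))
  if (!length(bands)) bands <- sort(unique(population$age_band))
  d <- tapply(deaths$deaths, deaths$age_band, sum)[bands]
  p <- tapply(population$person_years, population$age_band, sum)[bands]
  r <- ifelse(p > 0, d / p, 0)
  stats::setNames(as.numeric(r), bands)
}

#' Indirectly standardized expected death counts
#'
#' `expected(unit, period, group) = sum over the group's 5-year bands of
#' person_years x reference_rate(band)`. When the reference rates come
#' from [compute_reference_rates()] on the same data, total expected
#' equals total observed deaths exactly (the closure identity of indirect
#' standardization).
#'
#' @param population a `PopulationTable`.
#' @param rates named per-band reference rates.
#' @param age_group_map named character vector mapping every band present
#'   to its coarse group (default [default_age_group_map()]).
#' @return an `ExpectedCounts` data frame with columns `unit_id`,
#'   `period`, `age_group`, `expected`.
#' @export
compute_expected <- function(population, rates,
                             age_group_map = default_age_group_map()) {
  miss <- setdiff(unique(population$age_band), names(age_group_map))
  if (length(miss)) stop("age band(s) not mapped to a coarse group: ",
                         paste(miss, collapse = ", "))
  r <- rates[population$age_band]
  if (anyNA(r)) stop("reference rate missing for band(s): ",
                     paste(setdiff(unique(population$age_band), names(rates)),
                           collapse = ", "))
  grp <- age_group_map[population$age_band]
  agg <- stats::aggregate(
    list(expected = population$person_years * as.numeric(r)),
    by = list(unit_id = population$unit_id, period = population$period,
              age_group = grp),
    FUN = sum)
  agg <- agg[order(agg$unit_id, agg$period,
                   match(agg$age_group, age_groups())), ]
  rownames(agg) <- NULL
  agg
}

#' Aggregate a 5-year-band mortality table to coarse age groups
#'
#' @param deaths a `MortalityTable` on the band index.
#' @param age_group_map named band-to-group map.
#' @return data frame `unit_id`, `period`, `age_group`, `deaths`.
#' @export
aggregate_to_age_groups <- function(deaths,
                                    age_group_map = default_age_group_map()) {
  miss <- setdiff(unique(deaths$age_band), names(age_group_map))
  if (length(miss)) stop("age band(s) not mapped to a coarse group: ",
                         paste(miss, collapse = ", "))
  agg <- stats::aggregate(
    list(deaths = deaths$deaths),
    by = list(unit_id = deaths$unit_id, period = deaths$period,
              age_group = age_group_map[deaths$age_band]),
    FUN = sum)
  agg <- agg[order(agg$unit_id, agg$period,
                   match(agg$age_group, age_groups())), ]
  rownames(agg) <- NULL
  agg
}

#' Raw (unsmoothed) standardized mortality ratios
#'
#' Observed over expected per cell. Cells with `expected = 0` are flagged
#' `defined = FALSE` (SMR `NA`) rather than dropped.
#'
#' @param deaths_grouped deaths on the (unit, period, age_group) index.
#' @param expected an `ExpectedCounts` table on the same index.
#' @return data frame with columns `unit_id`, `period`, `age_group`,
#'   `deaths`, `expected`, `smr`, `defined`.
#' @export
raw_smr <- function(deaths_grouped, expected) {
  key_d <- paste(deaths_grouped$unit_id, deaths_grouped$period,
                 deaths_grouped$age_group)
  key_e <- paste(expected$unit_id, expected$period, expected$age_group)
  hit <- match(key_d, key_e)
  if (anyNA(hit) || nrow(deaths_grouped) != nrow(expected)) {
    stop("deaths and expected tables are not on the same index")
  }
  out <- deaths_grouped
  out$expected <- expected$expected[hit]
  out$defined <- out$expected > 0
  out$smr <- ifelse(out$defined, out$deaths / out$expected, NA_real_)
  out
}
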