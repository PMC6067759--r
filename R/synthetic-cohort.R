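# Synthetic county natality cohorts with known ground-truth trend patterns.
#
# No public generative model exists for restricted county natality files, so
# the generator uses the minimal model consistent with rate-of-count data:
# race-specific log-linear rate trajectories with binomially sampled LBW
# counts given fixed annual births. An optional log-normal multiplier adds
# rate over-dispersion (off by default).

#' The five disparity-trend patterns
#'
#' @return Character vector of valid pattern labels, in rule-evaluation
#'   order, plus `"unclassified"` for fits matching no rule.
#' @export
trend_patterns <- function() {
  c("convergent_black_improving", "convergent_white_worsening",
    "divergent", "persistent_disparity", "sustained_equality")
}

#' Construct a county scenario
#'
#' A scenario fixes one synthetic county's ground truth: baseline LBW rates
#' per 100 births (at the first study year) and per-year log-rate slopes for
#' each race, plus constant annual birth volumes. Implied rates must stay in
#' (0, 100) across the horizon checked at simulation time.
#'
#' @param county_id Identifier string.
#' @param baseline_rate_white,baseline_rate_black Baseline LBW rates per 100
#'   births, in (0, 100).
#' @param slope_white,slope_black Per-year change in log rate.
#' @param births_white_per_year,births_black_per_year Annual live births
#'   (positive integers).
#' @param true_pattern The trend-pattern label implied by the parameters.
#' @param dispersion_sd Standard deviation of an optional log-normal
#'   multiplier on the annual rate (0 = pure binomial noise).
#' @return An object of class `county_scenario`.
#' @export
county_scenario <- function(county_id, baseline_rate_white,
                            baseline_rate_black, slope_white, slope_black,
                            births_white_per_year, births_black_per_year,
                            true_pattern, dispersion_sd = 0) {
  stopifnot(baseline_rate_white > 0, baseline_rate_white < 100,
            baseline_rate_black > 0, baseline_rate_black < 100,
            births_white_per_year >= 1, births_black_per_year >= 1,
            dispersion_sd >= 0)
  true_pattern <- match.arg(true_pattern, trend_patterns())
  structure(list(
    county_id = as.character(county_id),
    baseline_rate_white = baseline_rate_white,
    baseline_rate_black = baseline_rate_black,
    slope_white = slope_white,
    slope_black = slope_black,
    births_white_per_year = as.integer(births_white_per_year),
    births_black_per_year = as.integer(births_black_per_year),
    true_pattern = true_pattern,
    dispersion_sd = dispersion_sd), class = "county_scenario")
}

#' Archetype scenario for a disparity-trend pattern
#'
#' Returns a scenario whose noiseless rate trajectories satisfy the defining
#' inequalities of the requested pattern:
#' \describe{
#'   \item{convergent_black_improving}{black rate declining (10.5 to about
#'     3.9 per 100 over 11 years), white flat at 7.0; interaction negative.}
#'   \item{convergent_white_worsening}{black flat at 15.0, white rising from
#'     5.0 at +0.05/yr; interaction negative.}
#'   \item{divergent}{black rising from 13.0 at +0.05/yr, white flat at 7.0;
#'     interaction positive.}
#'   \item{persistent_disparity}{parallel flat lines, black 13.4 vs white
#'     7.0 (baseline log-gap about 0.65).}
#'   \item{sustained_equality}{identical parameters for both races (7.0,
#'     flat).}
#' }
#'
#' @param pattern One of [trend_patterns()].
#' @param births_per_year Annual births per race group (default 50000).
#' @param county_id Identifier (default derived from the pattern).
#' @param dispersion_sd Passed to [county_scenario()].
#' @return A `county_scenario` with `true_pattern = pattern`.
#' @export
make_archetype <- function(pattern, births_per_year = 50000,
                           county_id = NULL, dispersion_sd = 0) {
  if (length(pattern) != 1 || !pattern %in% trend_patterns()) {
    stop("unknown pattern '", paste(pattern, collapse = ","),
         "'; valid patterns: ", paste(trend_patterns(), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(county_id)) county_id <- pattern
  par <- switch(pattern,
    convergent_black_improving = list(bw = 7.0, bb = 10.5,
      sw = 0, sb = log(3.9 / 10.5) / 10),
    convergent_white_worsening = list(bw = 5.0, bb = 15.0,
      sw = 0.05, sb = 0),
    divergent = list(bw = 7.0, bb = 13.0, sw = 0, sb = 0.05),
    persistent_disparity = list(bw = 7.0, bb = 13.4, sw = 0, sb = 0),
    sustained_equality = list(bw = 7.0, bb = 7.0, sw = 0, sb = 0))
  county_scenario(county_id,
                  baseline_rate_white = par$bw, baseline_rate_black = par$bb,
                  slope_white = par$sw, slope_black = par$sb,
                  births_white_per_year = births_per_year,
                  births_black_per_year = births_per_year,
                  true_pattern = pattern, dispersion_sd = dispersion_sd)
}

# Deterministic 31-bit stream seed for a county, derived from the master
# seed and the county id, so adding or reordering counties leaves the other
# counties' draws unchanged.
county_stream_seed <- function(seed, county_id) {
  h <- 0
  for (code in utf8ToInt(county_id)) h <- (h * 131 + code) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 7919) %% 2147483647)
}

scenario_rates <- function(scenario, t) {
  list(white = scenario$baseline_rate_white * exp(scenario$slope_white * t),
       black = scenario$baseline_rate_black * exp(scenario$slope_black * t))
}

#' Simulate a county-year-race natality panel
#'
#' For each county, year and race, annual births are fixed by the scenario
#' and LBW births are drawn binomially with success probability `rate/100`,
#' where the rate follows the scenario's log-linear trajectory
#' `baseline * exp(slope * t)`, `t = year - start_year`. All randomness is
#' governed by `seed` through per-county streams.
#'
#' @param scenarios A `county_scenario` or list of them.
#' @param start_year,end_year Inclusive simulation horizon
#'   (default 2003-2013, 11 annual points).
#' @param seed Master seed (integer).
#' @return A validated natality tibble sorted by county, year, race.
#' @export
simulate_dataset <- function(scenarios, start_year = 2003, end_year = 2013,
                             seed = 1) {
  if (inherits(scenarios, "county_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) > 0, end_year >= start_year)
  years <- start_year:end_year
  t <- years - start_year

  out <- lapply(scenarios, function(sc) {
    stopifnot(inherits(sc, "county_scenario"))
    if (sc$births_white_per_year < 1 || sc$births_black_per_year < 1) {
      stop("county ", sc$county_id, ": births per year must be >= 1",
           call. = FALSE)
    }
    rates <- scenario_rates(sc, t)
    p <- c(rates$black, rates$white) / 100
    if (any(p <= 0 | p >= 1)) {
      stop("county ", sc$county_id,
           ": implied LBW probability outside (0, 1) within the horizon",
           call. = FALSE)
    }
    withr_seed <- county_stream_seed(seed, sc$county_id)
    old <- globalenv()$.Random.seed
    set.seed(withr_seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    draw_cell <- function(n, rate) {
      if (sc$dispersion_sd > 0) {
        rate <- pmin(rate * exp(stats::rnorm(length(rate), 0,
                                             sc$dispersion_sd) -
                                  sc$dispersion_sd^2 / 2), 99.999)
      }
      stats::rbinom(length(rate), n, rate / 100)
    }
    tibble::tibble(
      county_id = sc$county_id, state = "",
      year = rep(years, each = 2),
      race = rep(c("black", "white"), length(years)),
      births = rep(c(sc$births_black_per_year, sc$births_white_per_year),
                   length(years)),
      lbw_births = as.vector(rbind(
        draw_cell(sc$births_black_per_year, rates$black),
        draw_cell(sc$births_white_per_year, rates$white))))
  })
  validate_natality(dplyr::bind_rows(out))
}

#' Read or write scenario files
#'
#' Scenarios serialise to YAML as one mapping per county with keys matching
#' the `county_scenario` fields.
#'
#' @param scenarios List of `county_scenario` objects.
#' @param path YAML file path.
#' @return `write_scenarios` returns `path` invisibly; `read_scenarios`
#'   returns a list of `county_scenario` objects.
#' @export
write_scenarios <- function(scenarios, path) {
  if (inherits(scenarios, "county_scenario")) scenarios <- list(scenarios)
  yaml::write_yaml(lapply(scenarios, unclass), path)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  lapply(yaml::read_yaml(path), function(x) do.call(county_scenario, x))
}
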