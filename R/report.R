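# Pipeline orchestration and summary outputs: pattern-count summary,
# two-year county detail, aggregated convergent-county rate series and the
# counterfactual table.

#' Analysis configuration
#'
#' @param start_year,end_year Analysis horizon (defaults 2003, 2013).
#' @param alpha Two-tailed significance threshold (default 0.005).
#' @param min_lbw Eligibility minimum LBW births per race-year cell
#'   (default 10).
#' @param cost_per_stay Dollars per LBW hospitalization stay (default
#'   15100).
#' @param rounding_mode `"full_precision"` or `"printed_precision"`; see
#'   [disparity_table()].
#' @param seed Master seed for any simulation the run performs.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(start_year = 2003, end_year = 2013,
                            alpha = 0.005, min_lbw = 10,
                            cost_per_stay = 15100,
                            rounding_mode = c("full_precision",
                                              "printed_precision"),
                            seed = 1) {
  rounding_mode <- match.arg(rounding_mode)
  stopifnot(start_year < end_year, alpha > 0, alpha < 1, min_lbw >= 1,
            cost_per_stay > 0)
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year), alpha = alpha,
                 min_lbw = as.integer(min_lbw),
                 cost_per_stay = cost_per_stay,
                 rounding_mode = rounding_mode,
                 seed = as.integer(seed)), class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' Keys matching [analysis_config()] arguments override the defaults.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' Count-weighted aggregate rate series for a set of counties
#'
#' For each year and race, the aggregate rate is
#' `100 * sum(member LBW births) / sum(member births)` over the member
#' counties — a count-weighted aggregation, not a mean of rates, so larger
#' counties carry proportionally more weight.
#'
#' @param records Validated natality records covering all members.
#' @param members Non-empty character vector of county ids.
#' @return A tibble with `year`, `race`, `births`, `lbw_births`, `rate`.
#' @export
aggregate_category_series <- function(records, members) {
  records <- validate_natality(records)
  if (length(members) == 0) stop("members must be non-empty", call. = FALSE)
  absent <- setdiff(members, unique(records$county_id))
  if (length(absent) > 0) {
    stop("no records for member county: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  records |>
    dplyr::filter(.data$county_id %in% members) |>
    dplyr::group_by(.data$year, .data$race) |>
    dplyr::summarise(births = sum(.data$births),
                     lbw_births = sum(.data$lbw_births), .groups = "drop") |>
    dplyr::mutate(rate = compute_rate(.data$births, .data$lbw_births)) |>
    dplyr::arrange(.data$year, .data$race)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full disparity-trend pipeline
#'
#' Eligibility filter, per-county trend fits, pattern classification,
#' two-year disparity metrics, counterfactual averted births, and the
#' aggregated rate series for convergent (black-improving) counties.
#' Deterministic given the input records and configuration; stage-tagged
#' progress is logged via `message()`.
#'
#' @param records A validated natality tibble, or a path to a natality CSV.
#' @param config An [analysis_config()].
#' @return A list of class `report_bundle`: `config`, `excluded`
#'   (eligibility report), `fits` (coefficient table), `classification`
#'   (per-county categories), `table1_summary` (category counts),
#'   `table2_detail` (start/end-year disparity metrics for convergent
#'   black-improving counties, or all counties if none), `fig1_series`
#'   (aggregated convergent-county rates; NULL if no convergent county),
#'   and `averted` (counterfactual summary). If no county passes
#'   eligibility, classification tables are empty and a warning is issued.
#' @export
run_pipeline <- function(records, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(records)) records <- read_natality_csv(records)
  records <- validate_natality(records)
  horizon <- config$start_year:config$end_year
  pipeline_log("read", "%d records, %d counties", nrow(records),
               length(unique(records$county_id)))

  flt <- apply_eligibility_filter(records, min_lbw = config$min_lbw,
                                  horizon = horizon)
  pipeline_log("filter", "%d counties kept, %d excluded",
               length(unique(flt$kept$county_id)), nrow(flt$excluded))
  if (nrow(flt$kept) == 0) {
    warning("no county passed the eligibility filter", call. = FALSE)
    cls <- classify_dataset(flt$kept, alpha = config$alpha)
    return(structure(list(config = config, excluded = flt$excluded,
                          fits = NULL, classification = cls$counties,
                          table1_summary = cls$summary,
                          table2_detail = NULL, fig1_series = NULL,
                          averted = NULL), class = "report_bundle"))
  }

  fits <- fit_all_counties(flt$kept, alpha = config$alpha)
  cls <- classify_dataset(flt$kept, alpha = config$alpha)
  pipeline_log("classify", "%s",
               paste(cls$summary$category, cls$summary$n, sep = "=",
                     collapse = ", "))

  convergent <- cls$counties$county_id[
    cls$counties$category == "convergent_black_improving"]
  detail_ids <- if (length(convergent) > 0) convergent else
    unique(flt$kept$county_id)
  # national row aggregates every eligible county, not just the subset shown
  table2 <- dplyr::bind_rows(
    disparity_table(
      dplyr::filter(flt$kept, .data$county_id %in% detail_ids),
      config$start_year, config$end_year,
      rounding_mode = config$rounding_mode, national = FALSE),
    dplyr::filter(
      disparity_table(flt$kept, config$start_year, config$end_year,
                      rounding_mode = config$rounding_mode),
      .data$county_id == "National"))
  fig1 <- if (length(convergent) > 0) {
    aggregate_category_series(flt$kept, convergent)
  }
  averted <- averted_summary(flt$kept, cost_per_stay = config$cost_per_stay)
  pipeline_log("avert", "total averted %.1f, projected cost %.0f",
               averted$total_averted, averted$projected_cost_avoided)

  structure(list(config = config, excluded = flt$excluded,
                 fits = trend_fit_table(fits),
                 classification = cls$counties,
                 table1_summary = cls$summary, table2_detail = table2,
                 fig1_series = fig1, averted = averted),
            class = "report_bundle")
}

#' Write a report bundle to CSV files
#'
#' Writes `table1_summary.csv`, `table2_detail.csv`, `fig1_series.csv`,
#' `averted.csv`, `classification.csv`, `fits.csv` and `excluded.csv`
#' (components that are NULL are skipped).
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(table1_summary = bundle$table1_summary,
              table2_detail = bundle$table2_detail,
              fig1_series = bundle$fig1_series,
              averted = bundle$averted$by_cell,
              classification = bundle$classification,
              fits = bundle$fits, excluded = bundle$excluded)
  for (name in names(out)) {
    if (!is.null(out[[name]])) {
      utils::write.csv(out[[name]], file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' Published two-year county LBW rates for replication checks
#'
#' Loads the package's copy of published 2003/2013 one-decimal LBW rates
#' (per 100 births) for four convergent-trend U.S. counties and the
#' national average, used by the printed-precision replication mode of the
#' disparity metrics.
#'
#' @return A tibble with `county_id`, `year`, `rate_white`, `rate_black`.
#' @export
table2_printed <- function() {
  path <- system.file("extdata", "table2_printed.csv",
                      package = "lbwtrends", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
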