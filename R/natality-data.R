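# County-year-race natality records: schema, validation, CSV I/O, and the
# eligibility filter used before trend modelling.

NATALITY_COLUMNS <- c("county_id", "state", "year", "race", "births", "lbw_births")
RACE_LEVELS <- c("black", "white")

#' Validate a table of county-year-race natality counts
#'
#' Checks the natality schema: required columns, lowercase `black`/`white`
#' race codes, non-negative integer counts with `lbw_births <= births`, and
#' uniqueness of the (county, year, race) key. Invalid rows abort with the
#' offending row index or key.
#'
#' @param records A data frame with columns `county_id`, `state`, `year`,
#'   `race`, `births`, `lbw_births`.
#' @return The validated records as a tibble, sorted by county, year, race.
#' @export
validate_natality <- function(records) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(NATALITY_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("natality records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # an optional `population` column is accepted upstream and dropped here
  records <- records[NATALITY_COLUMNS]
  records$county_id <- as.character(records$county_id)
  records$state <- as.character(records$state)

  bad_race <- which(!records$race %in% RACE_LEVELS)
  if (length(bad_race) > 0) {
    stop(sprintf("row %d: race '%s' is not one of %s", bad_race[1],
                 records$race[bad_race[1]],
                 paste(RACE_LEVELS, collapse = "/")), call. = FALSE)
  }
  for (col in c("year", "births", "lbw_births")) {
    v <- records[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop(sprintf("row %d: %s = %s is not a non-negative integer",
                   bad[1], col, format(v[bad[1]])), call. = FALSE)
    }
    records[[col]] <- as.integer(round(v))
  }
  bad_lbw <- which(records$lbw_births > records$births)
  if (length(bad_lbw) > 0) {
    stop(sprintf("row %d: lbw_births (%d) exceeds births (%d)",
                 bad_lbw[1], records$lbw_births[bad_lbw[1]],
                 records$births[bad_lbw[1]]), call. = FALSE)
  }

  key <- paste(records$county_id, records$year, records$race, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop("duplicate (county, year, race) key: ", dup[1], call. = FALSE)
  }
  dplyr::arrange(records, .data$county_id, .data$year, .data$race)
}

#' Read a natality CSV
#'
#' Reads county-year-race natality counts from the package's CSV schema
#' (`county_id,state,year,race,births,lbw_births`; race lowercase
#' `black`/`white`) and validates every row. An extra `population` column is
#' tolerated and ignored.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of natality records.
#' @export
read_natality_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(county_id = "character"))
  validate_natality(raw)
}

#' Write natality records to CSV
#'
#' @param records Validated natality records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_natality_csv <- function(records, path) {
  records <- validate_natality(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' LBW rate per 100 live births
#'
#' @param births Total live births (> 0).
#' @param lbw_births Low-birthweight births.
#' @return `100 * lbw_births / births`, vectorised.
#' @examples
#' compute_rate(1000, 70) # 7.0
#' @export
compute_rate <- function(births, lbw_births) {
  if (any(births == 0)) {
    stop("rate undefined when births = 0", call. = FALSE)
  }
  100 * lbw_births / births
}

#' Apply the minimum-LBW eligibility filter
#'
#' A county enters the analysis only if, for every year of the horizon and
#' for both race groups, its (county, year, race) cell is present and has at
#' least `min_lbw` LBW births. This mirrors the confidentiality-driven
#' suppression rule used with restricted county natality files; a missing
#' race-year cell fails the filter rather than being imputed, so the kept
#' panel is complete and balanced.
#'
#' @param records Validated natality records.
#' @param min_lbw Minimum LBW births required in each race-year cell
#'   (default 10).
#' @param horizon Integer vector of analysis years (default: all years
#'   present in `records`).
#' @return A list with `kept` (records of eligible counties, restricted to
#'   the horizon) and `excluded` (one row per excluded county:
#'   `county_id`, `first_failing_year`, `failing_race`, `lbw_births`;
#'   `lbw_births` is `NA` when the cell is absent).
#' @export
apply_eligibility_filter <- function(records, min_lbw = 10, horizon = NULL) {
  records <- validate_natality(records)
  if (is.null(horizon)) horizon <- sort(unique(records$year))
  horizon <- sort(unique(as.integer(horizon)))
  if (length(horizon) == 0) stop("empty analysis horizon", call. = FALSE)
  records <- dplyr::filter(records, .data$year %in% horizon)

  grid <- tidyr::expand_grid(year = horizon, race = RACE_LEVELS)
  excluded <- list()
  keep <- character(0)
  for (cid in unique(records$county_id)) {
    cells <- dplyr::left_join(grid,
      dplyr::filter(records, .data$county_id == cid),
      by = c("year", "race"))
    fail <- which(is.na(cells$lbw_births) | cells$lbw_births < min_lbw)
    if (length(fail) == 0) {
      keep <- c(keep, cid)
    } else {
      f <- fail[1]
      excluded[[cid]] <- tibble::tibble(
        county_id = cid,
        first_failing_year = cells$year[f],
        failing_race = cells$race[f],
        lbw_births = cells$lbw_births[f])
    }
  }
  list(
    kept = dplyr::filter(records, .data$county_id %in% keep),
    excluded = if (length(excluded) > 0) dplyr::bind_rows(excluded) else
      tibble::tibble(county_id = character(0),
                     first_failing_year = integer(0),
                     failing_race = character(0),
                     lbw_births = integer(0)))
}

#' Annual LBW rate series for one county and race
#'
#' @param records Validated natality records.
#' @param county One county id.
#' @param race `"black"` or `"white"`.
#' @return A tibble with `county_id`, `race`, `year`, `rate` (per 100
#'   births), years strictly increasing.
#' @export
rate_series <- function(records, county, race) {
  race <- match.arg(race, RACE_LEVELS)
  rows <- dplyr::filter(records, .data$county_id == county,
                        .data$race == !!race)
  if (nrow(rows) == 0) {
    stop("no records for county ", county, ", race ", race, call. = FALSE)
  }
  rows <- dplyr::arrange(rows, .data$year)
  tibble::tibble(county_id = county, race = race, year = rows$year,
                 rate = compute_rate(rows$births, rows$lbw_births))
}
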