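# Rate ratios and percent-change disparity statistics.

#' Black-white rate ratio
#'
#' @param rate_black,rate_white LBW rates per 100 births; `rate_white` must
#'   be positive.
#' @return `rate_black / rate_white` (dimensionless), vectorised.
#' @examples
#' rate_ratio(10.5, 4.2) # 2.5
#' @export
rate_ratio <- function(rate_black, rate_white) {
  if (any(rate_white == 0)) {
    stop("rate ratio undefined when the white rate is 0", call. = FALSE)
  }
  rate_black / rate_white
}

#' Percent change in an LBW rate
#'
#' `(rate_end - rate_start) / rate_start * 100`.
#'
#' @param rate_start,rate_end Rates per 100 births; `rate_start` must be
#'   positive.
#' @return Percent change, vectorised.
#' @examples
#' pct_change_rate(4.2, 5.6) # 33.33...
#' @export
pct_change_rate <- function(rate_start, rate_end) {
  if (any(rate_start == 0)) {
    stop("percent change undefined when the baseline rate is 0",
         call. = FALSE)
  }
  (rate_end - rate_start) / rate_start * 100
}

#' Percent change in the rate ratio relative to baseline excess disparity
#'
#' `(rr_end - rr_start) / (rr_start - 1) * 100`: the change in the
#' black-white rate ratio expressed as a percentage of the baseline excess
#' disparity (RR - 1). Negative values are progress; -100 means the gap
#' fully closed; values below -100 mean the ratio crossed below 1.
#'
#' @param rr_start,rr_end Rate ratios; `rr_start` must not equal 1 (zero
#'   baseline excess leaves the statistic undefined). A baseline ratio below
#'   1 (white rate above black) is allowed arithmetically but warned about,
#'   since the "excess" is then negative.
#' @return Percent of baseline excess disparity, vectorised.
#' @examples
#' pct_change_rate_ratio(2.5, 0.7) # -120
#' @export
pct_change_rate_ratio <- function(rr_start, rr_end) {
  if (any(rr_start == 1)) {
    stop("excess-disparity change undefined when the baseline rate ratio is 1",
         call. = FALSE)
  }
  if (any(rr_start < 1 & rr_start > 0)) {
    warning("baseline rate ratio below 1: baseline excess disparity is ",
            "negative, interpret the sign with care", call. = FALSE)
  }
  (rr_end - rr_start) / (rr_start - 1) * 100
}

#' Disparity summary between two years
#'
#' Builds a county-by-county table comparing race-specific LBW rates and
#' the black-white rate ratio between two years, with both percent-change
#' statistics, plus a national row aggregated from summed counts.
#'
#' Two rounding modes are supported. `"full_precision"` (the default for
#' analysis) carries rates and ratios at full precision. In
#' `"printed_precision"` mode rates are first rounded to one decimal, rate
#' ratios are computed from the rounded rates and themselves rounded to one
#' decimal before the excess-disparity formula, and all outputs are reported
#' to one decimal — the convention under which published one-decimal tables
#' are reproduced exactly.
#'
#' @param records Validated natality records covering both years.
#' @param year_start,year_end The two comparison years.
#' @param rounding_mode `"full_precision"` or `"printed_precision"`.
#' @param national Add a `"National"` row aggregated from summed counts
#'   (default TRUE).
#' @return A tibble with one row per county (plus the national row):
#'   `county_id`, `rate_white_start`, `rate_white_end`, `pct_change_white`,
#'   `rate_black_start`, `rate_black_end`, `pct_change_black`, `rr_start`,
#'   `rr_end`, `pct_change_rr`.
#' @export
disparity_table <- function(records, year_start, year_end,
                            rounding_mode = c("full_precision",
                                              "printed_precision"),
                            national = TRUE) {
  rounding_mode <- match.arg(rounding_mode)
  records <- validate_natality(records)
  both <- dplyr::filter(records, .data$year %in% c(year_start, year_end))
  if (national && nrow(both) > 0) {
    nat <- both |>
      dplyr::group_by(.data$year, .data$race) |>
      dplyr::summarise(births = sum(.data$births),
                       lbw_births = sum(.data$lbw_births), .groups = "drop") |>
      dplyr::mutate(county_id = "National", state = "")
    both <- dplyr::bind_rows(both, nat)
  }
  wide <- both |>
    dplyr::mutate(rate = compute_rate(.data$births, .data$lbw_births),
                  when = ifelse(.data$year == year_start, "start", "end")) |>
    dplyr::select("county_id", "race", "when", "rate") |>
    tidyr::pivot_wider(names_from = c("race", "when"), values_from = "rate",
                       names_glue = "rate_{race}_{when}")
  if (anyNA(wide)) {
    stop("every county needs both races observed in both comparison years",
         call. = FALSE)
  }
  if (rounding_mode == "printed_precision") {
    wide <- dplyr::mutate(wide, dplyr::across(dplyr::starts_with("rate_"),
                                              \(x) round(x, 1)))
  }
  out <- wide |>
    dplyr::mutate(
      pct_change_white = pct_change_rate(.data$rate_white_start,
                                         .data$rate_white_end),
      pct_change_black = pct_change_rate(.data$rate_black_start,
                                         .data$rate_black_end),
      rr_start = rate_ratio(.data$rate_black_start, .data$rate_white_start),
      rr_end = rate_ratio(.data$rate_black_end, .data$rate_white_end))
  if (rounding_mode == "printed_precision") {
    out <- dplyr::mutate(out, rr_start = round(.data$rr_start, 1),
                         rr_end = round(.data$rr_end, 1))
  }
  # a baseline ratio of exactly 1 leaves the excess-disparity change
  # undefined for that county; report NA rather than aborting the table
  out <- dplyr::mutate(out,
    pct_change_rr = ifelse(.data$rr_start == 1, NA_real_,
                           (.data$rr_end - .data$rr_start) /
                             (.data$rr_start - 1) * 100))
  if (rounding_mode == "printed_precision") {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            \(x) round(x, 1)))
  }
  dplyr::select(out, "county_id",
                "rate_white_start", "rate_white_end", "pct_change_white",
                "rate_black_start", "rate_black_end", "pct_change_black",
                "rr_start", "rr_end", "pct_change_rr")
}
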