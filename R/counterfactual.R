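# Counterfactual averted black LBW births and hospitalization-cost
# projection. For each county-year, the averted count is the number of
# observed black LBW births in excess of what the county's white rate would
# have produced on the black birth volume:
#   averted = lbw_black - (rate_white / 100) * births_black.
# Negative cells (black outcome better than white) are retained by default,
# so totals are net figures; a truncated variant is exposed for sensitivity
# reporting.

#' Averted black LBW births for one cell
#'
#' @param lbw_black Observed black LBW births.
#' @param births_black Total black births (>= 0).
#' @param rate_white White LBW rate per 100 births, in `[0, 100]`.
#' @return `lbw_black - (rate_white / 100) * births_black`, vectorised;
#'   negative when the black rate is below the white rate.
#' @examples
#' averted_births(130, 1000, 7.0) # 60
#' @export
averted_births <- function(lbw_black, births_black, rate_white) {
  stopifnot(all(births_black >= 0), all(rate_white >= 0),
            all(rate_white <= 100))
  # multiply before dividing so the equal-rates null is exactly zero for
  # integer count inputs
  lbw_black - rate_white * births_black / 100
}

#' Averted-birth table and totals for a natality panel
#'
#' Applies the cell-wise counterfactual to every county-year and sums,
#' keeping full precision (summation before any rounding).
#'
#' @param records Validated natality records with both races present for
#'   every county-year.
#' @param truncate_negative If TRUE, floor each cell at zero before
#'   totalling (sensitivity variant); default FALSE retains negative
#'   contributions.
#' @param cost_per_stay Dollar cost per LBW hospitalization stay used for
#'   the projection (default 15100, an intentionally conservative
#'   2001-dollar figure; 22953.76 is the 2012 inflation-adjusted
#'   alternative).
#' @return A list with `by_cell` (tibble: `county_id`, `year`,
#'   `averted_births`), `by_county` (county totals), `total_averted`, and
#'   `projected_cost_avoided = total_averted * cost_per_stay`.
#' @export
averted_summary <- function(records, truncate_negative = FALSE,
                            cost_per_stay = 15100) {
  records <- validate_natality(records)
  wide <- records |>
    dplyr::select("county_id", "year", "race", "births", "lbw_births") |>
    tidyr::pivot_wider(names_from = "race",
                       values_from = c("births", "lbw_births"))
  if (anyNA(wide)) {
    stop("both races must be observed in every county-year", call. = FALSE)
  }
  by_cell <- wide |>
    dplyr::mutate(averted_births = averted_births(
      .data$lbw_births_black, .data$births_black,
      compute_rate(.data$births_white, .data$lbw_births_white))) |>
    dplyr::select("county_id", "year", "averted_births")
  if (truncate_negative) {
    by_cell$averted_births <- pmax(by_cell$averted_births, 0)
  }
  by_county <- by_cell |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(averted_births = sum(.data$averted_births),
                     .groups = "drop")
  total <- sum(by_cell$averted_births)
  list(by_cell = by_cell, by_county = by_county, total_averted = total,
       projected_cost_avoided = project_cost(total, cost_per_stay))
}

#' Project hospitalization costs avoided
#'
#' @param total_averted Total averted LBW births.
#' @param cost_per_stay Dollars per LBW hospitalization stay (> 0).
#' @return `total_averted * cost_per_stay`, in dollars.
#' @examples
#' project_cost(371176, 15100) # 5,604,757,600
#' @export
project_cost <- function(total_averted, cost_per_stay = 15100) {
  stopifnot(cost_per_stay > 0)
  total_averted * cost_per_stay
}
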