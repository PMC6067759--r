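# Decision rules mapping per-county trend fits to the five disparity-trend
# patterns. Rules are evaluated in a fixed order; the first match wins, and
# fits matching no rule are surfaced as "unclassified" with a rationale
# rather than forced into a pattern.

sig_flag <- function(fit, term) {
  p <- fit$p[[term]]
  est <- fit[[term]]
  if (is.na(p) || p >= fit$alpha) "flat"
  else if (est < 0) "sig_neg"
  else "sig_pos"
}

#' Classify one county's disparity-trend pattern
#'
#' Applies the pattern decision rules to a full-model fit (for the slopes
#' and interaction) and a reduced-model fit (for the baseline intercept
#' gap), both at the same significance threshold. In order:
#'
#' 1. `convergent_black_improving` — interaction significantly negative,
#'    black slope significantly negative, white slope flat.
#' 2. `convergent_white_worsening` — interaction significantly negative,
#'    white slope significantly positive, black slope significantly
#'    negative or flat.
#' 3. `divergent` — interaction significantly positive, black slope flat or
#'    significantly positive, white slope significantly negative or flat.
#' 4. Interaction not significant: `sustained_equality` if the
#'    reduced-model race shift is not significant, `persistent_disparity`
#'    if it is significantly positive (black above white).
#' 5. Anything else (e.g. a significantly negative race shift, or a
#'    significant interaction whose slope signs match no rule) —
#'    `unclassified`, with the fired flags recorded as rationale.
#'
#' "Flat" means the two-tailed test fails to reject zero at the fits'
#' alpha.
#'
#' @param fit_full A full-model `trend_fit` from [fit_county_trend()].
#' @param fit_reduced A reduced-model `trend_fit` from
#'   [fit_reduced_trend()], fitted at the same alpha.
#' @return A list of class `trend_category` with `value` (one of
#'   [trend_patterns()] or `"unclassified"`) and `rationale` (named flags
#'   for interaction, slopes and race shift).
#' @export
classify_trend <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "trend_fit"), inherits(fit_reduced, "trend_fit"))
  if (!isTRUE(all.equal(fit_full$alpha, fit_reduced$alpha))) {
    stop("full and reduced fits were computed at different alpha (",
         fit_full$alpha, " vs ", fit_reduced$alpha, ")", call. = FALSE)
  }
  flags <- c(interaction = sig_flag(fit_full, "interaction"),
             slope_black = sig_flag(fit_full, "slope_black"),
             slope_white = sig_flag(fit_full, "slope_white"),
             race_shift = sig_flag(fit_reduced, "race_shift"))
  value <-
    if (flags[["interaction"]] == "sig_neg" &&
        flags[["slope_black"]] == "sig_neg" &&
        flags[["slope_white"]] == "flat") {
      "convergent_black_improving"
    } else if (flags[["interaction"]] == "sig_neg" &&
               flags[["slope_white"]] == "sig_pos" &&
               flags[["slope_black"]] %in% c("sig_neg", "flat")) {
      "convergent_white_worsening"
    } else if (flags[["interaction"]] == "sig_pos" &&
               flags[["slope_black"]] %in% c("flat", "sig_pos") &&
               flags[["slope_white"]] %in% c("sig_neg", "flat")) {
      "divergent"
    } else if (flags[["interaction"]] == "flat") {
      if (flags[["race_shift"]] == "flat") "sustained_equality"
      else if (flags[["race_shift"]] == "sig_pos") "persistent_disparity"
      else "unclassified"
    } else {
      "unclassified"
    }
  structure(list(value = value, rationale = flags,
                 county_id = fit_full$county_id), class = "trend_category")
}

#' @export
print.trend_category <- function(x, ...) {
  cat(sprintf("<trend_category: %s (%s)>\n", x$value,
              paste(names(x$rationale), x$rationale, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Classify every county in a natality panel
#'
#' Runs rates, full and reduced trend fits and the pattern rules for each
#' county, and tabulates the result.
#'
#' @param records Validated, eligibility-filtered natality records.
#' @param alpha Two-tailed significance threshold (default 0.005).
#' @return A list with `counties` (tibble: `county_id`, `category`,
#'   `p_interaction`, `p_race_shift`, `p_slope_black`, `p_slope_white`) and
#'   `summary` (tibble: `category`, `n`, `percent`, covering every pattern
#'   plus `unclassified`, percentages of classified counties rounded to
#'   whole percent).
#' @export
classify_dataset <- function(records, alpha = 0.005) {
  records <- validate_natality(records)
  if (nrow(records) == 0) {
    counties <- tibble::tibble(county_id = character(0),
                               category = character(0),
                               p_interaction = numeric(0),
                               p_race_shift = numeric(0),
                               p_slope_black = numeric(0),
                               p_slope_white = numeric(0))
    return(list(counties = counties,
                summary = category_summary(counties)))
  }
  fits <- fit_all_counties(records, alpha)
  counties <- dplyr::bind_rows(lapply(names(fits), function(cid) {
    cat_i <- classify_trend(fits[[cid]]$full, fits[[cid]]$reduced)
    tibble::tibble(county_id = cid, category = cat_i$value,
                   p_interaction = fits[[cid]]$full$p[["interaction"]],
                   p_race_shift = fits[[cid]]$reduced$p[["race_shift"]],
                   p_slope_black = fits[[cid]]$full$p[["slope_black"]],
                   p_slope_white = fits[[cid]]$full$p[["slope_white"]])
  }))
  list(counties = counties, summary = category_summary(counties))
}

category_summary <- function(counties) {
  levels <- c(trend_patterns(), "unclassified")
  n <- vapply(levels, function(l) sum(counties$category == l), integer(1))
  total <- sum(n)
  tibble::tibble(category = levels, n = n,
                 percent = if (total == 0) rep(NA_real_, length(n))
                           else round(100 * n / total))
}
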