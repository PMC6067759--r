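# Per-county log-linear LBW trend model.
#
# For one county, log(rate) is regressed by OLS on an intercept, a race
# dummy (black = 1), time t = year - first year, and the race-by-time
# interaction. The interaction coefficient (slope_black - slope_white) is
# the main quantity of interest: its sign and significance decide whether
# the county's black and white trend lines converge, diverge or run
# parallel. A reduced common-slope model supplies the baseline-gap
# (intercept-difference) test used when the interaction is null.

trend_fit_fields <- c("race_shift", "slope_white", "slope_black",
                      "interaction")

new_trend_fit <- function(county_id, model, coefs, se, p, n_obs, alpha,
                          years) {
  structure(list(county_id = county_id, model = model,
                 intercept = coefs[["intercept"]],
                 race_shift = coefs[["race_shift"]],
                 slope_white = coefs[["slope_white"]],
                 slope_black = coefs[["slope_black"]],
                 interaction = coefs[["interaction"]],
                 se = se, p = p, n_obs = n_obs, alpha = alpha,
                 years = years), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit: %s model, county %s, %d obs, alpha = %g>\n",
              x$model, x$county_id, x$n_obs, x$alpha))
  est <- unlist(x[trend_fit_fields])
  tab <- data.frame(estimate = est, se = x$se[trend_fit_fields],
                    p = x$p[trend_fit_fields])
  print(round(tab[!is.na(tab$estimate), ], 5))
  invisible(x)
}

check_trend_input <- function(rates_black, rates_white) {
  stopifnot(is.data.frame(rates_black), is.data.frame(rates_white))
  if (!identical(sort(rates_black$year), sort(rates_white$year))) {
    stop("black and white rate series must cover the same years",
         call. = FALSE)
  }
  if (length(unique(rates_black$year)) < 3) {
    stop("at least 3 distinct years are required to test a slope",
         call. = FALSE)
  }
  if (any(rates_black$rate <= 0) || any(rates_white$rate <= 0)) {
    stop("zero rate encountered: apply the eligibility filter ",
         "(every race-year cell needs LBW births) before fitting",
         call. = FALSE)
  }
}

trend_design <- function(rates_black, rates_white) {
  rates_black <- rates_black[order(rates_black$year), ]
  rates_white <- rates_white[order(rates_white$year), ]
  t0 <- min(rates_black$year)
  data.frame(
    log_rate = log(c(rates_white$rate, rates_black$rate) / 100),
    race = rep(c(0, 1), times = c(nrow(rates_white), nrow(rates_black))),
    t = c(rates_white$year, rates_black$year) - t0)
}

# lm's covariance summary warns on exact-interpolation input; that boundary
# is handled deliberately in two_tailed_p, so the warning is muffled.
quiet_vcov <- function(fit) {
  withCallingHandlers(stats::vcov(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Two-tailed t-test p-value. When the regression interpolates the data
# exactly (residual variance numerically zero), the t statistic is 0/0
# floating noise; at that boundary a zero coefficient gets p = 1 and any
# non-zero coefficient p = 0.
two_tailed_p <- function(term_est, term_se, df, sigma2) {
  if (sigma2 < 1e-20) {
    return(if (abs(term_est) < 1e-10) 1 else 0)
  }
  2 * stats::pt(abs(term_est / term_se), df, lower.tail = FALSE)
}

#' Fit the full race-by-year interaction trend model for one county
#'
#' OLS of `log(rate)` on `{1, race, t, race:t}` with `race` coded black = 1
#' and `t = year - first year`, so the intercept is the white log rate at
#' the baseline year and `race_shift` the baseline black-white log-rate gap.
#' Standard errors use the unbiased residual-variance estimator with
#' `n_obs - 4` degrees of freedom; p-values are two-tailed from the t
#' distribution. `slope_black = slope_white + interaction`, with its
#' standard error from the coefficient covariance.
#'
#' @param rates_black,rates_white Rate series for the two races (tibbles
#'   with `year` and `rate` per 100 births, as from [rate_series()]),
#'   covering the same set of at least 3 years, all rates positive.
#' @param alpha Two-tailed significance threshold recorded on the fit
#'   (default 0.005).
#' @return A `trend_fit` with coefficients, standard errors and p-values
#'   for `race_shift`, `slope_white`, `slope_black` and `interaction`.
#' @export
fit_county_trend <- function(rates_black, rates_white, alpha = 0.005) {
  check_trend_input(rates_black, rates_white)
  d <- trend_design(rates_black, rates_white)
  fit <- stats::lm(log_rate ~ race + t + race:t, data = d)
  b <- stats::coef(fit)
  V <- quiet_vcov(fit)
  df <- fit$df.residual
  est <- c(intercept = unname(b["(Intercept)"]),
           race_shift = unname(b["race"]),
           slope_white = unname(b["t"]),
           interaction = unname(b["race:t"]))
  est["slope_black"] <- est[["slope_white"]] + est[["interaction"]]
  se <- c(race_shift = sqrt(V["race", "race"]),
          slope_white = sqrt(V["t", "t"]),
          interaction = sqrt(V["race:t", "race:t"]),
          slope_black = sqrt(V["t", "t"] + V["race:t", "race:t"] +
                               2 * V["t", "race:t"]))
  sigma2 <- sum(stats::residuals(fit)^2) / df
  p <- vapply(trend_fit_fields, function(f) {
    two_tailed_p(est[[f]], se[[f]], df, sigma2)
  }, numeric(1))
  new_trend_fit(rates_black$county_id[1] %||% NA_character_, "full",
                est, se, p, nrow(d), alpha, sort(unique(d$t)))
}

#' Fit the reduced common-slope trend model for one county
#'
#' OLS of `log(rate)` on `{1, race, t}`. Used to test the baseline
#' intercept difference (`race_shift`) for counties whose interaction is
#' not significant; the interaction fields are `NA`.
#'
#' @inheritParams fit_county_trend
#' @return A `trend_fit` with `model = "reduced"`.
#' @export
fit_reduced_trend <- function(rates_black, rates_white, alpha = 0.005) {
  check_trend_input(rates_black, rates_white)
  d <- trend_design(rates_black, rates_white)
  fit <- stats::lm(log_rate ~ race + t, data = d)
  b <- stats::coef(fit)
  V <- quiet_vcov(fit)
  df <- fit$df.residual
  est <- c(intercept = unname(b["(Intercept)"]),
           race_shift = unname(b["race"]),
           slope_white = unname(b["t"]),
           slope_black = unname(b["t"]),
           interaction = NA_real_)
  se <- c(race_shift = sqrt(V["race", "race"]),
          slope_white = sqrt(V["t", "t"]),
          slope_black = sqrt(V["t", "t"]),
          interaction = NA_real_)
  sigma2 <- sum(stats::residuals(fit)^2) / df
  p <- c(interaction = NA_real_)
  for (f in c("race_shift", "slope_white", "slope_black")) {
    p[[f]] <- two_tailed_p(est[[f]], se[[f]], df, sigma2)
  }
  new_trend_fit(rates_black$county_id[1] %||% NA_character_, "reduced",
                est, se, p[trend_fit_fields], nrow(d), alpha,
                sort(unique(d$t)))
}

#' Fit both trend models for every county in a panel
#'
#' @param records Validated natality records (eligibility-filtered).
#' @param alpha Significance threshold.
#' @return A named list per county, each with elements `full` and
#'   `reduced`.
#' @export
fit_all_counties <- function(records, alpha = 0.005) {
  records <- validate_natality(records)
  counties <- unique(records$county_id)
  out <- lapply(counties, function(cid) {
    rb <- rate_series(records, cid, "black")
    rw <- rate_series(records, cid, "white")
    tryCatch(
      list(full = fit_county_trend(rb, rw, alpha),
           reduced = fit_reduced_trend(rb, rw, alpha)),
      error = function(e) {
        stop("county ", cid, ": ", conditionMessage(e), call. = FALSE)
      })
  })
  stats::setNames(out, counties)
}

#' Serialise trend fits to a coefficient table
#'
#' @param fits Output of [fit_all_counties()].
#' @return One row per county with estimates, standard errors, p-values
#'   from the full fit plus the reduced-model race-shift test, `n_obs`
#'   and `alpha`.
#' @export
trend_fit_table <- function(fits) {
  dplyr::bind_rows(lapply(names(fits), function(cid) {
    f <- fits[[cid]]$full
    r <- fits[[cid]]$reduced
    tibble::tibble(
      county_id = cid, intercept = f$intercept,
      race_shift = f$race_shift, slope_white = f$slope_white,
      slope_black = f$slope_black, interaction = f$interaction,
      se_race_shift = f$se[["race_shift"]],
      se_slope_white = f$se[["slope_white"]],
      se_slope_black = f$se[["slope_black"]],
      se_interaction = f$se[["interaction"]],
      p_race_shift = f$p[["race_shift"]],
      p_slope_white = f$p[["slope_white"]],
      p_slope_black = f$p[["slope_black"]],
      p_interaction = f$p[["interaction"]],
      race_shift_reduced = r$race_shift,
      p_race_shift_reduced = r$p[["race_shift"]],
      n_obs = f$n_obs, alpha = f$alpha)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
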