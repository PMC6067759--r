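# Fixtures are built in code: small natality panels with known structure.

# Noiseless panel: LBW counts are rate/100 * births exactly (births chosen
# so counts are integers), so log-rates fall exactly on the trend lines.
noiseless_panel <- function(county_id = "c1", years = 2003:2013,
                            base_white = 8, base_black = 16,
                            slope_white = 0, slope_black = 0,
                            births = 1e6) {
  t <- years - years[1]
  rw <- base_white * exp(slope_white * t)
  rb <- base_black * exp(slope_black * t)
  tibble::tibble(
    county_id = county_id, state = "XX",
    year = rep(years, each = 2),
    race = rep(c("black", "white"), length(years)),
    births = births,
    lbw_births = as.integer(round(as.vector(rbind(rb, rw)) / 100 * births)))
}

# Balanced two-race panel with constant per-cell counts.
flat_panel <- function(county_id, years = 2003:2005, births = 1000,
                       lbw_black = 120, lbw_white = 70, state = "XX") {
  tibble::tibble(
    county_id = county_id, state = state,
    year = rep(years, each = 2),
    race = rep(c("black", "white"), length(years)),
    births = births,
    lbw_births = rep(c(lbw_black, lbw_white), length(years)))
}

rate_series_from_panel <- function(panel, county, race) {
  lbwtrends::rate_series(panel, county, race)
}

# Hand-built trend_fit for classifier rule tests: estimates and p-values
# are set directly, bypassing the regression.
fake_fit <- function(est, p, alpha = 0.005, model = "full",
                     county_id = "fake") {
  fields <- c("race_shift", "slope_white", "slope_black", "interaction")
  est_full <- stats::setNames(rep(0, 4), fields)
  est_full[names(est)] <- est
  p_full <- stats::setNames(rep(1, 4), fields)
  p_full[names(p)] <- p
  if (model == "reduced") {
    est_full["interaction"] <- NA_real_
    p_full["interaction"] <- NA_real_
  }
  structure(list(county_id = county_id, model = model, intercept = -2.5,
                 race_shift = est_full[["race_shift"]],
                 slope_white = est_full[["slope_white"]],
                 slope_black = est_full[["slope_black"]],
                 interaction = est_full[["interaction"]],
                 se = stats::setNames(rep(0.01, 4), fields), p = p_full,
                 n_obs = 22, alpha = alpha, years = 0:10),
            class = "trend_fit")
}
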