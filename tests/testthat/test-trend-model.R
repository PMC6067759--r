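test_that("noiseless log-linear panels are recovered exactly", {
  a_w <- log(8 / 100); a_b <- log(14 / 100)
  b_w <- -0.01; b_b <- -0.06
  years <- 2003:2013
  t <- years - 2003
  rb <- tibble::tibble(county_id = "c", year = years,
                       rate = 100 * exp(a_b + b_b * t))
  rw <- tibble::tibble(county_id = "c", year = years,
                       rate = 100 * exp(a_w + b_w * t))
  fit <- fit_county_trend(rb, rw)
  expect_equal(fit$intercept, a_w, tolerance = 1e-10)
  expect_equal(fit$race_shift, a_b - a_w, tolerance = 1e-10)
  expect_equal(fit$slope_white, b_w, tolerance = 1e-10)
  expect_equal(fit$slope_black, b_b, tolerance = 1e-10)
  expect_equal(fit$interaction, b_b - b_w, tolerance = 1e-10)
  expect_equal(fit$n_obs, 22)
})

test_that("slope decomposition and p-value ranges hold on noisy panels", {
  d <- simulate_dataset(make_archetype("divergent", 5000, "c"), seed = 3)
  fit <- fit_county_trend(rate_series(d, "c", "black"),
                          rate_series(d, "c", "white"))
  expect_equal(fit$slope_black, fit$slope_white + fit$interaction,
               tolerance = 1e-12)
  expect_true(all(fit$p >= 0 & fit$p <= 1))
  expect_equal(fit$n_obs, 22)
})

test_that("trend fits refuse short series, mismatched years and zero rates", {
  two <- tibble::tibble(county_id = "c", year = 2003:2004, rate = c(7, 8))
  expect_error(fit_county_trend(two, two), "at least 3")

  a <- tibble::tibble(county_id = "c", year = 2003:2005, rate = c(7, 8, 9))
  b <- tibble::tibble(county_id = "c", year = 2004:2006, rate = c(7, 8, 9))
  expect_error(fit_county_trend(a, b), "same years")

  z <- tibble::tibble(county_id = "c", year = 2003:2005, rate = c(7, 0, 9))
  expect_error(fit_county_trend(z, a), "eligibility")
})

test_that("reduced model isolates the baseline log-gap", {
  years <- 2003:2013
  rw <- tibble::tibble(county_id = "c", year = years,
                       rate = 100 * exp(log(0.07) - 0.02 * (years - 2003)))
  # identical series: zero shift, test statistic at its null boundary
  same <- fit_reduced_trend(rw, rw)
  expect_equal(same$race_shift, 0)
  expect_equal(same$p[["race_shift"]], 1)
  expect_true(is.na(same$interaction))

  # constant log-gap delta, no noise: recovered exactly
  delta <- 0.6
  rb <- dplyr::mutate(rw, rate = rate * exp(delta))
  off <- fit_reduced_trend(rb, rw)
  expect_equal(off$race_shift, delta, tolerance = 1e-10)
})

test_that("reduced-model race shift recovers a true log-gap under noise", {
  delta <- 0.6
  sc <- county_scenario("c", 7, 7 * exp(delta), -0.01, -0.01, 50000, 50000,
                        "persistent_disparity")
  est <- vapply(1:200, function(s) {
    d <- simulate_dataset(sc, seed = s)
    fit_reduced_trend(rate_series(d, "c", "black"),
                      rate_series(d, "c", "white"))$race_shift
  }, numeric(1))
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - delta), 3 * mc_se)
})

test_that("swapping the race coding negates shift and interaction only", {
  d <- simulate_dataset(make_archetype("convergent_black_improving", 8000,
                                       "c"), seed = 9)
  rb <- rate_series(d, "c", "black")
  rw <- rate_series(d, "c", "white")
  fit <- fit_county_trend(rb, rw)
  swapped <- fit_county_trend(rw, rb)  # white coded as the indicator race
  expect_equal(swapped$race_shift, -fit$race_shift, tolerance = 1e-10)
  expect_equal(swapped$interaction, -fit$interaction, tolerance = 1e-10)
  expect_equal(swapped$slope_black, fit$slope_white, tolerance = 1e-10)
  expect_equal(swapped$slope_white, fit$slope_black, tolerance = 1e-10)
  expect_equal(swapped$p[["interaction"]], fit$p[["interaction"]],
               tolerance = 1e-10)
})

test_that("per-county fits equal the pooled fully-interacted regression", {
  scens <- list(make_archetype("convergent_black_improving", 4000, "c1"),
                make_archetype("persistent_disparity", 4000, "c2"),
                make_archetype("divergent", 4000, "c3"))
  d <- simulate_dataset(scens, seed = 21)

  # independent oracle: normal-equations solve of the pooled design with
  # county dummies and county-specific race, time and race:time columns
  counties <- c("c1", "c2", "c3")
  d <- dplyr::arrange(d, county_id, year, race)
  y <- log(compute_rate(d$births, d$lbw_births) / 100)
  race <- as.numeric(d$race == "black")
  t <- d$year - min(d$year)
  X <- do.call(cbind, lapply(counties, function(cid) {
    dummy <- as.numeric(d$county_id == cid)
    cbind(dummy, dummy * race, dummy * t, dummy * race * t)
  }))
  beta <- solve(crossprod(X), crossprod(X, y))

  for (i in seq_along(counties)) {
    fit <- fit_county_trend(rate_series(d, counties[i], "black"),
                            rate_series(d, counties[i], "white"))
    pooled <- beta[(4 * i - 3):(4 * i)]
    expect_equal(fit$intercept, pooled[1], tolerance = 1e-10)
    expect_equal(fit$race_shift, pooled[2], tolerance = 1e-10)
    expect_equal(fit$slope_white, pooled[3], tolerance = 1e-10)
    expect_equal(fit$interaction, pooled[4], tolerance = 1e-10)
  }
})

test_that("fit_all_counties attaches the county id to fit errors", {
  good <- flat_panel("ok", years = 2003:2006)
  short <- flat_panel("short", years = 2003:2004)
  expect_error(fit_all_counties(dplyr::bind_rows(good, short)),
               "county short")
  fits <- fit_all_counties(good)
  tab <- trend_fit_table(fits)
  expect_equal(tab$county_id, "ok")
  expect_equal(tab$n_obs, 8)
})
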