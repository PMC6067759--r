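classify_flags <- function(interaction = c(0, 1), slope_black = c(0, 1),
                           slope_white = c(0, 1), race_shift = c(0, 1)) {
  full <- fake_fit(
    est = c(interaction = interaction[1], slope_black = slope_black[1],
            slope_white = slope_white[1]),
    p = c(interaction = interaction[2], slope_black = slope_black[2],
          slope_white = slope_white[2]))
  reduced <- fake_fit(est = c(race_shift = race_shift[1]),
                      p = c(race_shift = race_shift[2]), model = "reduced")
  classify_trend(full, reduced)$value
}

sig <- 1e-4  # well below alpha = 0.005
ns <- 0.5

test_that("each decision rule routes its flag combination correctly", {
  expect_equal(classify_flags(interaction = c(-0.05, sig),
                              slope_black = c(-0.05, sig),
                              slope_white = c(0.001, ns)),
               "convergent_black_improving")
  expect_equal(classify_flags(interaction = c(-0.05, sig),
                              slope_black = c(0.001, ns),
                              slope_white = c(0.05, sig)),
               "convergent_white_worsening")
  expect_equal(classify_flags(interaction = c(-0.07, sig),
                              slope_black = c(-0.02, sig),
                              slope_white = c(0.05, sig)),
               "convergent_white_worsening")
  expect_equal(classify_flags(interaction = c(0.05, sig),
                              slope_black = c(0.05, sig),
                              slope_white = c(-0.001, ns)),
               "divergent")
  expect_equal(classify_flags(interaction = c(0.05, sig),
                              slope_black = c(0.001, ns),
                              slope_white = c(-0.05, sig)),
               "divergent")
  expect_equal(classify_flags(race_shift = c(0.01, ns)),
               "sustained_equality")
  expect_equal(classify_flags(race_shift = c(0.6, sig)),
               "persistent_disparity")
})

test_that("contradictory or uncontemplated flag sets become unclassified", {
  # converging only because both rates rise (black more slowly): the
  # white-worsening rule requires a flat or falling black rate, so no match
  expect_equal(classify_flags(interaction = c(-0.05, sig),
                              slope_black = c(0.02, sig),
                              slope_white = c(0.07, sig)),
               "unclassified")
  expect_equal(classify_flags(interaction = c(-0.05, sig),
                              slope_black = c(0.05, sig),
                              slope_white = c(0.001, ns)),
               "unclassified")
  # diverging with a significantly rising white rate matches no rule
  expect_equal(classify_flags(interaction = c(0.05, sig),
                              slope_black = c(0.10, sig),
                              slope_white = c(0.05, sig)),
               "unclassified")
  # parallel lines with the white rate significantly above the black rate
  expect_equal(classify_flags(race_shift = c(-0.6, sig)), "unclassified")
})

test_that("classification requires matching alpha between fits", {
  full <- fake_fit(est = c(), p = c())
  reduced <- fake_fit(est = c(), p = c(), model = "reduced", alpha = 0.05)
  expect_error(classify_trend(full, reduced), "different alpha")
})

test_that("the rationale records which flags fired", {
  full <- fake_fit(est = c(interaction = -0.05, slope_black = -0.05),
                   p = c(interaction = sig, slope_black = sig))
  reduced <- fake_fit(est = c(race_shift = 0.5), p = c(race_shift = sig),
                      model = "reduced")
  cat_out <- classify_trend(full, reduced)
  expect_equal(cat_out$value, "convergent_black_improving")
  expect_equal(unname(cat_out$rationale[["interaction"]]), "sig_neg")
  expect_equal(unname(cat_out$rationale[["slope_white"]]), "flat")
})

test_that("archetype counties are classified as their true pattern", {
  scens <- lapply(trend_patterns(), make_archetype, births_per_year = 50000)
  d <- simulate_dataset(scens, seed = 7)
  res <- classify_dataset(d)
  expect_equal(res$counties$category, res$counties$county_id)
  expect_equal(sum(res$summary$n), 5)
  expect_true(all(res$summary$n[res$summary$category %in%
                                  trend_patterns()] == 1))
})

test_that("an empty panel classifies to an empty table without error", {
  res <- classify_dataset(flat_panel("x")[0, ])
  expect_equal(nrow(res$counties), 0)
  expect_equal(sum(res$summary$n), 0)
})

test_that("small counties lose power but never drift toward divergence", {
  sc <- make_archetype("convergent_black_improving", 2000, "c")
  categories <- vapply(1:200, function(s) {
    d <- simulate_dataset(sc, seed = s)
    classify_dataset(d)$counties$category
  }, character(1))
  expect_false(any(categories == "divergent"))
  # misclassification is toward non-significance (or, rarely, the other
  # convergent pattern), never toward divergence
  expect_true(all(categories %in% c("convergent_black_improving",
                                    "convergent_white_worsening",
                                    "persistent_disparity",
                                    "sustained_equality", "unclassified")))
})
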