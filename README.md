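# lbwtrends

Tools for analysing county-level trends in black–white disparities in low
birthweight (LBW) rates. The package is aimed at perinatal epidemiologists
and health-equity researchers working with county-year-race natality panels
(total live births and LBW births per county, year and race group), and at
anyone who needs a tested, simulation-backed implementation of the
disparity-trend classification workflow those panels support.

## The model

For each county, annual race-specific LBW rates (per 100 live births) are
modelled on the log scale by ordinary least squares:

```
log r(race, t) = β0 + β1·race + β2·t + β3·race·t + ε
```

with `race = 1` for black births, `t = year − first study year`. Under this
parameterisation `β0` is the white baseline log rate, `β1` the baseline
black–white log-rate gap, `β2` the white per-year log-rate slope, and `β3`
— the race-by-year interaction, the main quantity of interest — the
difference between the black and white slopes. All tests are two-tailed at
α = 0.005.

Each county is then classified into one of five disparity-trend patterns:

1. **Convergent, black improving** — interaction significantly negative,
   black slope significantly negative, white slope flat;
2. **Convergent, white worsening** — interaction significantly negative,
   white slope significantly positive, black slope falling or flat;
3. **Divergent** — interaction significantly positive, black slope flat or
   rising, white slope falling or flat;
4. **Persistent disparity** — no significant interaction, but a
   significantly positive baseline gap (tested in a reduced common-slope
   model);
5. **Sustained equality** — neither the interaction nor the baseline gap
   is significant.

Disparity metrics include the black–white rate ratio RR, the percent change
in each race's rate, and the percent change in RR relative to the baseline
*excess* disparity, `(RR_end − RR_start) / (RR_start − 1) × 100`, for which
−100 means the gap fully closed. The counterfactual module computes, per
county-year, the black LBW births that would have been averted had the
black rate equalled the white rate,
`averted = LBW_black − rate_white/100 × births_black`, and projects
hospitalization costs avoided at a configurable cost per stay (default
$15,100).

Because real all-county natality files are restricted, the package includes
a seeded synthetic-cohort generator: race-specific log-linear rate
trajectories with binomially sampled LBW counts, and one archetype scenario
per trend pattern, so every stage of the pipeline is testable end to end
with known ground truth.

## Worked example

```r
library(lbwtrends)

scens <- lapply(trend_patterns(), make_archetype, births_per_year = 50000)
panel <- simulate_dataset(scens, start_year = 2003, end_year = 2013, seed = 7)
bundle <- run_pipeline(panel, analysis_config())
bundle$table1_summary
#> # A tibble: 6 × 3
#>   category                       n percent
#>   <chr>                      <int>   <dbl>
#> 1 convergent_black_improving     1      20
#> 2 convergent_white_worsening     1      20
#> 3 divergent                      1      20
#> 4 persistent_disparity           1      20
#> 5 sustained_equality             1      20
#> 6 unclassified                   0       0
```

Each of the five simulated archetype counties is recovered as its true
pattern: `n` counts counties per category and `percent` is the share of
classified counties. The bundle also carries the per-county coefficient
table (`bundle$fits`), the two-year disparity detail for convergent
counties with a count-aggregated national row (`bundle$table2_detail`), the
aggregated convergent-county rate series (`bundle$fig1_series`), and the
counterfactual summary (`bundle$averted`); `write_report_bundle()` writes
them all as CSV.

For published two-year tables reported at one decimal, the
printed-precision mode (`disparity_table(..., rounding_mode =
"printed_precision")`) rounds rates and rate ratios to one decimal before
the percent-change formulas, which is the convention needed to reproduce
such tables cell for cell:

```r
pct_change_rate_ratio(2.5, 0.7)
#> [1] -120
```

i.e. a county whose rate ratio fell from 2.5 to 0.7 eliminated 120% of its
baseline excess disparity — the gap closed and crossed below parity.

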