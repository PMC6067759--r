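---
title: "Classifying county-level black-white disparity trends in low birthweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying county-level black-white disparity trends in low birthweight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbwtrends)
```

## The problem

Black infants in the U.S. are born at low birthweight (LBW, ≤ 2,500 g)
roughly twice as often as white infants, but the disparity is not uniform
across places: some counties have closed the gap while most have not.
Characterising *how* a county's gap is changing matters, because a falling
black–white rate ratio can reflect genuine improvement in black birth
outcomes or merely a worsening white rate. `lbwtrends` implements a
county-level workflow that separates these cases: race-specific log-linear
rate trends, a formal interaction test for converging or diverging lines,
a five-pattern classification, rate-ratio disparity metrics, and a
counterfactual projection of the black LBW births that equal rates would
have averted.

## The trend model

For one county with annual LBW rates $r_{g}(t)$ per 100 births for race
group $g \in \{\text{white}, \text{black}\}$ over years
$t = 0, 1, \dots, T-1$ (with $t = 0$ the first study year), the full model
is the OLS regression

$$\log r_g(t) = \beta_0 + \beta_1\,\mathrm{black}_g + \beta_2\,t +
  \beta_3\,\mathrm{black}_g \cdot t + \varepsilon_{gt},$$

so $\beta_2$ is the white log-rate slope, $\beta_2 + \beta_3$ the black
slope and $\beta_3$ the slope difference. Standard errors use the unbiased
residual-variance estimator with $2T - 4$ degrees of freedom and p-values
are two-tailed t tests. A *reduced* common-slope model
($\log r = \beta_0 + \beta_1\,\mathrm{black} + \beta_2 t$) supplies the
baseline-gap test used when the interaction is not significant: testing an
intercept difference inside the full model would condition on an
interaction already deemed null, so the common-slope fit is the cleaner
reading of "difference between the intercepts".

Design choices worth stating explicitly, since the underlying methodology
leaves them open:

* **Per-county fits rather than one pooled regression.** A pooled design
  with county dummies and county-specific race, year and interaction terms
  gives point estimates identical to fitting each county separately (the
  test suite asserts this against a direct normal-equations solve at
  relative tolerance 1e-10); separate fits are more transparent and let
  the residual variance be county-specific. Pooling would only change
  standard errors, by borrowing a common error variance.
* **Time origin at the first study year**, so the intercept difference is
  a *baseline-year* gap test. Centering would test the mid-period gap
  instead; either is defensible, the baseline convention is fixed here and
  documented.
* **Natural log, unweighted OLS.** Each county-year-race cell has weight
  one regardless of birth volume; the eligibility filter (below) keeps
  cell rates away from zero so the log is always defined.
* **"Statistically flat"** means failing to reject a zero slope at the
  analysis α. The default α = 0.005 (two-tailed) is deliberately strict,
  reflecting the multiple-testing burden of classifying hundreds of
  counties; it is configurable.

## Classification rules

`classify_trend()` evaluates, in order: convergent with black improvement
(interaction significantly negative, black slope significantly negative,
white flat); convergent due to white worsening (interaction significantly
negative, white slope significantly positive, black falling or flat);
divergent (interaction significantly positive, black flat or rising,
white falling or flat); then, with a null interaction, sustained equality
versus persistent disparity by the reduced-model baseline-gap test. The
first matching rule wins; rule order only matters for contradictory flag
sets that no rule claims, and anything unclaimed — including a
significantly *negative* baseline gap (white above black), which the
taxonomy never contemplates — is reported as `unclassified` with the fired
flags as rationale rather than being forced into a category.

## Eligibility filtering

Restricted vital-statistics releases suppress small cells, so the analysis
requires at least `min_lbw = 10` LBW births in every race-year cell of
every included county; a county missing any race-year cell fails the
filter outright rather than being imputed, which keeps the analysed panel
complete and balanced. The filter also guarantees strictly positive rates,
so the log-linear model needs no zero-handling. Raising `min_lbw` can only
shrink the kept set (a property test asserts monotonicity). A minimum
county population criterion is treated as upstream provenance: the data
model carries no population field, and an optional `population` column in
input CSVs is accepted and ignored.

## Disparity metrics and rounding

Two percent-change statistics summarise a county between a start and end
year: the ordinary percent change in each race's rate, and the change in
the black–white rate ratio expressed as a percentage of the *baseline
excess* disparity, $(RR_{end} - RR_{start}) / (RR_{start} - 1) \times
100$. The denominator makes −100 mean "gap fully closed" and values below
−100 mean the ratio crossed below 1; it is undefined at $RR_{start} = 1$
(the scalar function errors, the tabulator reports `NA`), and a baseline
ratio below 1 triggers a warning since the "excess" is then negative.

Analysis mode carries full precision throughout. A separate
*printed-precision* mode exists for replicating tables published at one
decimal: rates are rounded to one decimal, rate ratios are computed from
the rounded rates and themselves rounded to one decimal *before* the
excess-disparity formula. The order matters — for a county with rates
17.8/5.0 falling to 7.5/4.9 the printed-ratio computation gives −80.8
while full precision gives about −79.3 — and only the printed-precision
protocol reproduces one-decimal published tables cell for cell, which is
what `scripts/acceptance.R` checks.

## The counterfactual

Per county-year, the averted count is
$\mathrm{LBW}_{black} - (r_{white}/100) \cdot \mathrm{births}_{black}$:
the black LBW births in excess of what the county's white rate would have
produced on the black birth volume. Cells where the black rate is below
the white rate contribute *negative* counts and are retained by default,
so totals are net figures, exactly additive over counties and years; a
`truncate_negative` flag floors cells at zero for sensitivity reporting.
The cost projection multiplies the total by a per-stay hospitalization
cost, by default a deliberately conservative $15,100 (a 2001-dollar
estimate; the 2012 inflation-adjusted $22,953.76 can be supplied instead).
No inflation adjustment is applied by the package itself.

## What the synthetic cohort emulates — and what it does not

Observed data of this kind come as county-year-race counts only, with no
public generative model, so the simulator uses the minimal model
consistent with rates-of-counts: each county has race-specific log-linear
rate trajectories $r_g(t) = r_g(0)\,e^{b_g t}$, annual births fixed per
race (constant across years by default), and LBW counts drawn binomially
with probability $r_g(t)/100$. An optional log-normal multiplier on the
annual rate (mean-corrected, default off) adds over-dispersion. Randomness
sits behind a single master seed from which each county derives its own
stream, so adding or reordering counties never perturbs the other
counties' draws.

Defaults mirror a realistic study design: an 11-year horizon (2003–2013),
baseline rates in the 4–18 per 100 range, and archetype scenarios — one
per trend pattern — whose effect sizes are typical of counties that a
classification of this kind flags: the black-improving archetype declines
from 10.5 to about 3.9 per 100 over the horizon (log-rate slope ≈
−0.099/yr) against a flat white rate of 7.0; the white-worsening archetype
holds black flat at 15.0 while white rises from 5.0 at +0.05/yr; the
divergent archetype rises from 13.0 at +0.05/yr against flat white 7.0;
persistent disparity holds parallel flat lines at 13.4 vs 7.0 (baseline
log-gap ≈ 0.65); sustained equality is identical flat 7.0 lines.

The simulator deliberately omits features of real natality panels: no
spatial correlation between counties, no migration, no within-year
seasonality, no gestational-age structure, and no drift in birth volumes
unless configured. Passing recovery tests therefore demonstrates that the
pipeline's statistics behave as designed under the stated noise model —
not that real counties satisfy that model. In particular, real rates may
be over-dispersed relative to binomial sampling, which would make the
nominal test sizes anti-conservative; the `dispersion_sd` knob exists to
probe that sensitivity.

## Numerical choices and degenerate inputs

* Fewer than 3 distinct years, mismatched year coverage between races, or
  a zero rate abort the fit with an instruction to filter first.
* Exact-interpolation fits (residual variance numerically zero, as with
  noiseless fixtures) would make t statistics 0/0; at that boundary a
  coefficient within 1e-10 of zero gets p = 1 and any other p = 0.
* The averted-births formula multiplies before dividing
  (`rate * births / 100`) so that exactly equal race-specific rates yield
  exactly zero averted births on integer count inputs.
* Summation always precedes rounding; whole-percent rounding appears only
  in the category-count summary, one-decimal rounding only in
  printed-precision outputs.

## Operating characteristics checked by the test suite

The suite (and the acceptance tests) verify, under the archetype
conditions at 50,000 births per race-year: ≥ 90% correct pattern recovery
per archetype over 200 seeded replicates; empirical size of the
interaction test ≤ 1.5% over 1,000 sustained-equality replicates at α =
0.005; mean bias of a true −0.08/yr interaction within 3 Monte-Carlo
standard errors with ≥ 98% coverage of nominal 99.5% intervals over 200
replicates; and, at 2,000 births per race-year, that a convergent county
losing power degrades toward non-significance (persistent disparity or
sustained equality), never toward divergence. These problem sizes are the
package's chosen simulation design for characterising the method at
desk scale.

## Limitations

The classification inherits the discreteness of null-hypothesis testing:
a county with a real but under-powered convergence will be labelled
persistent disparity, and the strict α makes that conservatism deliberate.
The baseline-gap test depends on the time-origin convention. Rate ratios
are undefined where white rates are zero, and the excess-disparity change
is undefined at baseline parity. The counterfactual treats the white rate
as an achievable target rate, which is an accounting convention, not a
causal claim.
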