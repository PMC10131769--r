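---
title: "Methods: search-query surveillance of anxiety themes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: search-query surveillance of anxiety themes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anxitrends)
```

## The surveillance problem

Population-level anxiety is hard to measure continuously: surveys are sparse,
expensive, and lag events. Search engines record, at scale and in near real
time, what people are worried about — provided one can (a) decide which search
terms are actually anxiety-related, (b) put their search volumes on a common
quantitative scale across time, and (c) analyse the resulting country ×
theme × month panel without over-reading a noisy, non-experimental signal.
`anxitrends` implements that pipeline end to end, together with a synthetic
data generator that plants every structure the analyses are meant to detect,
so the whole chain is testable without access to proprietary query logs.

## Identifying anxiety themes in query logs

A candidate term (e.g. *childbirth*) is counted per country and month twice:
once wherever it appears at all (*without context*), and once where the query
also contains at least one phrase from a ten-entry anxiety lexicon
(`anxiety_lexicon()`: "anxious about", "worried about", "nervous", "dread",
"panic", "bothered by", "concerned", "distressed", "frightened",
"tormented"). Matching is case-folded substring matching after whitespace
normalization — deliberately the simplest reproducible rule, since
language-specific tokenization and morphology are out of scope.

`score_terms()` pools counts over countries and computes, per term, the
Spearman rank correlation between the monthly with-context and
without-context series, plus the context fraction (total with-context over
total without-context mentions). A term whose ambient usage tracks its
anxious usage month by month is likely anxiety-related even when mentioned
bare. Two genuinely open choices are made here and flagged rather than
asserted: the ranking statistic is a *rank* correlation (robust to
heavy-tailed counts), and the pairing index is *months pooled over countries*
(the native resolution of the data). `select_top_terms()` takes the top *k*
by correlation, breaking ties by context fraction and then lexicographically,
so selection is deterministic. Terms whose correlation is undefined (a
zero-variance series) are excluded before selection, never silently ranked.

Annotator agreement for the manual grouping of survey responses into themes
is quantified by `cohen_kappa()`, `(p_o − p_e)/(1 − p_e)` with the chance
term from the annotators' marginal label frequencies; the statistic is
flagged undefined when both annotators use one identical label throughout
(`p_e = 1`).

## From normalized windows to a volume panel

Trends services return each requested window scaled to 0–100, destroying the
common scale. `stitch_windows()` reconstructs it by anchor chaining:
consecutive windows must overlap and share an anchor term with positive
values; the ratio of the anchor's values in the overlap (geometric mean over
overlap months — for internally consistent windows every overlap month gives
the same ratio) rescales the later window, and ratios chain across the
sequence. The result is the true volume series up to one global
multiplicative constant, which is all that correlation- and rank-based
analyses require. Single-anchor ratio chaining is used rather than a
multi-anchor least-squares reconciliation; the latter is a non-goal at this
scale. Stitching fails loudly — naming the window pair — when an overlap has
no shared positive anchor.

`annual_volume()` sums months within calendar years (a mean option exists);
years with missing months are *flagged*, not imputed, and the correlation
analyses refuse flagged country-years, because silent imputation would
distort exactly the rank correlations the pipeline reports.

## Descriptive correlation structure

`temporal_stability()` computes, per country, the Spearman correlation across
themes between two years' annual volumes, and averages coefficients across
countries with a plain unweighted mean (a Fisher-z option exists). The
default comparison years are 2004 and 2019: pre-pandemic analyses stop at
2019 so the 2020 shock does not distort them. `cross_country_similarity()`
builds the country × country Spearman matrix across themes for one year and
reports the upper-triangle average. `external_correlation()` relates a
per-country series (e.g. the leading theme's volume) to an external
per-country series (e.g. reported anxiety incidence) by Pearson correlation
with the usual t transform on n − 2 degrees of freedom.

## Trend clustering with correlation similarity

`total_volume_series()` sums themes per country-month; `cluster_series()`
z-standardizes each country's series and runs Lloyd k-means with k-means++
seeding, best of 20 restarts by within-cluster sum of squares. On
standardized series, squared Euclidean distance is `2(T − 1)(1 − r)` — a
monotone transform of the Pearson correlation — so this *is* k-means under
correlation similarity, with per-country affine rescalings of volume
provably irrelevant. Assignments are labelled 1..k (labels are arbitrary up
to permutation).

`select_k()` implements the cluster-count rule: the smallest k in a search
range (default 2–10) whose smallest cluster has at least `min_size = 5`
countries, with an explicit failure flag when no k qualifies. A consequence
worth stating plainly: on *clean* synthetic data with three well-separated
shape classes of sizes 22/9/19, k = 2 already produces two clusters far
above the minimum size, so the rule selects k = 2 — selecting k = 3 by this
rule requires data in which k = 2 strands a handful of outlier countries in
a tiny cluster, something real query panels can produce but an exact
three-class synthetic panel cannot. The package therefore validates the
substantive claim (that k-means at k = 3 recovers the planted 22/9/19
partition exactly) separately from the selection rule, whose behaviour on
clean data is what it is.

One property of z-scoring deserves attention: a country with *constant*
volume has no shape, so after standardization its series is amplified noise,
roughly orthogonal to every other series. A "constant" cluster is therefore
diffuse rather than tight, and any persistent year-level drift makes a flat
country spuriously resemble a trending one. The clean-shapes configuration
used in the recovery tests consequently switches the year-level drift off
(`year_sd = 0`) and keeps only monthly measurement noise.

## The compensatory / noncompensatory effect model

For each country-year, the three most searched themes (recomputed yearly,
ties lexicographic) define X, their summed monthly volume; Y is the summed
volume of all remaining themes, so X + Y is the total by construction.
`fit_interaction_model()` estimates, by ordinary least squares,

Y = β₀ + β₁X + β₂C + β₃Year + β₄(X·C) + ε

with country indicators C, year indicators, and per-country interactions
(first country and year absorbed as references). `classify_effects()` then
tests each country's *total slope* — β₁ for the reference country, β₁ plus
the country's interaction deviation otherwise — against zero with the
standard error taken from the coefficient covariance (including the
cross-covariance term). The total slope, rather than the raw interaction
deviation, is tested because "a rise in the top themes associated with a
fall in the rest" is a statement about each country's own slope,
symmetrically across countries including the reference. A significantly
negative slope is *compensatory* (attention to dominant worries crowds out
the rest), significantly positive is *noncompensatory* (anxiety rises across
the board), otherwise *none*. The default α is 0.05; no multiple-testing
correction is applied across the per-country tests by default (a
`p_adjust = "BH"` option exists), matching the plain reading of the original
analysis.

Standard errors are classical homoskedastic ones by default, because the
model is plain pooled OLS. This has a consequence the tests quantify: when
residual scale differs across countries (e.g. because overall search volume
differs by an order of magnitude), the pooled variance under-estimates the
standard error for large countries and the no-effect group over-rejects —
roughly 6–10% instead of 5% under the generator's realistic heterogeneous
defaults. Calibration is therefore verified under the model's own null
(scale-homogeneous panels, constant trends, no coupling), where the
false-label rate sits at the nominal α, and a heteroskedasticity-robust
option (`vcov_type = "HC1"`) is exposed for users who want inference that
survives scale heterogeneity.

## Attribute associations

All attribute analyses are rank-based. `volume_attribute_correlation()`
correlates each theme's annual volumes with each (year-constant) country
attribute by Spearman's ρ, pooling country-year observations — the pooling
unit is an open choice, made here because it matches the
small-ρ/large-n regime such analyses report — with Bonferroni adjustment over
all theme × attribute pairs. `kruskal_wallis()` tests an attribute across the
effect-label groups (tie-corrected H, χ² approximation, flagged below 5
observations); `pairwise_posthoc()` runs Dunn's z tests on the pooled ranks
with Bonferroni correction over pairs, and records whether the omnibus test
passed its gate (all identical values yield z = 0 by convention after tie
handling). `cluster_attribute_test()` compares an attribute between one
cluster group and the rest with a two-sided Mann–Whitney rank-sum test —
the original analysis does not name its test, and a two-sample rank test is
the choice consistent with its rank-based style — reporting direction as the
rank-biserial correlation.

## What the synthetic generator emulates

`generate_volume_panel()` draws volumes as lognormal multiplicative noise
around deterministic mean paths (volumes are positive and heavy-tailed;
`noise_dispersion` is the log-scale s.d., default 0.15, and 0 yields the
exact mean paths). Its structure, and the defaults' rationale:

* **Trend classes.** Each country carries one of three log-scale shapes:
  declining to −0.7 by 2014 then flat, constant, or flat then rising to
  +0.7 — the three centroid shapes real panels showed, split 22/9/19 by
  default. The *broad theme base* carries the trend; the designated top
  themes are trend-free (see below).
* **Rank persistence.** Country-theme log-means deviate year to year by an
  AR(1) with coefficient `persistence = 0.9` and stationary s.d.
  `year_sd = 0.25`; together with baseline spreads (theme popularity s.d.
  0.44, country-theme s.d. 0.44) these were sized analytically so the
  average Spearman correlation between 2004 and 2019 theme volumes sits
  near 0.89.
* **Geography.** Countries fall into blocks (default five blocks of ten)
  whose baselines share a fraction `rho_block = 0.5` of the country-theme
  variance, putting within-block similarity above between-block and the
  overall cross-country average near 0.49.
* **Planted interaction effects.** Three designated top themes have
  deterministic baselines with a fixed popularity margin — pinning the
  realized yearly top-3 to the designated set — and, in countries with a
  planted sign (default 13 negative / 17 positive / 20 zero), a
  deterministic 12-month oscillation of relative amplitude 0.6; the
  remaining themes respond multiplicatively with strength `coupling = 0.8`
  and the planted sign. Top themes carry *no* year-level persistence and no
  trend: their stochastic variation is purely monthly and serially
  independent, which is exactly the condition under which the pooled OLS
  slope test is calibrated for countries with no planted coupling. The
  amplitude and coupling defaults are the "strong coupling" condition; under
  them, sign recovery for coupled countries is essentially perfect, and the
  overall per-country accuracy sits at about 95%, capped by the no-effect
  group's false-positive rate at α plus the over-rejection quantified below.
* **Shock.** From `shock_start` (default 2020-03) all societal-domain themes
  are multiplied by `shock_size = 3`, emulating a pandemic-like flip of the
  leading domain; the top themes are never shocked, so the level shift
  cannot masquerade as an interaction effect.

`generate_query_log()` drives with-context and without-context monthly
counts by correlated lognormal latent rates (target correlation 0.95 for the
ten planted related terms, 0.0 for the forty others; Poisson counts around
the rates, with a deterministic-rate mode for exactness checks).
`generate_country_attributes()` fills the full attribute table from
plausible marginals and shifts the mental-disorder prevalence of no-effect
countries upward by `prevalence_shift` (default 3 percentage points),
planting the reported association. Every generator emits its ground truth
(trend classes, signs, top themes, related terms, labels) alongside the
data.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: real query text and multilingual matching
(terms are opaque identifiers), seasonality and holiday structure, serially
correlated *monthly* shocks within countries, cross-country correlation of
noise (only baselines are correlated), missing data mechanisms, and any
dependence between the attribute table and the volume panel beyond the
planted prevalence shift. Where the original study's magnitudes were not
reported (noise levels, coupling strength), defaults were chosen once for
recoverability, not realism, and are documented above.

## Numerical and procedural choices

* Undefined statistics (zero-variance series, `p_e = 1` kappa, constant
  attributes) are flagged, never coerced to 0 or dropped silently.
* Ties: theme ranking breaks ties by context fraction then term; top-theme
  ranking and the leading domain break ties lexicographically / by the fixed
  order personal > familial > societal, with an explicit tie flag.
* k-means uses k-means++ seeding, 20 restarts, 100 Lloyd iterations, and a
  recorded seed; all generator and pipeline randomness flows from named
  seeds, and identical config + seed reproduces byte-identical CSVs.
* The interaction design drops single-level factors (a one-country or
  one-year panel degrades gracefully to simple regression) and stops with
  the offending columns named when rank-deficient.
* Simulation sizes in the test suite are the package's own choices: 100
  seeded panels at full study scale (50 × 37 × 204) for recovery rates, 2000
  reduced panels (10 countries) for null calibration — the per-country
  false-label rate does not depend on the number of countries — and 2000
  replicates for each test's type-I error.

## Known limitations

Pooled homoskedastic OLS over-rejects under cross-country scale
heterogeneity (quantified above; robust option available). The smallest-k
selection rule cannot select k = 3 on clean three-class data (explained
above). Context matching is substring-based and language-blind. Anchor
stitching assumes internally consistent windows; real services add
quantization and sampling noise that single-anchor chaining propagates.
Correlation analyses treat volumes as abstract nonnegative intensities;
whether they are counts or rates is immaterial to ranks but matters for any
absolute interpretation.
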