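---
title: "Indicator-based status assessment with control charts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indicator-based status assessment with control charts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baltind)
```

`baltind` turns taxon-resolved zooplankton monitoring samples into an
assessment of whether a community is inside or outside its reference
state. This vignette is the package's own account of the underlying
statistics: what each stage assumes, which knobs matter, and where the
design was genuinely open and a choice had to be made.

## From samples to indicators

A sample record is one taxon × station × date observation carrying
abundance (ind m⁻³) and/or biomass (mg WW m⁻³), with individual wet
weight in µg. The identity `biomass = abundance × mass × 10⁻³` is
enforced on ingest to a relative tolerance of 10⁻⁶; when a file carries
both a stated biomass and an inconsistent product, the stated biomass
wins with a warning, because laboratory biomass values typically embed
stage-resolved weights that the single mass column cannot represent.

Annual values use the summer period (months 6–9), the season all Baltic
monitoring programs cover and the period of peak production and
planktivory. Within a year, samples are averaged per station first and
stations averaged second (`average = "station"`). The alternative —a
grand mean over all samples— lets heavily sampled stations dominate in
the unbalanced designs that are the rule in monitoring data; both
orders are available, and they agree exactly on balanced designs.

Group pooling follows the functional classification in the trait
registry. Predatory cladocerans never enter the total, cladoceran or
microphagous pools. Copepod biomass (CB) uses all copepods, all stages,
including pelagic harpacticoids; the community ratios use calanoids only
in the denominator. These two readings are deliberately kept distinct
rather than harmonized, because they answer different questions (fish
food stock vs. community balance). Copepod nauplii are microphagous
feeders ecologically but are excluded from the microphagous pool by
default, the inclusion list being defined per taxon rather than per
stage; `nauplii_microphagous = TRUE` flips this, and the tests exercise
both paths. Ratios with a zero denominator (no calanoids in a year)
become missing values rather than infinities or zeros, so they flow into
the imputation step like any other gap.

## Transformation, imputation, baselining

Indicator distributions are strongly right-skewed, so everything
downstream runs on Box-Cox transformed values. λ is chosen by profile
maximum likelihood on λ ∈ [−2, 3] (optimizer tolerance 10⁻⁴); λ = 0 is
handled as the log limit, and a series containing zeros is shifted by
half its smallest positive value, the shift being recorded in the
transform object so it can be inverted (round-trip accuracy 10⁻⁸).
A constant series has no defined λ and is an error.

Normality of the transformed, standardized series can be checked with a
Kolmogorov–Smirnov test. Because μ and σ are estimated from the same
data, the plain KS p-value is anti-conservative; the package therefore
simulates the null distribution of the statistic (the Lilliefors
correction) with 10⁴ Monte-Carlo draws under a fixed internal seed, so
the result is reproducible and the caller's RNG stream is untouched.
Series shorter than 12 years are reported "not eligible" instead of
tested — below that length the test has essentially no power and a
p-value would only invite over-interpretation. The threshold is a
parameter.

Missing years (and missing ratio values) inside a dataset's span are
completed by eigenvector filtering: initialize gaps with column means,
standardize columns, reconstruct from the leading principal axes (the
smallest number explaining ≥ 80% of variance, capped at 3), replace the
gaps, iterate until the imputed cells change by < 10⁻⁶ relative or 500
iterations (non-convergence is an error carrying the iteration trace).
Observed cells are never altered, the procedure is idempotent, and a
rank-1 structure is restored essentially exactly. Columns more than 40%
missing are refused — at that point imputation would be invention.
Imputation runs on the transformed scale, before standardization
(transform → impute → standardize); imputed cells are flagged in the
output so downstream users can discount them.

A baseline is the controlling mean and standard deviation of a
transformed series over a year window — the entire series, or a
reference-condition window per dataset (in practice derived from
chlorophyll-a environmental quality ratios or fish weight-at-age; here
they are user-supplied year ranges). The window must contain at least 5
years with data and σ must be positive. σ is the window's own sample
standard deviation, not a pooled estimate: the reference period defines
both the level and the acceptable variability. Standardization
`z = (x − μ)/σ` is applied to every year, inside and outside the window.

## Control charts

Two charts run side by side on each z-score series:

* **Shewhart** flags single extreme years. With a reference-window
  baseline the limits are ±3 z. With a whole-series baseline the limits
  are the two-sided 99% normal quantile, ±2.576 z, applied per
  observation. A confidence interval *of the mean* would shrink with
  series length and flag nearly every year in a long series, which is
  not a usable definition of "deviating year"; the per-observation
  reading is the package's documented interpretation of a 99% band.
* **Decision-interval CuSum** accumulates persistent small departures:
  S⁺ = max(0, S⁺₋₁ + z − k), S⁻ = min(0, S⁻₋₁ + z + k), both from 0,
  with allowance k = 0.5 z and decision interval h = 5 z. k = 0.5 is the
  classical design point for detecting a 1 σ shift in the mean; with
  h = 5 the two-sided scheme has an in-control average run length of
  about 465 observations and detects a sustained 1 σ shift in about 10
  years. The acceptance suite re-measures both numbers by simulation.

Flags use strict inequalities — a statistic exactly at the limit is in
control, matching the language of "exceeding" a limit. The CuSum is not
reset after an alarm, so a regime that never returns to baseline shows
as an unbroken excursion. If a z-value is missing despite imputation,
the CuSum carries its previous value forward and the year cannot raise a
flag (logged); this situation should not occur in the normal pipeline.

Out-of-control **periods** are maximal runs of same-direction CuSum
violations of length ≥ 4 ("more than 3 consecutive years"). Year
**labels** for the logistic stage apply an any-of rule across the nine
indicators: one violating indicator makes the year out-of-control. The
rule is deliberately sensitive; it is monotone (adding an indicator can
only move a year out of control), which the tests verify.

## Trends and breakpoints

Monotonic trends use the Mann–Kendall test: score
S = Σᵢ<ⱼ sign(xⱼ − xᵢ), tie-corrected variance, and a two-sided p-value
from the continuity-corrected normal approximation for n ≥ 10. For
n ≤ 8 the exact permutation distribution is enumerated; for n = 9 a
seeded Monte-Carlo permutation p is used. As a rank statistic it is
invariant under monotone transforms, so running it on z-scores or on
transformed values is equivalent.

Breakpoints come from chronologically constrained clustering: only
temporally adjacent years may group together. The package implements
this as constrained binary segmentation. Within a segment, the boundary
minimizing the pooled within-group sum of squares (Euclidean geometry on
the years × indicators z-matrix) is located; its significance is judged
by a permutation test whose null statistic is *re-maximized over
boundaries in every permutation*. This max-statistic construction is the
crucial numerical choice: testing the data-selected boundary against a
fixed-split null is anti-conservative and produced spurious breakpoints
on homogeneous series at several times the nominal rate in development
testing, whereas the selection-aware null keeps the false-breakpoint
rate at about the nominal α (the acceptance suite measures ≤ 5% at
α = 0.01 over 200 homogeneous 20-year series). A split with p ≤ α is
kept and both sides are searched recursively, so larger α (the
"clustering sensitivity") yields finer partitions, and the accepted
boundaries are nested across α by construction. A final linkage pass
implements the connectedness idea of proportional-link clustering:
adjacent groups whose inter-group distances are mostly small —at least
`connectedness` (default 50%) of them below the median pairwise distance
of the whole series— are re-joined. Permutation seeds derive
deterministically from each segment's position, so results are
reproducible and identical tests agree across α levels. Singleton
groups are allowed. The exact algorithm inside legacy chronological
clustering software is not published at this level of detail; this
implementation is matched to the published method family (contiguity
constraint, Euclidean dissimilarity, permutation-gated grouping at
sensitivity α, connectedness linkage), not bit-for-bit to any program.

Variance shifts between a pre and post period use the F ratio
s²_post/s²_pre with (n_post − 1, n_pre − 1) degrees of freedom, one-sided
for an increase (two-sided also reported), requiring ≥ 3 years per side.

## Logistic GES models

The binary response is the year label (1 = in-control). Fitting is
standard binomial regression via iteratively reweighted least squares
(`stats::glm`, convergence tolerance 10⁻¹⁰); the package reports β, SE,
Wald χ² = (β/SE)², per-coefficient p, AIC, log-likelihood, scaled
deviance and Pearson χ². Complete separation is detected and flagged
rather than silently returning divergent coefficients. Predictors are
whole-series z-scores, so coefficients are log-odds per 1 z-unit and
`exp(β)` is the odds ratio per z-unit; a model-level odds ratio from the
2×2 confusion table is reported separately and labelled as such.

Model search is exhaustive over subsets of at most 3 predictors
(including the intercept-only model) after variance-inflation screening:
the highest-VIF candidate is dropped until all VIF < 3. Ranking is by
AIC, with a parsimony rule: a simpler model nested in the AIC winner,
within ΔAIC ≤ 2, whose likelihood-ratio test against the winner is
non-significant (p > 0.05) replaces it. "Similar AIC" had to be given a
number; ΔAIC ≤ 2 is the standard equivalence window. The `dataset`
identifier can enter as a reference-coded categorical covariate to test
whether neighbouring areas share a model.

Classification metrics are in-sample at a 0.5 cutoff (predicted
in-control when the fitted probability is ≥ 0.5): sensitivity = % of
in-control years predicted in-control, specificity = % of
out-of-control years predicted out-of-control. No cross-validation is
performed — a known limitation; with 20–50 years per dataset, held-out
estimates would be extremely noisy, and the in-sample figures should be
read as upper bounds.

## MSTS: the two-dimensional status

The mean-size/total-stock classification reduces the suite to two
z-scores against a reference baseline: MeanSize, and total stock as TZA
or TZB. Both at or above the threshold (default 0 z, i.e. the baseline
mean) is in-GES ("green"); both below is "red"; exactly one failing
gives the two orange states, named for the failing component
(`orange_size_only`: size fails, stock adequate; `orange_stock_only`:
the reverse). Reading "adequate" as z ≥ 0 is a choice — no numeric
boundary is inherent in the concept — and the threshold is a parameter.
The classification is monotone in each component, and a missing
component yields an undetermined (`NA`) status.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, not plankton biology: six functional groups (calanoids, other
copepods split into copepodite and naupliar components, herbivorous and
predatory cladocerans, rotifers, appendicularians) with mean summer
biomasses of 60/20/30/5/8/4 mg WW m⁻³ and individual masses of
8/2/5/30/0.3/2 µg — a productive Baltic-like summer community of about
120 mg WW m⁻³ total. Noise is multiplicative lognormal (CV 0.4 — chosen
so the Box-Cox stage is exercised non-trivially, with raw-scale CVs in
the range monitoring series show), station effects are persistent
lognormal factors (CV 0.2) so the station-averaging choice is testable,
and whole years drop out with probability 0.05 to trigger the
imputation path. Trends are multiplicative per-group drifts, regime
shifts are step multipliers from a given year. Abundance is derived
from biomass and individual mass, so the record-level consistency
invariant holds exactly, and generation is byte-reproducible from the
seed.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: temporal autocorrelation
beyond the injected trend/step (real regime dynamics are smoother),
taxonomic substitution within groups, seasonal structure within the
summer window, changing sampling methodology, and temperature/salinity
covariates. Results on generated data validate the machinery, not any
field conclusion.

## Problem sizes and numerical tolerances

The test suite sizes simulations to keep the full run around one to two
minutes on a single core: CuSum/oracle agreement on 1000 series of 50
years (exact equality), average run lengths over 2000 runs, Mann–Kendall
calibration over 5000 null series of 30 years, breakpoint
recovery/false-alarm over 200 seeds (199 permutations per test),
end-to-end label recovery over 100 generated 35-year datasets, logistic
IRLS vs. a direct optimizer on 50 datasets (agreement 10⁻⁴), AIC
predictor recovery over 200 simulations. `scripts/acceptance.R` re-runs
the same measurements (some at 60–200 replicates) from a command-line
seed and writes the numbers as JSON. Key tolerances: biomass identity
10⁻⁶ relative; Box-Cox round-trip 10⁻⁸; imputation convergence 10⁻⁶;
z-score normalization identities 10⁻⁹; IRLS gradient tolerance 10⁻¹⁰.

## Known limitations

* Reference windows are user-supplied year ranges; the package does not
  derive them from chlorophyll or fish data.
* The any-of labelling rule makes no multiplicity adjustment across the
  nine indicators; with whole-series baselines it is intentionally
  sensitive.
* Years are treated as exchangeable under the baseline: no
  autocorrelation modelling, no seasonal decomposition.
* In-sample model evaluation only, as discussed above.
* The chronological clustering is a principled reconstruction of the
  method family, not a re-implementation of any specific legacy program.
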