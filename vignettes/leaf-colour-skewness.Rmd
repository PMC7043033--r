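---
title: "Skewed-distribution leaf colour descriptors and SPAD models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skewed-distribution leaf colour descriptors and SPAD models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafskew)
```

## The measurement model

A leaf photograph is reduced to the marginal histograms of its four channels
— red, green, blue and BT.601 gray — over the pixels of a leaf mask. The
working assumption is that all the chlorophyll-relevant information used
here is *marginal*: every descriptor is a function of the per-channel
gradation histogram, never of pixel positions. The mask is taken as ground
truth: either the alpha channel of a transparent-background PNG (the output
of any cutout/segmentation tool) or, for photographs on a bright matte
background, a gray-level threshold (`background = "threshold"`, default cut
250 of 255; pixels strictly darker are leaf). No de-noising is applied
beyond masking — smoothing would distort exactly the histogram shape this
package exists to measure.

Each channel is summarised by the five skewed-distribution parameters:
mean, median, mode, skewness `g1 = m3/m2^{3/2}` and kurtosis `m4/m2²`, with
*population* (biased) central moments and no small-sample correction —
at pixel-scale n (10⁴–10⁶) the bias correction is far below measurement
noise, and the uncorrected moments are what the common numerical
environments return by default. Three conventions are fixed deliberately:

- **Kurtosis is reported as excess (normal → 0) by default.** Reported leaf
  kurtosis values for near-symmetric channels cluster around 0.1–0.5, which
  is only consistent with the excess convention; `kurtosis = "raw"`
  (normal → 3) is available for strict fidelity to environments whose
  `kurtosis` function returns the raw ratio.
- **Mode ties resolve to the smallest gradation level**, computed on integer
  levels, never on smoothed densities.
- **Median of an even-sized sample** is the mean of the two central order
  statistics, so non-integer medians are expected.

Degenerate inputs are flagged, not fatal: a constant channel has
mean = median = mode with skewness and kurtosis `NA`.

The gray conversion uses the BT.601 weights (0.2989, 0.5870, 0.1140) with
round-half-away-from-zero. Because the weights sum to 0.9999, this maps
every equal-channel pixel back to its common level exactly (verified over
all 256 levels in the tests). An optional nearest-neighbour resize
(`resize_nearest()`, off by default) exists for pipelines that standardise
image size; nearest-neighbour is the only resampling that cannot invent new
gradation levels, but any resize reweights the histogram, so descriptors are
computed on the native image unless the user opts in.

## Normality testing

Two tests are provided, chosen for their complementary sensitivities:

- **Jarque–Bera**, `JB = n/6 (S² + (K−3)²/4)` with biased skewness S and raw
  kurtosis K, against χ²(2). The asymptotic tail is used as-is: at the
  pixel counts involved (n ≥ 10³) it is adequate, which the test suite
  checks by Monte-Carlo calibration of the type-I error at n = 1000.
- **Lilliefors**, the Kolmogorov–Smirnov statistic against a normal law with
  estimated mean and SD. Because parameters are estimated, p-values come
  from a Monte-Carlo critical-value table shipped with the package: 20,000
  null replicates at each of 21 sample sizes from 4 to 1000 (fixed seed;
  regenerable with `lilliefors_critical_table()`). For a given n the
  critical values are interpolated across the grid linearly in 1/√n; above
  the grid they are continued by the asymptotic 1/√n law from the largest
  row; the p-value is then log-linearly interpolated in the statistic and
  **clipped to [0.001, 0.5]**, the conventional reporting range — a huge
  leaf sample from any skewed law therefore reports exactly p = 0.001, the
  floor, rather than a meaningless 10⁻³⁰⁰.

Both tests are location-scale invariant by construction (asserted on random
samples). Pooling across leaves is the caller's choice: `channel_sample()`
returns per-leaf samples, and the CLI `normality` subcommand has a `--pool`
flag, since whether the histogram of one leaf or of a 50-leaf pool is tested
are different questions with different answers.

## Group statistics

Correlation tables report Pearson r against SPAD with two-tailed p from the
t distribution (n − 2 df) and stars at 0.05 / 0.01. No multiple-testing
correction is applied across the 30 features: the table is descriptive, and
corrected and uncorrected users can both read it. Duncan's multiple-range
test runs on per-leaf feature values grouped by age (never on pooled
pixels): one-way ANOVA MSE, least significant ranges from studentized-range
quantiles at the Duncan protection level `1 − (1−α)^{p−1}` for a stretch of
p ordered means, harmonic mean of the extreme group sizes for unequal
groups, and compact letters by insert-and-absorb on ascending means (letter
"a" = smallest). The letter display is cross-checked in the tests against a
brute-force all-stretches oracle and, for two groups, against the
pooled-variance t-test.

## SPAD association models

`spad_model(formula, data, family)` fits one of three families; all carry
print/summary/coef/predict/residuals/plot/simulate methods.

**Stepwise linear regression** (`family = "stepwise"`) is the classic
forward-with-backward-elimination on partial-F p-values, entry 0.05 and
removal 0.10 — the defaults of the mainstream statistics packages, since no
better-documented choice exists. Determinism is guaranteed: candidates are
scanned in column order, ties resolve to the smallest p then first column;
exactly collinear candidates are skipped with a warning. Two guards matter
on clean synthetic data: selection stops once the residual sum of squares
falls below 10⁻¹² of the total (an exact fit makes further partial-F ratios
0/0), and with an exact fit a variable whose removal keeps the fit exact is
removed (p treated as 1). An iteration cap of 100 actions rules out
enter/remove cycles. Note that at entry level 0.05 with ~20 null candidates,
admitting one spurious variable is the *expected* behaviour of the
procedure, not a defect; the tests assert signal recovery, not an empty
noise set.

**Fourier curve** (`family = "fourier"`): `y = a0 + a1 cos(wx) + b1 sin(wx)`.
For fixed w the problem is linear; the frequency is found by profiling the
SSE over a grid from half the fundamental (`0.5·2π/range(x)`) up to the
resolution limit (`2π/Δx_min`), with 8 grid points per fundamental period so
no SSE basin is skipped. Every local basin is then refined by golden-section
search (tolerance 10⁻¹²). Equally spaced predictors alias: w and
`2π/Δx − w` fit identically, so among frequencies whose refined SSE ties
within 10⁻¹² of the optimum, the smallest w wins. A constant response
returns `a0 = mean(y)`, `a1 = b1 = 0` at the smallest grid frequency.

**Polynomial surface** (`family = "surface"`): least squares over the
monomials `x1^i x2^j`, `i + j ≤ 3`. The default term set (`terms =
"exact"`) drops the pure `x1³` monomial, matching the nine-term published
cubic layout; `terms = "full"` fits all ten. Columns are scaled by their
max-absolute value before QR for conditioning (R_Mean³ reaches ~4·10⁶),
with coefficients reported on the original scale; rank deficiency is an
error that names the offending terms.

The four published models are available verbatim via `published_model()`:
F1 and F2 (linear), F3 (Fourier in R_Median, arguments in radians; its
printed frequency 1.314 rad per gradation level is inside the default search
bounds) and F4 (nine-term cubic in R_Mean and R_Skewness). The test suite
refits every family on noiseless data generated from its own published
coefficients and requires recovery to 10⁻⁶.

**Evaluation** follows the standard definitions — SSE, `RMSE = √(SSE/n)`,
`R² = 1 − SSE/SST`, `adj R² = 1 − (1−R²)(n−1)/(n−p−1)` — plus the per-leaf
predictive accuracy `(1 − |ŷ−y|/y)·100 %` (undefined, and an error, when a
measured value is 0). Two conventions are configurable because the
published usage is ambiguous: the "abnormal" filter defaults to
|standardized residual| > 3 with the removal count reported (`n_removed`),
since no published rule is stated; and the accuracy *standard deviation* is
reported on the fractional scale by default (published SDs of 0.17–0.23
against means of 64–82 % are only coherent on the fractional scale), with
`accuracy_scale = "percent"` as the switch.

## The synthetic generator

`generate_leaf()` rasterizes an elliptical mask (default canvas 500 × 665,
half the common standardised size, for speed; fully configurable) and fills
each masked pixel independently from per-channel laws:

- **skew-normal(ξ, ω, α)** for red, green (and hence gray): its skewness is
  bounded by |0.9953|, which covers the mildly skewed channels;
- **scaled beta(a, b) on [0, 255]** for the strongly right-skewed blue
  channel.

Draws are rounded half-away and clipped; laws must keep under 0.1 % of
their mass outside [0, 255] or the generator warns, so the closed-form
moments (`analytic_moments()`) remain valid oracles after discretization.
`skew_normal_from_moments()` and `beta_from_moments()` invert the moment
maps so profiles can be planted by target mean/SD/skewness. A hard
feasibility fact surfaces here: a beta law on [0, 255] with mean μ cannot
exceed skewness `(1−2m)/√(m(1−m))`, `m = μ/255` (the two-point limit) —
about 1.70 at the 65-day blue mean. The default `age_profile()` therefore
uses blue skewness targets scaled by 0.8 (1.46, 1.18, 1.32, 1.68), which
preserves the observed sign and age ordering while staying attainable; the
red/green means and skewness targets are the observed per-age values
(means rising with age as the leaf yellows, skewness falling from positive
at 40 days to negative at 60–65 days). Channel SDs, which are not published,
are fixed at 20 (red) and 18 (green) gradation levels — the order of
magnitude seen in the field for single-leaf histograms.

SPAD is generated as a published model's prediction on the *realized*
features plus Gaussian noise, σ = 2.5 meter units by default (comparable to
the residual scatter of the published fits); σ = 0 gives the exact link
used by the recovery tests. Per-leaf sub-seeds derive deterministically
from one master seed, and a seed is mandatory everywhere — there is no
silent nondeterminism.

What the generator does **not** emulate: spatial texture and venation
(channels are drawn i.i.d. per pixel), inter-channel correlation at the
pixel level, lighting gradients, specular highlights and segmentation
errors. Passing tests therefore demonstrate that the *estimators and models
are correct for data whose marginals match the planted laws* — they say
nothing about mask quality or illumination robustness on real photographs.

## Problem sizes used in validation

The shipped tests run at deliberately modest scales chosen as the smallest
that still make each check sharp: end-to-end moment recovery on one
~10⁵-pixel and one ~10⁶-pixel leaf (3-standard-error bands, with standard
errors estimated from 100 subsample blocks and floored at the normal-theory
values √(6/n), √(24/n)); Jarque–Bera size calibration with 2,000 normal
replicates of n = 1000; Lilliefors calibration from the shipped 20,000-
replicate table; model-recovery fits on 100-point curves and 400-point
grids; dataset-level tests with 2–8 leaves per age on 40 × 50 to 120 × 160
canvases.

## Known limitations

- The Lilliefors table is calibrated for n ≥ 4 up to 1000 and continued
  asymptotically above; p-values are only ever reported inside
  [0.001, 0.5] by design.
- Stepwise inference is selection-contaminated, as always: the reported
  coefficients are conditional on selection, and no post-selection
  correction is attempted.
- The Fourier family fits a single harmonic; multi-harmonic fits are out of
  scope, as are regularized regression and cross-validation beyond a
  train/test split the caller arranges.
- Colour spaces other than RGB + BT.601 gray (HSV, CIELAB) and
  texture/shape descriptors are out of scope.
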