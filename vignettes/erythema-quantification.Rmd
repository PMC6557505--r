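---
title: "Quantifying skin erythema from calibrated photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skin erythema from calibrated photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevtools)
library(dplyr)
```

## The measurement problem

Radiation-induced dermatitis (RID) is still graded by eye, on ordinal
scales such as CTCAE, and two experienced observers routinely disagree by a
full grade. When the question is whether one topical treatment prevents
skin reactions better than another, that disagreement can be larger than
the treatment effect being sought. sevtools implements an image-based
alternative: photograph the irradiated region and the patient's own
non-irradiated contralateral skin under controlled lighting together with a
color reference card, convert the calibrated pixels to CIELAB, and reduce
each region to a small set of objective color statistics.

The pipeline is:

1. **Calibration** — fit an affine color correction from the photographed
   reference card and apply it to the image.
2. **Color conversion** — sRGB to CIELAB (D65, 2° observer), per pixel.
3. **Measurement** — mean and SD of L\*, a\*, b\* over each masked
   measurement area.
4. **Erythema scoring** — per-pixel Standard Erythema Value
   $\mathrm{SEV} = (L^*_{max} - L^*)\, a^*$ and the baseline-subtracted
   $\Delta\mathrm{SEV} = \overline{\mathrm{SEV}}_{irradiated} -
   \overline{\mathrm{SEV}}_{control}$.
5. **Cohort statistics** — contingency-table tests, two-sample t-tests,
   one-way ANOVA with Tukey–Kramer post-hoc comparisons, and an
   inter-observer grade comparison.

## Why SEV, and why subtract a baseline

The redness axis a\* alone is not a reliable erythema measure: increased
pigmentation lowers L\* and drags a\* down with it, so a light-red and a
dark-red lesion can return the same a\*. Multiplying the redness by the
darkness headroom, $(L^*_{max}-L^*)\,a^*$, restores a monotone response
across skin tones. `l_max` defaults to 100 — the top of the CIELAB
lightness scale — and is configurable for sensitivity analyses.

Two aggregations of SEV over an area are possible and both are exposed:

* `sev_map()` — the mean of per-pixel SEVs (canonical; erythema is
  spatially inhomogeneous, and per-pixel scoring weights every pixel's
  response),
* `sev_of_mean_color()` — the SEV of the area's mean color.

For a uniform area they coincide exactly; in general they differ by the
within-area covariance $\mathrm{cov}(-L^*, a^*)$, an identity the test
suite checks against a brute-force oracle. Because darker (lower L\*)
pixels in a reaction also tend to be redder, the per-pixel mean is
typically the larger — and more sensitive — statistic.

The remaining nuisance is the patient's own baseline tone: two patients
with identical reactions but different constitutive pigmentation return
different SEVs. Subtracting the SEV of the contralateral control area
yields ΔSEV. Exact tone invariance is not mathematically attainable for a
multiplicative index (under additive reaction shifts,
$\Delta\mathrm{SEV} = (L^*_{max}-L^*_b)\Delta a - \Delta L\,(a_b +
\Delta a)$, which retains a weak baseline dependence), but the subtraction
removes the dominant $(L^*_{max}-L^*_b)\,a_b$ term. The package
demonstrates this on synthetic cohorts: with a fixed erythema effect and
baseline tones drawn at realistic inter-patient scatter, the across-patient
SD of ΔSEV is roughly half that of the unsubtracted irradiated-area SEV.

## Color space conventions

Conversion follows the standard chain sRGB → linear RGB → XYZ → CIELAB with
the IEC 61966-2-1 primaries and the piecewise sRGB transfer curve. Because
consumer cameras and the sRGB standard assume D65 and the 2° observer,
those are fixed; chromatic adaptation to other illuminants is out of scope.
The reference white is taken as the row sums of the RGB→XYZ matrix rather
than tabulated D65 values, so exactly neutral inputs (r = g = b) map to
a\* = b\* = 0 with no rounding residue; the difference from the tabulated
white is below 1e-5 in XYZ and irrelevant at photographic precision.

8- and 16-bit images are normalized to [0, 1] on load. `lab_to_rgb()` is
the exact inverse for in-gamut colors; out-of-gamut results are clipped to
[0, 1] in linear RGB and the count of genuinely clipped pixels (beyond a
1e-9 floating-point guard) is reported in the `n_clipped` attribute rather
than raised as an error, because a handful of clipped pixels is normal when
rendering noisy synthetic scenes.

## Calibration model

The correction is affine in *linear* RGB — a 3×3 matrix plus offset,
fitted by ordinary least squares over the card patches — because an affine
map in linear light absorbs both a channel-wise exposure/white-balance
change and a global additive cast, and has a closed-form fit. At least 4
chromatically independent patches are required; an all-gray card leaves the
3×3 matrix unidentifiable and is rejected with a rank message. The shipped
24-patch ColorChecker-style layout is comfortably over-determined, and the
fit residual (RMS patch error after correction, linear-RGB units) is
reported so poor card photographs are visible. Patch locations come from a
JSON/YAML layout config — automatic card detection is deliberately out of
scope, mirroring a manual clinical workflow and keeping the fit testable.

Nonlinear (polynomial) corrections and flat-field/vignetting models are
non-goals; within-image illumination gradients are therefore *not*
corrected, only global casts.

## Measurement areas

Masks are strictly binary; no feathering or partial-pixel weighting, since
the measurement areas are defined as whole regions. Area summaries use the
population SD (denominator *n*): the masked pixels are the entire
population of interest for that image, not a sample from it. (Inference
across patients, by contrast, uses sample SDs inside the t-tests.) A
warning — never an error — is emitted when an area falls below 10^6
pixels, the recommended minimum data volume for clinical-scale
measurement; bench-scale synthetic images are routinely smaller and remain
usable.

## Statistical layer

The conventions were chosen to reproduce the kind of output classical
clinical statistics packages print for a univariate cohort table:

* `chi_square_test()` — Pearson chi-square *without* Yates continuity
  correction, df = (r−1)(c−1); Yates available behind `correct = TRUE`.
  Expected cell counts below 5 append a warning to the result instead of
  failing, because real cohort tables (including the one this package's
  acceptance checks recompute) contain such cells.
* `two_sample_t()` — Student's pooled-variance test, computable directly
  from printed group summaries (mean, SD, n); Welch behind
  `var_equal = FALSE`; raw samples accepted via `x`/`y`. Zero pooled
  variance with unequal means returns p = 0 with a warning rather than
  NaN.
* `anova_posthoc()` — one-way ANOVA via `aov()`, pairwise comparisons via
  Tukey HSD with the Tukey–Kramer adjustment for unequal group sizes. The
  post-hoc family was genuinely open (the source conventions for such
  analyses rarely name one); Tukey–Kramer is the standard default after a
  one-way ANOVA and is fixed here.
* `interobserver_comparison()` — chi-square on the observer × grade table
  of marginal grade counts, plus the paired cross-tabulation for
  inspection. The marginal test ignores pairing (it asks "do the two
  observers use the grades at the same rates?"); a paired agreement
  statistic such as kappa is a possible extension, not implemented.

All tests are two-sided with α = 0.05 as the significance convention.
Under the null, the simulated type-I error of each test is within ±0.01 of
0.05 (t-test and chi-square over 10,000 replicates, ANOVA over 4,000,
fixed seeds) — part of the acceptance suite.

## The synthetic-data generator

No patient images are distributable, so the generator is first-class,
tested code that defines the study conditions for every pipeline test.

`generate_skin_image()` renders: a uniform baseline skin tone (default
L\* = 66.66, a\* = 6.91, b\* = 16.53, the control-skin means of a
100-patient breast radiotherapy cohort); a spatially smooth erythema field
(white noise smoothed with a Gaussian of sigma = `field_smoothness` pixels,
min-max rescaled to [0, 1]) that raises a\* and lowers L\* inside the
irradiated half — erythema and radiation-induced pigmentation travel
together; i.i.d. Gaussian Lab pixel noise (default SD 1 Lab unit — the
source cohort reports no within-image variance, so this default is our
calibration of a plausibly textured skin area); a 24-patch reference card
strip rendered at its exact reference colors; and an optional global affine
cast in linear RGB applied to the whole rendered image, card included.
Setting `field_smoothness = 0` makes the field uniform, turning the peak
amplitudes into exact mean shifts — the configuration used when a test
needs closed-form ground truth. The default peak amplitudes (Δa\* = 11.8,
ΔL\* = −16.1) are twice the cohort-mean shifts (a\*: 6.91 → 12.83, L\*:
66.66 → 58.60), so the smoothed field's area means land near the published
post-radiotherapy values.

`generate_cohort()` draws per-patient baseline tones (between-patient SDs
6.99/3.16/4.75 for L\*/a\*/b\*), adds arm-specific reaction shifts with
between-patient scatter (defaults sized so the irradiated-area redness
lands near a\* = 11.4 ± 4.0 under bepanthen vs 15.6 ± 4.9 under r1r2, with
a common ≈8-unit L\* drop and no arm difference in lightness), and
simulates two observers who threshold the true ΔSEV at cutpoints 250/550
with observer-specific offsets (0 and 150) plus a 10% one-grade error
rate — the minimal grading model able to reproduce a realistic
inter-observer disagreement pattern, where the stricter observer calls
many more Grade 1 reactions. The default `"analytic"` mode computes
summaries in closed form from the sampled means (exact for uniform areas);
`"render"` mode pushes every patient through the full image pipeline on
small rendered photographs.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real photographs: skin texture, hair, specular
highlights, vignetting and illumination gradients, lens/sensor noise
models, JPEG artifacts, pose differences between the two breasts, and any
within-patient correlation structure beyond the shared baseline tone.
Results on real images additionally depend on acquisition discipline
(uniform lighting, no shine), which no amount of downstream computation
can repair.

## Numerical choices

* Whole-image conversions are vectorized matrix operations; the scalar
  transcription of the CIE equations lives in the test suite as an
  independent oracle (agreement to 1e-9 is an acceptance requirement).
* The calibration fit uses QR least squares; rank < 4 on the design is an
  error naming the deficiency.
* Clipping in `lab_to_rgb()` and `apply_correction()` uses a 1e-9 guard so
  floating-point dust at 0 and 1 is not reported as gamut clipping.
* Lab noise in the generator can push L\* marginally outside [0, 100];
  it is clipped back before the truth image is formed, so ground truth and
  rendered image agree.
* Degenerate statistics inputs (zero variance, single grade level, zero
  marginals) are either errors or explicit warnings, never silent NaNs.

## Problem sizes used by the test and acceptance suites

Synthetic photographs are 120 × 128 pixels (≈5,900 pixels per measurement
area) — large enough that patch regions hold 64 pixels and area means are
stable to well under 0.1 Lab units, small enough that the full suite runs
in well under a minute. Null-calibration simulations use 2,000–10,000
replicates; cohort power simulations use 1,000 replicates of the full
100-patient cohort. All stochastic tests fix their seeds.

## A worked example

```{r example}
# a casted photograph with known ground truth
cast <- list(matrix = diag(c(1.1, 0.94, 1.04)),
             offset = c(0.025, -0.01, 0.02))
syn <- generate_skin_image(skin_image_spec(seed = 42, cast = cast))

# calibrate from the rendered card, then measure
corr <- fit_color_correction(extract_patch_colors(syn$image, syn$card),
                             syn$card)
res <- analyze_image(syn$image, syn$areas$irradiated, syn$areas$control,
                     correction = corr)
tidy(res)
glance(res)
syn$truth$delta_sev   # generator ground truth
```

```{r cohort}
cohort <- generate_cohort(cohort_spec(seed = 42))
cohort |>
  group_by(arm) |>
  summarise(n = n(), mean_dsev = mean(delta_sev), sd_dsev = sd(delta_sev))
x <- split(cohort$delta_sev, cohort$arm)
tidy(two_sample_t(x$r1r2, x$bepanthen))
tidy(interobserver_comparison(cohort))
```

## Known limitations

* Global affine calibration only: no vignetting or illumination-gradient
  correction, no nonlinear color models, no automatic card localization.
* RAW decoding and ICC profile handling are out of scope; inputs must be
  already-decoded PNG/TIFF assumed to be sRGB.
* ΔSEV's baseline independence is approximate by construction (see above);
  the package quantifies, rather than hides, the residual dependence.
* The grading simulator is a deliberately minimal ordinal-threshold model;
  it reproduces marginal disagreement patterns, not the full psychology of
  clinical grading.
* The statistical layer covers the univariate tests of a single-time-point
  cohort comparison; longitudinal "erythema wave" analysis across
  treatment fractions is a non-goal.
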