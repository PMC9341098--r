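---
title: "Estimated axial length and magnification-error correction in OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimated axial length and magnification-error correction in OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocumag)
```

## The problem

En-face OCTA metrics - above all the foveal avascular zone area (FAZA) -
are reported on a lateral scale that the instrument computes assuming a
standard axial length (AL). Real eyes deviate from that standard by
millimetres, so uncorrected FAZA can be wrong by tens of percent, with
longer (more myopic) eyes underestimated and shorter eyes overestimated.
The accepted remedy is the Littmann-Bennett transverse magnification
correction, which needs the eye's AL; but AL requires a biometer that many
clinics lack, and retrospective image archives often have no AL at all.

`ocumag` implements the workflow that fills that gap: estimate AL from two
routinely available quantities - mean keratometry (corneal radius of
curvature, mm) and spherical equivalent (SE, dioptres) - and push the
estimate through the Littmann-Bennett correction, together with the
method-comparison statistics needed to judge how much accuracy the
substitution costs.

## The axial-length regression

The shipped default model is an ordinary least-squares fit on a
post-cycloplegic young-adult cohort of 650 eyes:

$$\mathrm{AL_{est}} = 2.102\,K - 0.4125\,\mathrm{SE} + 7.268
\qquad (R^2 = 0.794),$$

with $K$ the mean corneal radius in mm (average of the two principal
meridians) and SE in dioptres. The signs are anatomically sensible: flatter
corneas (larger radius) and more myopic refractions both go with longer
eyes. Units matter - the model consumes $K$ as a radius in mm; dioptric
keratometry is converted first with the standard keratometric-index
relation $r = 337.5/K_D$ (`diopters_to_radius_mm()`). Only the mm reading
makes the model's output consistent at typical corneal radii (about
7-9 mm) with adult axial lengths of 21-28 mm.

```{r}
estimate_axial_length(7.81, -1.51)   # at a test cohort's mean K and SE
```

`fit_al_model()` refits the same form on any cohort with measured AL
(`stats::lm` under the hood, residual SD on n - 3 degrees of freedom), so
site- or ethnicity-specific models slot into the identical pipeline via
`write_al_model()`/`read_al_model()`. The model deliberately contains no
age term: over the age ranges of interest, age adds essentially no
explanatory power once SE and K are in, and lens-driven age effects on
refraction are already absorbed by SE.

Cycloplegia is metadata, not arithmetic: the same formula applies either
way, but non-cycloplegic SE is biased toward myopia by accommodation
(strongly so in young subjects), which inflates AL estimates. The record's
`cycloplegic` flag is therefore carried through so the two regimes can be
compared downstream.

## The Littmann-Bennett correction

The ocular magnification factor is

$$q = 0.01306 \times (\mathrm{AL} - 1.82),$$

where 1.82 mm relates to the distance between the corneal apex and the
eye's second principal plane; the true linear dimension on the fundus is
$D_t = p \cdot q \cdot D_m$ with $p$ the instrument factor. The bundled
device profile is the Optovue RTVue XR Avanti: $p = 3.48$, assumed AL
23.95 mm, 3-mm scan. Areas scale with the square of the linear factor:

```{r}
correct_area(0.25, rtvue_avanti(), al = 23.95)
```

Two numerical points are worth stating plainly:

* **Areas use $(p\,q)^2$, not $q^2$.** $q$ alone is about 0.29 at typical
  axial lengths, so multiplying an area by $q^2$ would shrink it twelvefold;
  the full Littmann relation forces the $(p\,q)^2$ reading, which leaves
  corrections near unity at typical ALs, as observed.
* **$p \cdot q$ is not exactly 1 at the reference AL.** With the published
  $p = 3.48$, the product at AL 23.95 mm is 1.00578. We keep the published
  constant as the default. Users who want measured $=$ true exactly at the
  reference AL can opt into `mode = "ratio"`, which scales by
  $q(\mathrm{AL})/q(\mathrm{AL_{ref}})$ instead.

The constants 0.01306 and 1.82 are fixed model parameters, overridable only
through the expert arguments of `ocular_magnification_q()`. The package
works at the measurement level: it emits scale factors and corrected values
(`pixel_scale()` gives the on-retina sampling pitch), and leaves image
resampling to image tooling. The correction assumes an unaltered anterior
segment; eyes after refractive surgery or with significant anterior-segment
change need SE considered jointly with AL and are out of scope.

## Agreement statistics

The evaluation battery in `agreement_report()` follows standard
method-comparison practice. Differences are always first method minus
second method, with the reference passed second, and every output labels
the direction - published tables are not always consistent about sign, so
the package is explicit instead.

* **Bland-Altman**: mean difference $\bar d$, SD of differences (n - 1
  denominator), 95% limits of agreement $\bar d \pm 1.96\,\mathrm{SD}$.
  Confidence intervals use $\mathrm{SE}(\bar d) = \mathrm{SD}/\sqrt n$ and
  the classical approximation $\mathrm{SE}(\mathrm{LoA}) =
  \mathrm{SD}\sqrt{3/n}$ with the same 1.96 multiplier; an exact-t variant
  is available via `ci_method = "t"`. `ba_from_summary()` accepts printed
  $(\bar d, \mathrm{SD}, n)$ summaries so published tables can be
  reconstructed without raw data.
* **Paired t**: $t = \bar d / (\mathrm{SD}/\sqrt n)$ on $n - 1$ df,
  two-sided.
* **ICC**: single-measure, absolute-agreement ICC from the two-way
  random-effects model, ICC(A,1) - the variant that penalizes systematic
  offsets, which is the relevant notion when one method is meant to replace
  another. The CI uses the standard F bounds with Satterthwaite degrees of
  freedom. The variant is a deliberate, documented default; "absolute
  agreement" alone does not pin single- vs average-measures.
* **CR exceedance**: percentage of pairs whose absolute difference
  *strictly* exceeds the coefficient of repeatability. The default CR,
  0.052 mm², is the published FAZA repeatability for healthy eyes on the
  RTVue XR Avanti; it is an input constant, not estimated from replicates.
* **Relative change**: per-pair $100\,|ref - other|/ref$ with maxima, the
  clinically interpretable "how far off is the uncorrected value" number.

In formatted reports p-values display to 3 decimals floored at "< 0.005";
machine-readable JSON output keeps full precision.

## The synthetic cohort generator

Restricted cohort data cannot ship with a package, so `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes, and
the defaults are fixed at the study conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| K | N(7.76, 0.26) mm | mean corneal radius |
| SE (post-cycloplegic) | N(-0.15, 1.62) D | refraction marginal |
| AL | model(K, SE) + N(0, 0.486) mm | conditional on K, SE |
| accommodation shift | N(-0.43, 0.30) D | non-cycloplegic SE offset |
| FAZA (true) | N(0.25, 0.10) mm², truncated at 0.05 | ground truth area |
| SQI | uniform on 7-10 | retained quality band |

AL is generated *conditionally* on (K, SE) through the regression rather
than from an empirical joint covariance: that makes coefficient recovery
the natural acceptance test and matches the model form, at the cost of
understating the richer covariance of real biometry. The accommodation
shift's mean is the observed post- minus non-cycloplegic gap in the
reference cohort; its SD (0.30 D) is a free choice since no replicate data
pin it. The FAZA truncation at 0.05 mm² prevents non-physical near-zero
denominators in relative-change calculations. Measured FAZA is the true
FAZA pushed through the exact inverse of `correct_area()` at the eye's
actual AL, so correction with the actual AL recovers the truth to machine
precision - a closure property the tests assert at 1e-10. FAZA measurement
noise defaults to zero (no replicate variance is available to calibrate
it); any nonzero choice is the user's.

Implied by these choices, the refitted model on a 650-eye cohort has
$R^2 \approx 0.76$ (residual variance 0.486² against a total AL variance of
about 0.98), comfortably inside the 0.70-0.85 band the tests check, and an
AL SD near 0.99 mm - close to the 0.95 mm of the emulated cohort.

All randomness flows from the single seed in the `cohort_spec`; the
generator saves and restores the caller's RNG state, and regeneration is
bit-identical across runs. What passing tests on these cohorts do *not*
show: robustness to real-data features the generator omits - non-Gaussian
refraction tails, K/SE measurement error, SQI-dependent noise, inter-eye
correlation (the generator emits right eyes only, as analyses conventionally
use one eye per participant).

## Problem sizes and numerical choices

Cohort-level tests run at n = 650 (matching the training-cohort size) and
the Monte-Carlo agreement harness at n = 46 per replicate (the size of a
FAZA evaluation cohort); parameter-recovery coverage uses 200 refits of
n = 650, which completes in a few seconds. Degenerate inputs are handled
explicitly: zero-SD differences give point limits of agreement and an
error (not NaN) from the t-statistic; identical methods give ICC 1; AL at
or below 1.82 mm raises a classed error naming the Littmann constant;
rank-deficient regression designs error rather than silently dropping
terms. Out-of-range AL estimates warn and continue, with configurable
bounds (default 15-40 mm).

## Known limitations

* The default regression was built on a predominantly Caucasian young-adult
  cohort; transfer to other ages, ethnicities or instruments is exactly what
  `fit_al_model()` + `write_al_model()` exist for.
* Published agreement tables for this workflow contain two internal
  inconsistencies we deliberately do not reproduce: one non-cycloplegic
  validation mean difference is not recoverable from its own cohort means
  under the model's linearity, and one t-statistic does not match its own
  printed $\bar d/\mathrm{SD}/n$. Fixtures use only internally consistent
  rows. An undefined "R²" column sometimes reported alongside agreement
  tables has no stated regression behind it and is not implemented.
* Vessel-density correction is not provided; FAZA and linear dimensions
  only.
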