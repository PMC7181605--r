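---
title: "Morphometric quantification of renal interstitial fibrosis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric quantification of renal interstitial fibrosis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

## The measurement problem

Interstitial fibrosis (IF) — the replacement of functional renal cortical
tissue by fibrillar collagen — is the dominant chronic lesion of kidney
allografts, and its early progression predicts long-term graft dysfunction.
The routine Banff `ci` score grades IF visually on a four-point ordinal
scale, which is coarse and shows substantial inter-observer variation.
Picrosirius Red stains collagen I/III red under ordinary bright-field
light, so fibrosis can instead be *measured*: digitize the stained section,
select the cortex, remove glomeruli and medium-sized arteries, classify
each remaining pixel as Sirius-Red positive or negative, and report the
percent positive area. We call that score **mIF** (morphometric
interstitial fibrosis).

The practical obstacle is staining variation: sections are stained in
batches, and hue and intensity drift between batches. fibroquant therefore
never uses a fixed colour threshold. Each slide is calibrated against
itself: the operator outlines small reference patches of unambiguously
positive and unambiguously negative tissue on that slide, and classification
of the whole section is relative to those internal controls.

## The pixel classifier

Reference pixels are mapped from 8-bit RGB into a cyclic HSV embedding

$$ (s \cos 2\pi h,\; s \sin 2\pi h,\; v) $$

with hue $h$, saturation $s$ and value $v$ on $[0,1]$. Two properties
motivate this space: Sirius-Red discrimination is chiefly chromatic (red
hue at appreciable saturation vs pale yellow counterstain), and the
embedding is continuous both across the red hue wrap-around at $h = 0$ and
at the saturation singularity ($s \to 0$ collapses the hue terms, so
near-white pixels are not destabilised by meaningless hues).

Each class (positive, negative) gets a Gaussian fitted by its sample mean
and covariance, with a ridge of $10^{-3}$ added to the covariance diagonal
so that nearly uniform hand-drawn patches still give well-conditioned
models; at least 100 pixels per class are required. A pixel in the
evaluation region is called positive when the log-likelihood ratio exceeds
an offset (default 0); ties go to the negative class, a deterministic
choice that errs toward under- rather than over-calling fibrosis. The
number of positive pixels is non-increasing in the offset, which gives a
simple sensitivity dial.

This is deliberately the smallest supervised model consistent with the
workflow "select positive and negative areas, then run": two classes, one
decision boundary, no spatial regularisation. Because both class models are
refitted per slide from that slide's own patches, a global gain or modest
hue rotation applied to slide *and* patches moves both Gaussians together
and the decision boundary with them; the package's property tests bound the
resulting mIF change at 0.5 percentage points for gains in $[0.8, 1.2]$ and
offsets of $\pm 10$ intensity units.

## Regions, masks and the denominator

Annotations are GeoJSON FeatureCollections of polygons with a `role`
property: `cortex` (inclusion), `exclusion` (glomeruli, arteries),
`ref_positive`, `ref_negative`. Overlapping cortex polygons are unioned, as
are exclusions, and exclusion wins over cortex — mirroring the operator's
"select, then delete" workflow. Rasterization uses one fixed convention:
0-based continuous coordinates, x right, y down, a pixel belonging to a
polygon iff its centre lies inside under the non-zero winding rule. That
makes an axis-aligned rectangle with integer corners cover exactly
width × height pixels (half-open), which the tests check against direct
arithmetic.

The reported score is

$$ \mathrm{mIF} = 100 \times \frac{\text{positive pixels}}{\text{evaluated pixels}} . $$

By default (`entire_section`) the denominator is the whole cortical
selection, luminal white space included — the convention of reporting the
red area as a percentage of the entire cortical section. Whether the
original commercial pipeline excluded luminal white space is not
documented, so a `tissue_only` policy is provided as an explicit option: it
removes near-white pixels (HSV saturation < 0.08 and value > 0.85) from
numerator candidates and denominator alike. The two policies differ
roughly by the luminal fraction of the section; comparisons across slides
are valid only within one policy.

Specimen adequacy (at least 7 glomeruli and an artery) is a pathologist's
judgement made at the microscope; `batch_quantify()` consumes it as a
manifest flag and routes inadequate slides to an exclusion list rather than
attempting to count glomeruli, which is out of scope.

## The synthetic histology generator

No real slides ship with the package, so correctness is established on
synthetic cortex images with exact ground truth. `generate_slide()`
renders, deterministically from a config and seed:

* an octagonal cortical region on a white background;
* non-overlapping tubule ellipses (counterstain ring, white lumen) and
  glomerular discs, the latter paired with polygonal exclusion
  annotations as an operator would draw them;
* interstitial fibrosis where a Gaussian-smoothed noise field (blur sigma
  3 px by default) exceeds a threshold. The threshold is chosen as an
  exact order statistic of the field over the interstitial candidates, so
  the realized fraction of the evaluation region matches the target to
  within one pixel — well inside the documented 0.002 tolerance — and is
  reported as `realized_fraction`;
* class colours (defaults: positive ≈ (190, 45, 45), counterstain ≈
  (235, 215, 170), lumen/background ≈ (250, 250, 250) — generator
  parameters, not claims about real stains) plus per-pixel Gaussian noise
  (SD 4), then a global batch transform: intensity gain and hue rotation;
* truth masks recorded before noise, partitioning the canvas;
* reference patches, auto-drawn as the largest axis-aligned squares fully
  inside pure truth regions (found with an exact Chebyshev distance
  transform, capped at 40 px side, several patches until ≥ 100 pixels per
  class). Two control bars of pure stain in the top margin — outside the
  cortex, so they never enter the score — stand in when a class region is
  too fragmented to host patches, as with fibrosis fractions near zero.

The smoothed-field model yields connected, wispy fibrotic bands rather
than salt-and-pepper noise, which is what makes patch placement and the
98% pixel-agreement test meaningful. What the generator does **not**
emulate: nuclei and chromatin texture, scanner optics and compression
artifacts, stain gradients within one slide, tubular atrophy, and the
histologic ambiguity of edematous or inflamed interstitium. Passing the
recovery tests therefore demonstrates that the calibration-and-classify
machinery is correct and batch-invariant on cleanly separable stains, not
that mIF on real tissue is unbiased; on real slides the operator's patch
selection remains the critical step.

Batches derive per-slide seeds from a base seed and the slide index, so a
batch is reproducible as a whole while fields stay independent across
slides. The default validation batch crosses fractions 0.05/0.15/0.25
with gains 0.9/1.0/1.1 on 192 × 192 canvases — sizes chosen so the whole
suite runs in seconds while leaving thousands of evaluation pixels per
slide.

## Validation statistics

**ICC.** Reproducibility of mIF between two pathologists (and within one
pathologist 6 months apart) is summarised by an intraclass correlation.
The package implements the one-way random-effects single-rater variant,
ICC(1,1): with between/within mean squares from the one-way ANOVA,

$$ \widehat{\rho} = \frac{MS_B - MS_W}{MS_B + (k-1) MS_W}, \qquad
   F = MS_B / MS_W,\; df_1 = n - 1,\; df_2 = n(k-1), $$

and 95% bounds from $F_L = F / F_{0.975}(df_1, df_2)$,
$F_U = F \cdot F_{0.975}(df_2, df_1)$ mapped through
$\rho = (F^* - 1)/(F^* + k - 1)$. The variant choice was genuinely open —
published reports rarely name one — and was settled analytically: only the
one-way F bounds reproduce the published interval [0.67, 0.81] from the
estimate 0.75 at n = 151, k = 2 (and the upper bound 0.95 at n = 21).
`icc_ci_from_estimate()` performs exactly that reconstruction, inverting
the estimate to its F statistic, so published intervals can be verified
without raw data. Two-way and average-rater variants are out of scope. The
p-value is the upper F tail under $\rho = 0$.

**Pearson.** Correlations carry Fisher-z intervals,
$\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})$, with the t-test
p-value. The association between mIF and the ordinal Banff `ci` grade is
fully determined, up to sampling noise, by the published per-grade
summaries (n = 40/82/18/11, means 8.3/10.7/17.1/20.1, SDs
2.4/3.6/6.4/8.0); `simulate_grouped(ci_grade_groups())` regenerates such
cohorts, and the mean simulated correlation concentrates near 0.61–0.62,
the closed-form value implied by those summaries.

**Location tests.** Progression uses the Wilcoxon signed-rank test (exact
null for ≤ 25 untied non-zero differences, normal approximation with
continuity correction above, zero differences dropped) alongside the
paired t test; if all differences vanish both p-values are 1 with a
degenerate flag rather than an error. Associations with clinical outcomes
use simple least squares via `ols_simple()`, reporting slope, intercept,
$R^2$ and the slope t-test. No multiple-testing correction is applied —
matching the reporting style the statistics reproduce.

## The synthetic cohort

`generate_synthetic_cohort()` emulates the longitudinal structure of a
66-patient transplant cohort biopsied at donor baseline (D0), days 15–30,
month 3 and month 12, with per-timepoint mIF means/SDs of 8.4 ± 3.8,
10.0 ± 3.9, 13.6 ± 6.7 and 15.9 ± 5.2 and availability 43/20/28/28.
Design choices where the published record is silent:

* **Within-patient correlation** across timepoints defaults to 0.5 via a
  Gaussian copula on a latent severity factor — longitudinal fibrosis
  data are correlated, but no value is published; it is a free parameter.
* **Banff `ci` grades** derive from mIF by fixed thresholds 9.5/13.5/19.0,
  calibrated once so the per-grade means approximate the published
  validation groups; real grading is noisier, so optional threshold
  jitter is available. The construction makes per-grade mean mIF monotone
  by design.
* **Clinical outcomes** (time to graft-function recovery, creatinine
  increase at month 12 and last follow-up, day-3 LDH) are linear in the
  latent month-12 score with noise scaled to hit target $R^2$ values
  (0.29/0.32/0.29, and 0.1028 for recovery-on-LDH) in expectation. The
  definition of "creatinine increase" in the source record is not stated;
  it is modelled directly as a change score.
* The month-3 and month-12 biopsy sets coincide (routine protocol
  biopsies), and at least seven patients carry all of D15–30, M3 and M12
  so a paired subgroup exists, matching the published analysis layout.

`progression_analysis()` reports both unpaired (cross-sectional) and
paired (shared-patient) comparisons for each consecutive timepoint pair,
because published longitudinal biopsy series mix overlapping
cross-sections with small paired subgroups and do not always say which
test produced which p-value.

## Numerical choices and degenerate inputs

* Covariance ridge $10^{-3}$ on unit-scaled channels; minimum 100
  calibration pixels per class; calibrations whose training pixels are
  not majority-correct are flagged degenerate, not rejected.
* LLR ties classify negative (deterministic, conservative).
* Comparisons against printed values round half-up to the printed
  precision.
* Zero total variance makes the ICC undefined (error); `MS_W = 0` gives
  estimate 1 with a collapsed interval. `|r| = 1` collapses the Fisher
  interval. Constant x makes the least-squares fit undefined (error).
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; batches and cohorts are bit-reproducible from
  (parameters, seed).

## Worked example

```{r example, eval = FALSE}
slide <- generate_slide(synth_config(fibrosis_fraction = 0.15, seed = 42))
compute_mif(slide$image, slide$annotations)
#> <fibrosis_result> synth-seed42: mIF = 15.00% (4112 / 27410 px, ...)

icc_ci_from_estimate(0.75, n = 151, k = 2)   # [0.671, 0.812]
pearson_ci_from_estimate(0.62, n = 151)      # [0.511, 0.710]
```

## Known limitations

* The classifier is purely chromatic: collagen-coloured non-collagen
  structures (red blood cells in Sirius-Red sections, strongly
  eosinophilic casts) would be counted positive; on real tissue this is
  mitigated by the operator's exclusions, not by the model.
* One raster per slide at a fixed magnification; pyramidal whole-slide
  formats are out of scope.
* The ICC reconstruction assumes the one-way model; if a published
  interval came from a two-way variant the reconstruction will disagree —
  that disagreement is informative, not a bug.
* Synthetic-cohort associations are constructions, not evidence: they
  show the analysis code recovers known structure, nothing more.
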