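# fibroquant

Morphometric quantification of interstitial fibrosis (mIF) on Sirius-Red
stained renal cortex sections, with the validation statistics used to
establish such a method and a synthetic-histology testbed.

## The problem

Interstitial fibrosis is the hallmark chronic lesion of kidney allografts,
and its early progression predicts graft dysfunction. The routine Banff
`ci` grade scores it visually on a 0–3 ordinal scale — too coarse to track
early change and subject to inter-observer variation. Picrosirius Red
stains fibrillar collagen red under bright-field light, so fibrosis can be
measured instead: digitize the section, outline the cortex, delete
glomeruli and medium-sized arteries, classify each remaining pixel as
Sirius-Red positive or negative, and report

```
mIF = 100 × (positive pixels) / (evaluated cortical pixels)   [percent]
```

Staining drifts between batches, so no fixed colour threshold works.
fibroquant calibrates every slide against itself: the operator draws small
reference patches of unambiguously positive and negative tissue on that
slide, a two-class Gaussian colour model (in a cyclic HSV embedding) is
fitted to those patches, and the whole section is classified by the
log-likelihood ratio of the two Gaussians. Because both class models move
with the slide's own staining, scores are comparable across batches.

The package is aimed at renal pathologists and image-analysis developers
who want a transparent, scriptable alternative to closed commercial
morphometry pipelines, plus the statistical machinery to validate one:
one-way random-effects ICC(1,1) with F-based 95% confidence intervals
(including analytic reconstruction of a published CI from estimate and n
alone), Fisher-z Pearson intervals, exact small-sample Wilcoxon
signed-rank tests, simple least-squares association fits, and a
longitudinal biopsy-cohort simulator.

## Worked example

No real slides are needed: the built-in generator renders cortex images
with known ground truth, operator-style annotations (cortex polygon,
glomerular exclusions, reference patches) and exact truth masks.

```r
library(fibroquant)

slide <- generate_slide(synth_config(fibrosis_fraction = 0.15, seed = 42))
slide
#> <synth_slide> synth-seed42: 192x192, realized fibrosis 0.1500 (target 0.1500)

compute_mif(slide$image, slide$annotations)
#> <fibrosis_result> synth-seed42: mIF = 15.00% (4112 / 27410 px, cortex 27410 px, entire_section)
```

The slide was generated with 15% of its evaluation region fibrotic; the
pipeline — rasterize the cortex minus exclusions, fit the calibration from
the slide's own patches, classify, count — recovers 15.00% (4112 of 27410
evaluated pixels). The same number stays within 1.5 points across staining
gains 0.9–1.1, which is the point of the internal-control calibration.

The validation statistics work from raw ratings or from published
summaries:

```r
icc_oneway(simulate_paired_ratings(0.75, n = 151, k = 2, seed = 1))
#> ICC(1,1) = 0.674, 95% CI [0.577, 0.753], F(150,151) = 5.14, p = 6.85e-22, n = 151, k = 2

icc_ci_from_estimate(0.75, n = 151, k = 2)   # published interval, no raw data
#> [1] 0.6710365 0.8121696

pearson_ci_from_estimate(0.62, n = 151)
#> [1] 0.5108631 0.7094686
```

`icc_ci_from_estimate(0.75, 151, 2)` reconstructs the inter-operator
interval [0.67, 0.81] reported for this method at two decimals, and the
Fisher-z interval for r = 0.62 at n = 151 gives [0.51, 0.71] — the
published mIF-vs-Banff-ci correlation interval.

A command-line interface wraps the same functions
(`inst/cli/fibroquant.R`): `quantify`, `batch`, `simulate-slide`,
`simulate-cohort`, `stats {icc, icc-ci, corr, ols}` and `cohort-report`,
with JSON/CSV outputs that embed the tool version, resolved configuration
and seed.

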