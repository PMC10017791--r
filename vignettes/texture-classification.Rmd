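---
title: "Texture-based classification of multiphoton tissue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based classification of multiphoton tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmtex)
```

## The problem and the model

Label-free multiphoton microscopy of liver tissue produces three
co-registered signal channels per field of view (FoV): CARS (lipid-rich
structures), TPEF (endogenous fluorophores, cellular patterns) and SHG
(fibrillar collagen). Metastatic tumor tissue and normal liver parenchyma
differ in how intensity is *arranged* — gland/nest motifs and dense
stromal collagen versus hepatocyte cords with sparse collagen — more
reliably than in how bright they are. mpmtex therefore classifies each FoV
from texture statistics of its three channels:

1. Each channel is min–max normalized per FoV, removing detector gain.
2. Five first-order statistics are computed (mean, population sd,
   non-excess kurtosis, skewness, Shannon entropy of the 256-bin
   histogram in bits).
3. Gray-level co-occurrence matrices (GLCMs) are computed at distances
   1, 12 and 30 pixels (1 µm/pixel, so 1, 12, 30 µm) in the four
   orientations 0°, 45°, 90°, 135°; contrast, correlation, energy and
   homogeneity are read off each matrix and averaged over orientations
   per distance. That is 12 second-order parameters, 17 per channel in
   total.
4. A Gaussian class-conditional discriminant model — linear (pooled
   covariance, divisor $N-K$) or quadratic (per-class covariance,
   divisor $n_k-1$) — converts a feature vector $x$ into the posterior
   probability of "tumor" via Bayes' rule,
   $p(k \mid x) \propto \pi_k\, \mathcal N(x; \mu_k, \Sigma_k)$,
   and an image is called tumor exactly when that posterior exceeds 0.5.

The canonical feature subsets are exposed as `feature_spec_full()` (17
parameters × 3 channels), `feature_spec_selected()` (full CARS and TPEF
but only the 5 first-order parameters plus the three contrasts for SHG —
42 features, the configuration that performs best for this tissue pair)
and `feature_spec_cars_only()` (the variant that survives perturbed
autofluorescence).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `distances` | 1, 12, 30 px | GLCM offsets; at 1 µm/pixel these probe cell-scale, nucleus-cluster-scale and gland-scale structure |
| `levels` | 8 | GLCM gray levels (equal-width bins on [0, 1]) |
| `symmetric` | `FALSE` | directed pair counting |
| `priors` | empirical | class priors from training frequencies; `uniform` available |
| QC `min_coverage` | 0.90 | minimum foreground fraction (borders) |
| QC `max_hole_fraction` | 0.05 | largest 4-connected background blob |
| QC `max_saturated_fraction` | 0.01 | pixels at the 16-bit ceiling |

GLCM quantization (8 levels) and asymmetric counting follow the
long-standing defaults of common texture-analysis toolboxes for
normalized-intensity images; both are configurable, and kurtosis is
deliberately non-excess and uncorrected (a Gaussian raster scores 3) to
match that same convention. Normalization is per FoV and per channel;
features are consequently invariant to any positive gain applied to a
channel (this is tested).

Degenerate inputs never propagate non-finite values: a constant channel
normalizes to zeros with a warning; zero-variance rasters report sd,
skewness and kurtosis of 0; a GLCM with vanishing marginal variance
reports correlation 0. Posteriors are evaluated in log space with a
symmetric eigendecomposition; if a covariance's condition number exceeds
1e8, a ridge `eps * (trace/dim) * I` is added with `eps` escalated in
decades from 1e-8 and recorded in the model. A tumor posterior of exactly
0.5 is assigned to "normal" — the conservative tie direction for a
screening application.

## Quality control

Tiles containing tissue borders, large holes, or saturation artifacts are
screened before features are extracted. Published descriptions of such
screening are qualitative (it was done by visual inspection), so the
package reconstructs the intent with auditable numeric rules, evaluated
in the fixed order saturation → low coverage → hole (first failure
reported): a pixel is foreground when CARS + TPEF exceeds 5% of the
single-channel full scale (SHG is excluded on purpose — sparse SHG is
normal in healthy liver); coverage below 0.90 marks a border; the largest
4-connected background component above 5% of the area marks a hole;
more than 1% saturated pixels in any channel marks saturation. All four
thresholds are parameters of `qc_thresholds()`. Filtering is idempotent
and monotone in `min_coverage` (both tested).

## What the synthetic cohort emulates — and what it does not

No patient images ship with the package, so `generate_cohort()` draws a
fully synthetic cohort: by default 8 matched patients × 2 samples × 30
tiles of 152 × 302 px — a cohort that runs in minutes while keeping
enough samples for leave-one-sample-out folds in both classes. Tumor
tiles mix bright-ring/dark-lumen gland motifs into CARS and TPEF and lay
dense curved SHG fibers; normal tiles use quasi-periodic cord banding
with lipid droplets in CARS and sparse SHG. Poisson shot noise (expected
count 20000 at unit intensity, 16-bit head room) is the default noise
model. The class signal is injected through motif *weights and
densities*, not through mean brightness, precisely so that second-order
GLCM features carry the discriminative signal the method was designed
around.

`separability` linearly interpolates every class-dependent parameter
between a shared baseline (0: the two classes are literally the same
generative distribution, which a Kolmogorov–Smirnov test in the suite
confirms) and the class targets (1). Each tile consumes an RNG substream
keyed by (patient, sample, tile), so cohorts are reproducible and
structure is independent of the seed.

What the generator does **not** emulate: necrosis, steatosis and fibrosis
gradients, vessel walls, stitching seams, inter-patient variability in
illumination, or any real optics. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline's machinery is correct and that
it recovers a texture-borne class difference of the designed kind; they
do not certify clinical performance on real tissue.

## Cross-validation conventions

A "sample" is one tissue block of one patient; a patient contributes up
to two samples. Leave-one-sample-out CV holds out whole samples (all
images of one sample are classified by a model trained on all other
samples), while `split_by_patient()` holds out whole patients and only
lets patients with both matched tissue types into the test set — both
granularities mirror how matched-tissue studies are evaluated.
`select_model()` scores channel-structured candidate subsets rather than
the $2^{51}$ power set; ties break toward fewer features, then the
linear model.

Two per-class-rate conventions are reported side by side, because they
genuinely differ: pooled image-level recalls (identical to sensitivity
and specificity with tumor positive) and macro averages of per-sample
fractions. Neither is privileged in the report object.

One subtlety the suite documents deliberately: on a *null* cohort
(separability 0) with sample-level labels, LOSO accuracy is biased
**below** 0.5 — excluding a held-out sample's own tiles shifts its
class's training mean away from it (cluster-level anti-learning), and
empirical priors tilt against the held-out class. The chance-level check
in the acceptance suite therefore permutes labels at the image level,
for which the usual binomial Monte-Carlo interval around 0.5 applies.

## Problem sizes used by the test suite

The suite runs the full default cohort (480 tiles) once at separability
1 and once at 0 for the end-to-end checks; the separability-monotonicity
ladder uses a reduced 5-patient × 8-tile cohort of 96 × 96-px tiles;
oracle comparisons (GLCM pair enumeration, direct Gaussian densities,
reference LDA) run on small random instances. These sizes were chosen so
the whole suite stays at desk scale while every claim is still computed,
never asserted.

## Known limitations

* QC thresholds reconstruct a visual-inspection step; on real data they
  should be tuned against a small hand-labelled tile set.
* The 16-bit full scale (65535) is assumed for saturation detection;
  detectors with other ranges need `max_intensity` adjusted.
* Quadratic models with 42 features need hundreds of images per class;
  below that the recorded ridge coefficient should be inspected.
* Non-integer intensities survive stack I/O only to 16-bit precision.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_patients_matched = 4, tiles_per_sample = 10)
cohort <- generate_cohort(cfg)
kept <- lapply(cohort, filter_sample)
features <- extract_features(lapply(kept, `[[`, "kept"),
                             feature_spec_selected())
cv <- loso_cv(features, spec = feature_spec_selected(),
              model_type = "linear")
glance(cv)
autoplot(cv$report)

m <- assemble_map(dplyr::filter(cv$predictions,
                                sample_id == "P01_tumor"),
                  kept[[2]]$discards, cohort[[2]]$grid_shape)
autoplot(m)
```
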