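---
title: "Quantifying blueberry internal bruising from sliced-fruit plate images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blueberry internal bruising from sliced-fruit plate images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrybruise)
```

## The problem

Machine harvesting of fresh-market blueberries causes internal bruising:
sub-surface cell breakage that shows up as discolored flesh when a berry is
sliced along its equator. Breeding programs screening for bruise-resistant
genotypes photograph plates of dozens of sliced berry halves on white paper
and want, per berry, a single phenotype: the **bruising ratio** — the pixel
count of the discolored (bruised) region divided by the pixel count of the
whole cross-section. Cultivar means of this ratio separate bruise-resistant
from bruise-susceptible material and correlate negatively with instrumental
firmness (the Young's-modulus texture index YM20_BrSt, in MPa/%).

`berrybruise` implements this assessment pipeline in a model-agnostic way.
The cascade mirrors the standard three-stage design: detect each berry on
the plate, segment its cross-section on a padded crop, segment the bruise
within it, and form the ratio. The detection and segmentation engines are
pluggable *backends* behind one contract, so the same pipeline runs with

* the built-in **classical** image-processing backend (thresholding +
  morphology, no learned weights), or
* a **file backend** that replays externally produced predictions (for
  example, output of trained detection/segmentation networks) from
  YOLO-dialect label files.

Everything downstream — evaluation metrics, the cultivar screen — is
agnostic to which backend produced the masks.

## The synthetic plate generator

No public image set accompanies this problem at development scale, so the
package ships a deterministic generator (`synth_config()`,
`generate_plate()`) whose output carries *exact* ground truth. It emulates
the imaging protocol the pipeline targets:

* a near-white paper background (RGB 245, 245, 240);
* each berry half a filled rotated ellipse with a dark blue-purple **skin**
  annulus (default thickness 12% of the local radius) and pale **flesh**;
* an impact bruise modeled as a rim-anchored angular wedge of flesh
  recolored reddish-brown — impact bruises start at the impact point on the
  rim and spread toward the center, giving a triangle-like region;
* per-berry color jitter (±10 8-bit units) and Gaussian pixel noise
  (sd 5 by default).

Masks are rasterized before coloring, so the generator records each berry's
true ratio as an exact pixel quotient. The wedge's angular extent is not
solved by integration but chosen directly on the rasterized flesh pixels:
the `k` flesh pixels angularly closest to the impact direction are taken,
with `k` the rounded target fraction of the berry's pixel area. The
realized ratio therefore matches the requested fraction to well under 0.02
(the only slack comes from angular ties between symmetric pixel pairs).
Berries are placed on a jittered grid sized so that masks can never touch,
which keeps every plate a clean instance for the matching-based metrics;
plates with overlapping or touching fruit are a documented failure mode of
the classical detector, not of the evaluation machinery.

What the generator deliberately does **not** model: specular highlights,
shadows, seed cavities, camera vignetting, non-elliptical berry outlines,
diffuse bruise boundaries, or discoloration unrelated to impact. Passing
recovery tests on synthetic plates therefore demonstrate that the pipeline
machinery is correct and well-calibrated on idealized imagery; they do not
certify accuracy on real photographs, which is a property of whichever
trained backend is plugged in.

The cultivar simulator (`cultivar_sim_spec()`, `simulate_cultivars()`)
generates the phenotype layer: cultivars split evenly between a resistant
and a susceptible group (default mean ratios 0.12 and 0.32 — the two
cluster levels reported for real multi-year screens bracket a 0.22
threshold, and these defaults reproduce that geometry), berry-level ratios
from a truncated normal (sd 0.03, 20 berries per cultivar), and firmness
`6 − 10 · mean_ratio + N(0, 0.3)`, which puts values in the 2–5 MPa/%
range typical of instrumented blueberry texture data and encodes the
established negative ratio–firmness relationship.

## Pixel-grid conventions and numerical choices

* **Half-open integer boxes** `[x0, x1) × [y0, y1)`: areas are plain
  products, IoU needs no ±1 corrections.
* **Pixel-center rasterization**: a pixel belongs to a polygon iff its
  center lies inside under the even-odd rule. This is unambiguous and
  directly testable against a brute-force point-in-polygon loop, which the
  test suite does pixel by pixel.
* **Polygon export** traces mask outlines with `contourLines()` at level
  0.5, i.e. halfway between member and non-member pixel centers, so
  export → import → rasterize round-trips masks essentially exactly
  (IoU ≥ 0.98 is asserted; in practice it is 1.0 at the default berry
  sizes).
* **Crop bookkeeping**: crops carry their integer offset, so masks
  computed on a crop are placed back on the plate grid exactly, and the
  bruising ratio is invariant to the crop padding (default 4 px).

## The classical reference backend

The detector Otsu-thresholds the grayscale plate (berries are the dark
class), fills holes — the pale flesh often falls on the background side of
the threshold, leaving a thin skin ring that must become a solid component
before any morphology touches it — then applies opening and closing with a
1-px disc and keeps components with area in `[400, 1e5]` px. Confidence is
`min(1, area / 800)`: area is the only evidence a thresholding detector
has, and components near the minimum area are the least trustworthy.

The berry segmenter estimates the background color as the median of the
crop's border pixels, thresholds the color-distance map by Otsu, fills
holes, opens with a 1-px disc, and keeps the largest component.

The bruise segmenter works inside the berry mask eroded by the estimated
skin thickness (12% of the equivalent radius), scores pixels by the
redness index `R − G` (reddish-brown bruise ≈ +75 against greenish flesh
≈ −5 on 8-bit channels), and Otsu-splits that index. Two guards make the
split meaningful at the extremes: the candidate bruise class is discarded
when its mean redness is below 0.15 (an unbruised berry offers only noise
for Otsu to split), and when the *pale* class is itself red the whole
flesh is declared bruised (fully discolored berries give Otsu nothing but
an internal split of the bruise). Components under 30 px are removed and
the result is clipped to the berry mask before counting — the ratio is
**bruise / cross-section**, always ≤ 1.

## Evaluation metrics

`match_predictions()` implements the greedy, confidence-ordered,
single-match assignment protocol standard for detector evaluation;
`average_precision()` builds the PR curve over confidence prefixes,
applies the precision envelope and integrates it exactly (all-point rule;
the 101-point rule is available for ecosystem comparability — the two
differ by < 0.02 on dense curves and the all-point rule is the default
because it is exact). Conventions: precision is 1 with no predictions,
recall is 1 with no ground truth, and with zero truths AP is 1 iff there
are also zero predictions. `map_range()` averages AP over IoU thresholds
0.50–0.95 in steps of 0.05. For segmentation tasks mask-IoU is the
default overlap (box-IoU is available); ratio-level agreement is reported
as RMSE, MAE and MAPE (in percent, zero-truth samples excluded with a
surfaced count).

The test suite pins AP to an independent oracle — the mean over
ground-truth recall levels of the best prefix precision at or beyond each
level — on dozens of random small instances, and IoU to brute-force pixel
and cell counting.

## The cultivar screen

The susceptibility split is a 1-D, K = 2 clustering of cultivar mean
ratios. Rather than Lloyd's algorithm with arbitrary initialization, the
package computes the *exact* optimum: in one dimension the best
2-partition is contiguous in sorted order, so scanning the n − 1 sorted
split points finds the global within-cluster-sum-of-squares minimum
deterministically (`two_means_cluster()`; tests verify it against
exhaustive enumeration of all bipartitions and against Lloyd's from every
distinct-pair initialization). The susceptibility threshold is reported as
the centroid midpoint, with the midpoint of the closest cross-cluster pair
(`boundary`) alongside, since a single quoted threshold can be read either
way. Clustering is per year by default, with a pooled option.

Group separation is validated with Welch's t-test (unbiased variances,
Welch–Satterthwaite degrees of freedom) — chosen over the pooled test for
robustness to unequal variances and group sizes — and the firmness link is
an ordinary least-squares fit of mean ratio on YM20_BrSt, reporting slope,
R² (defined as 0 when the response is constant) and RMSE of residuals.

## Problem sizes used by the tests and the acceptance script

Unit tests run on one cached 320-px, 6-berry plate; the classical-backend
recovery study uses 20 plates of 20 berries at 640 px (8,000 detector
decisions, 400 ratio pairs); the screen-recovery study repeats the default
20-cultivar × 20-berry simulation over 50–100 seeds. These sizes give
stable statistics (detection F1 and label recovery have no observed
variance at these settings) while keeping a full run on one CPU in well
under a minute per component.

## Known limitations

* The classical backend assumes a light, uncluttered background and
  non-touching fruit; touching berries can merge into one detection (a
  logged degenerate case, excluded by the generator's placement).
* Augmentation rebuilds boxes as axis-aligned hulls of transformed
  geometry; for rotated boxes without paired polygons the hull
  over-covers, which is the standard convention.
* Multiplicity of "augmented three times" is read as three augmented
  copies per original without keeping the original; a `n_copies` argument
  makes the choice explicit.
* The screen treats each berry half as an independent sample; no
  within-berry pairing or multi-year mixed model is attempted.
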