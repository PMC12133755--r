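# berrybruise

High-throughput assessment of **internal bruising** in blueberry cultivars
from plate images of sliced fruit.

Machine-harvested blueberries suffer internal bruising — cell breakage
under intact skin, visible as discolored flesh once a berry is sliced along
its equator. Breeders screening germplasm for machine-harvest suitability
photograph plates of ~50 sliced berry halves on white paper and need, per
berry, the **bruising ratio**

```
ratio = bruised-region pixels / cross-section pixels        (0 <= ratio <= 1)
```

and, per cultivar, its mean — the phenotype that separates bruise-resistant
from bruise-susceptible material and correlates negatively with the
instrumental firmness index YM20_BrSt (MPa/%).

`berrybruise` implements the full assessment pipeline for this workflow:

* **Cascade** (`run_plate()`): detect each berry, segment its cross-section
  on a padded crop, segment the bruise, clip and count. Detection and
  segmentation engines are pluggable backends: a built-in *classical*
  image-processing backend (`classical_detector()`,
  `classical_berry_segmenter()`, `classical_bruise_segmenter()`), a *file*
  backend replaying externally produced model predictions from YOLO-dialect
  label files (`file_backend()`), and a ground-truth injection backend for
  validation (`truth_backend()`).
* **Synthetic data** (`synth_config()`, `generate_plate()`,
  `simulate_cultivars()`): deterministic plate images with exact per-berry
  ground-truth masks and ratios, plus a two-group cultivar/firmness
  simulator, so every stage is testable without proprietary imagery.
* **Annotation I/O** (`read_labels()`, `write_labels()`,
  `split_dataset()`, `augment()`): the YOLO text dialect (normalized boxes
  and polygons, optional confidences), deterministic 8:1:1 splitting, and
  annotation-preserving flip/rotation/photometric augmentation.
* **Metrics** (`match_predictions()`, `average_precision()`,
  `map_range()`, `error_metrics()`): greedy confidence-ordered matching,
  precision/recall, AP with the exact all-point precision envelope,
  mAP@0.5:0.95, and RMSE/MAE/MAPE for ratio agreement.
* **Cultivar screen** (`two_means_cluster()`, `welch_t_test()`,
  `fit_linear()`, `screen_report()`): the exact (deterministic, globally
  optimal) 1-D two-means split of cultivar mean ratios with a
  susceptibility threshold, Welch's t-test between the groups, and the
  mean-ratio-vs-firmness regression.

Batch front ends: `bb_synth()`, `bb_run()`, `bb_eval()`, `bb_analyze()`,
with a thin command-line wrapper in `inst/cli/berrybruise.R`.

## Worked example

```r
library(berrybruise)

cfg <- synth_config(seed = 42, n_berries = 12, image_size = 480)
plate <- generate_plate(cfg)
res <- run_plate(plate$image, classical_detector(),
                 classical_berry_segmenter(), classical_bruise_segmenter(),
                 image_id = plate$image_id)
res
#> <plate_result 'plate_0000': 12 berries (0 failed), mean ratio 0.237>

head(as.data.frame(res), 4)
#>    image_id berry_index  x0 y0  x1 y1 berry_area_px bruise_area_px     ratio
#>  plate_0000           1   9 11  71 71          2919           1028 0.3521754
#>  plate_0000           2 100 14 155 67          2280            363 0.1592105
#>  plate_0000           3 188 17 239 63          1850            270 0.1459459
#>  plate_0000           4 358 22 410 68          1887            658 0.3487016
```

Each row is one berry: its detection box (half-open pixel coordinates),
the segmented cross-section and bruise areas in pixels, and their
quotient — the bruising ratio. Against the generator's exact ground truth:

```r
truth <- vapply(plate$berries, `[[`, 0, "true_ratio")
em <- error_metrics(as.data.frame(res)$ratio, truth)
#> MAE 0.0081 | RMSE 0.0116 | MAPE 3.12%
```

The cultivar screen on simulated two-group data (20 cultivars, group mean
ratios 0.12 / 0.32, firmness negatively linear in the mean ratio):

```r
sim <- simulate_cultivars(cultivar_sim_spec(seed = 1))
screen_report(sim, firmness = unique(sim[, c("cultivar", "year", "firmness")]))
#> Year 2021: 20 cultivars, threshold 0.217 (centroids 0.119/0.315)
#>   firmness Welch test: t = 14.13, df = 17.9, p = 3.71e-11
#>   ratio ~ firmness: slope -0.0836, R^2 0.940, RMSE 0.0243
```

The threshold is the midpoint of the two cluster centroids: cultivars with
mean ratio below it are called bruise-resistant, above it
bruise-susceptible, and the Welch test confirms the recovered groups differ
sharply in firmness (resistant cultivars are firmer).

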