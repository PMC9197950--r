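# funduschange

Unsupervised change detection for registered pairs of longitudinal retinal
fundus photographs. Given an earlier *reference* image `I1` and a later
*current* image `I2` of the same retina, the package answers: **which pixels
of `I2` cannot be explained by `I1`?** Those unexplained pixels are the
change regions — typically new lesions — while smooth illumination
differences between the two visits, the main confounder of plain image
differencing, are absorbed automatically.

The intended users are researchers working on retinal image analysis who
need a label-free change detector, a pixel-wise evaluation toolbox, and a
controllable synthetic test bed with exact ground truth.

## Method

The core idea is **background modelling by local sparse representation**.
For each patch `x` (a vectorised `s x s` window of `I2`, default `s = 25`),
a local dictionary `D` is built from `q = g^2` neighbourhood patches of `I1`
(default 25 atoms on a uniform 5 x 5 grid spanning a 50-pixel square around
the corresponding location). The patch is sparse-coded by solving

```
alpha* = argmin_alpha  || x - D alpha ||_2^2  +  lambda || alpha ||_1
```

with the LARS-lasso homotopy algorithm and `lambda = 1/m` by default
(`m` = pixel count of the image). The reconstruction `D alpha*` is the
*background* of the patch: everything that local reference content can
linearly explain, including multiplicative and additive illumination changes
(they surface as rescaled coefficients, not as residual). Sliding the patch
over `I2` yields the background image `B2`; the change map is `I2 - B2`, its
absolute value is rescaled to `[0, 1]`, thresholded (0.3 by default for
small lesions), and morphologically cleaned into a binary change mask.

Large lesions defeat pure background subtraction — their interior can be
patched together from subordinate atoms — so a **fusion pathway** uses the
sparse-representation mask only as a coarse, illumination-robust gate over a
classical illumination-corrected difference image (each image corrected by a
robust polynomial surface fit to its log intensity, then intensity
normalised and differenced; threshold 0.15).

Evaluation against a ground-truth mask is pixel-wise: TPR, FPR,
precision/recall, full ROC and PR sweeps with AUC and mAP, and IOU of binary
masks.

## Worked example

```r
library(funduschange)

sim <- generate_pair(sim_config(seed = 7))   # synthetic pair + ground truth
sim
#> <sim_pair> 192 x 192, 5 lesion(s), truth area 1.51%, seed 7

det <- detect(sim$pair)                      # small-lesion (src) pipeline
glance(det)
#> # A tibble: 1 x 7
#>   mode  threshold    lambda mean_nnz mean_residual mask_area_fraction n_regions
#> 1 src         0.3 0.0000271     22.3         0.294            0.00388         2

tidy(det)                                    # detected regions
#> # A tibble: 2 x 4
#>   region  area centroid_row centroid_col
#> 1      1    76        149.          119.
#> 2      2    67         13.1         157.

glance(evaluate_detection(det, sim$truth))
#> # A tibble: 1 x 7
#>     auc   map   iou   tpr      fpr precision recall
#> 1 0.951 0.589 0.227 0.232 0.000386     0.902  0.232
```

What the numbers mean: the simulated pair carries five small lesions
(1.51 % of pixels), independent smooth illumination fields on the two
images, sensor noise, and a 0.5-px registration jitter. The detector's soft
map ranks lesion pixels almost perfectly (AUC 0.95) at a false-positive rate
near zero; at the conservative default threshold 0.3 two of the five
lesions survive binarisation and cleaning (precision 0.90, recall 0.23) —
lowering `threshold` in `detect_config()` trades precision for recall along
the PR curve shown by `autoplot(roc_pr_curves(det$map, sim$truth), "pr")`.

A shell interface with the same functionality is installed at
`inst/cli/funduschange.R` (`detect`, `simulate`, `evaluate` subcommands).

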