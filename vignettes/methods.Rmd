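---
title: "Sparse-representation change detection for fundus image pairs: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-representation change detection for fundus image pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funduschange)
```

## The problem

Longitudinal fundus photography compares two images of the same retina taken
months or years apart. Genuine changes — new lesions, haemorrhages, exudates
— must be separated from nuisance differences: global exposure shifts, local
illumination gradients from the hand-held optics, sensor noise, and residual
registration error. Pixel-by-pixel differencing confounds all of these; the
detector implemented here instead asks, patch by patch, whether the current
image can be *linearly explained by nearby content of the reference image*.

## Background modelling by local sparse coding

For a pixel `P` of the current image `I2`, take the `s x s` patch `x`
centred there (vectorised, `p = s^2`). Because the pair is registered, the
corresponding location `P'` in the reference image `I1` is the same pixel.
A dictionary `D` (size `p x q`) collects `q = g^2` vectorised patches of
`I1` whose centres form a uniform `g x g` grid spanning the `l x l` window
around `P'` (window border included, centres rounded to whole pixels). The
patch is coded by the lasso problem

$$\alpha^* = \arg\min_\alpha \; \lVert x - D\alpha\rVert_2^2 + \lambda \lVert\alpha\rVert_1,$$

and `D %*% alpha*` is taken as the *background* of `x` — the part of the
current patch the reference neighbourhood can explain. The residual
`x - D alpha*` carries what it cannot: lesions, noise, and (by design very
little) illumination.

Two properties make this illumination-robust. First, a multiplicative
intensity change within a patch is absorbed exactly by rescaling the
coefficient of the corresponding atom. Second, smooth gradients across a
patch are approximated by small mixtures of spatially offset atoms. Atoms
are therefore used *raw* — neither mean-centred nor l2-normalised — since
centring would destroy precisely the coefficient-rescaling mechanism that
performs the illumination correction.

The solver is the LARS-lasso homotopy: the regularisation path is traced
from the empty model and stopped where the active correlations reach
`lambda / 2`, the stationarity level for the objective written with no `1/2`
on the quadratic term. The path algorithm is exact, deterministic, and
handles the degenerate dictionaries that real patches produce (constant
regions duplicate atoms; such atoms are skipped when they become collinear
with the active set, with ties broken by lowest column index). The test
suite cross-checks the solver against an independent cyclic
coordinate-descent solve and against `glmnet` under the penalty mapping
`lambda' = lambda / (2p)`, and verifies the one-atom soft-threshold closed
form exactly. In the coordinate-descent comparison the random instances use
tall dictionaries (`p >= q`), the regime of the method's own `625 x 25`
dictionaries; for `q > p` and vanishing `lambda` the problem loses strong
convexity and coordinate descent can stall measurably short of the optimum,
so an objective comparison there would test the oracle, not the solver.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `patch_size` (s) | 25 px | patch side; odd so a centre pixel exists |
| `window_size` (l) | 50 px | neighbourhood square for atom centres |
| `grid` (g) | 5 | atom centres per axis, `q = 25` atoms |
| `lam` | `1/m` | sparsity weight; `m` = image pixel count |
| `stride` | `s` | patch-centre spacing; `s` tiles, `< s` averages overlaps |
| `threshold` | 0.3 / 0.15 | binarisation of the rescaled map (src / fusion) |
| `open/close radius, min_area` | 1, 3, 20 | mask cleaning at the ~200–600 px image scale |

The geometry defaults give `625 x 25` dictionaries whose window spacing is
`l/(g-1) = 12.5` px, rounded per centre; an odd `g` guarantees the exactly
corresponding patch is one of the atoms. Where the atom layout inside the
window was genuinely open (tiling, random, grid), the uniform
border-inclusive grid was chosen for symmetry and reproducibility. The
default stride equals the patch size — the background is assembled from
non-overlapping reconstructed tiles — because that matches the padding
description of the procedure; smaller strides are supported and overlapping
contributions are averaged through an explicit per-pixel coverage count.

`lambda = 1/m` is small (`2.7e-5` at 192 x 192): the coding is nearly a
least-squares fit onto the 25 atoms, and the l1 term mainly disambiguates.
The mean number of active atoms per patch (`mean_nnz` in `glance()`) is
typically 20–23 of 25.

## Difference maps, thresholds, and a rescaling floor

The change map is `I2 - B2` (signed) and its absolute value rescaled by its
maximum to `[0, 1]`, which is what makes fixed thresholds of 0.3
(small-lesion mode) and 0.15 (fusion mode) meaningful across exposures. One
numerical guard is deliberate: the divisor is `max(max|I2 - B2|, 1e-3)`. An
identical (or noiseless, lesion-free) pair leaves only the lasso shrinkage
residual, of order `lambda`; a pure max-rescale would stretch that
numerically empty map to full scale and manufacture arbitrary "detections".
The floor (`rescale_floor`, 1e-3 intensity units) is three orders of
magnitude below any modelled lesion contrast and well above shrinkage
residuals, so it only disengages rescaling on maps with no real dynamic
range. The same rule is applied after fusion gating.

Binarisation uses `>= threshold`; cleaning is binary opening (disc radius
1), closing (radius 3), and removal of 8-connected components under 20 px —
speckle scale for a few-hundred-pixel fundus image. Morphological cleaning
has no single right answer; these values are configuration, not science,
and are logged with every run.

## The fusion pathway for large lesions

A lesion much larger than the patch can be reconstructed from "subordinate"
atoms — dim reference structures rescaled — so background subtraction sees
mostly its outline. The detector therefore offers a fusion mode: the
thresholded sparse-representation map is turned into a *coarse gate*
(closing with radius 15 — about half the dictionary window, enough to bridge
outline fragments of window-scale lesions — hole filling, then a 3-px
dilation for the rim) and multiplied into an illumination-corrected
difference image, which supplies the precision inside the gate. The gate is
intentionally generous: its job is localisation that illumination cannot
fake, while false evidence outside it is zeroed.

The illumination-corrected difference is produced by a simplified
homomorphic correction: a bivariate polynomial (order 4) is fitted to each
image's log intensity by iteratively reweighted least squares with Tukey
biweight weights (c = 4.685, 5 iterations, MAD scale), so vessels, lesions
and the optic disc are down-weighted and the surface tracks the smooth
illumination component. Correction removes the surface and re-adds its
mean, `exp(log(img + eps) - S + mean(S)) - eps` with `eps = 1e-3` guarding
the dark surround; this preserves brightness in the log domain (exactly for
constant images, to ~1–2 % otherwise — the Jensen gap between log-domain
and arithmetic means is accepted rather than hidden by an extra
renormalisation, which would break exact flat-field recovery). Dedicated illumination models for fundus images require segmenting the
anatomy first; this fit is a deliberately simplified stand-in and is only
used to supply *an* illumination-corrected difference to the fusion gate.
The corrected images are then intensity-normalised to each other with the
affine map `(sigma_t/sigma_s)(x - mu_s) + mu_t` (population standard
deviations, so the moment postconditions are exact for any image size; no
clipping) and differenced.

## Evaluation

Soft maps are evaluated by sweeping every distinct score as a threshold:
the ROC integral uses trapezoids over tie-grouped operating points, which
makes AUC identical to the Mann–Whitney pair-counting statistic (the test
suite asserts equality to 1e-12); mAP defaults to the interpolated
precision-envelope AP, with a raw-trapezoid variant available. Binary masks
get confusion counts, TPR/FPR/precision/recall with the `0/0 -> 0`
convention, and IOU (`0/0 -> 1` for two empty masks). An optional
field-of-view mask excludes the uninformative black surround of real fundus
photographs from every count; synthetic images have no surround, so none is
used in the tests.

## The synthetic test bed

`generate_pair()` builds both images from one shared anatomy so that every
pairwise difference is attributable to an independently switchable cause:

- **background**: a bright disc with quadratic radial vignette; with
  vessels enabled, a bright optic-disc blob and dark curvilinear vessels
  drawn as random smoothed walks out of it (the blob is tied to the vessels
  — a vessel-free image is a pure monotone vignette, which the tests
  exploit);
- **illumination**: per image, an independent random polynomial gain
  (order 2, scaled to max |gain| 0.2) plus two Gaussian bumps (sigma 25 px,
  random sign, 50–100 % of the gain amplitude) and a planar bias (max 0.05),
  applied as `img (1 + gain) + bias`, clipped to `[0, 1]`;
- **lesions**: elliptical supports (diameters 7–15 px by default), texture =
  background + a 0.3-contrast plateau with a 1-px Gaussian edge,
  alpha-blended at 0.5 inside the support; the ground-truth mask is exactly
  the union of supports;
- **noise**: additive Gaussian, sigma 0.005;
- **jitter**: sub-pixel bilinear translation of the current anatomy
  (<= 0.5 px), standing in for residual registration error.

Default size is 192 x 192 — the working scale for all simulation-based
tests and for the acceptance script. Every stage draws from its own
seed-derived stream, so one seed gives one bitwise-identical pair.

What the generator does *not* emulate: real vessel branching statistics and
calibre, disease-specific lesion morphology (it makes smooth bright blobs),
the black extra-retinal surround, non-monotone camera response, and spatially
correlated noise. Passing tests therefore show that the mechanism works
under controlled smooth-illumination and blended-lesion conditions; they do
not certify clinical performance, which can only be measured on real
longitudinal pairs with expert ground truth.

## Numerical and degenerate-input choices

- Coordinates are 0-based `(row, col)`; patches are vectorised row-major.
- The reference image is zero-padded by `ceiling((l + s)/2)` so every atom
  of every dictionary exists; the current image is only padded (and the
  result cropped) when it is smaller than one patch.
- An all-zero dictionary returns the zero code with objective `||x||^2`
  rather than an error; a zero-variance image cannot be intensity-normalised
  and raises one.
- Homotopy tie-breaks: lowest column index; collinear entrants skipped.
- `binarize` rejects thresholds outside `[0, 1]`; `clean_mask` with all
  radii and `min_area` zero is the identity.
- Determinism: the solver path has no randomness; the generator's streams
  are fully determined by the seed.

## Problem sizes used by the tests and the acceptance script

Unit tests use small geometries (patches of 7–9 px on 40–128 px images)
where oracles are cheap; end-to-end properties run the full default geometry
on 192 x 192 pairs. The acceptance script measures: the solver-vs-oracle
objective gap on 50 random tall instances (up to 625 x 25); identity-null
mask area over 10 pairs; illumination-only mask area (detector vs naive
differencing) over 15 pairs; small-lesion AUC/mAP/IOU over 15 pairs;
large-lesion fused vs corrected-difference IOU over 10 pairs. These sizes
were chosen so the whole script completes in about a minute on one CPU while
keeping every estimate stable to well within the margins it is compared at
(the same properties hold, more tightly, at the larger counts used in the
test suite).

## Known limitations

- Lesions darker than the retina are supported by the generator
  (`lesion_contrast < 0`) but the defaults model bright lesions only.
- The fusion gate inherits any gross failure of the coarse mask: a large
  lesion that produces *no* outline response cannot be recovered.
- The simplified illumination surface is global-polynomial; pathological
  illumination that is not low-order smooth (specular glints) lands in the
  difference image.
- Inputs are assumed registered; only sub-pixel residual error is modelled.
- Two time points only; no longitudinal series logic.
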