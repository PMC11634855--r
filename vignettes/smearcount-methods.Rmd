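---
title: "Counting erythrocytes in smartphone-microscope smears: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting erythrocytes in smartphone-microscope smears: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`smearcount` counts red blood cells in brightfield photographs taken
through clip-on smartphone microscopes. This vignette explains the models
and numerical choices behind the package, what the synthetic-data
generator does and does not emulate, and the limitations a user should
keep in mind.

## The imaging situation

A phone-mounted ball-lens microscope yields a bright circular field of
view (FOV) on a dark surround. The backlight is a phone flashlight piped
through inexpensive optics, so illumination falls off toward the FOV rim
(vignetting) and dirt inside the unsealed optical path shows up as dark
speckles. At the reference calibration the raw capture resolves
26.3 px/µm (optical spatial resolution ≈ 2.19 µm). Unstained erythrocytes
appear as dark rings with a paler center — the central pallor of the
biconcave disc — with radii of roughly 2.5–5 µm.

## Preprocessing chain

`preprocess()` applies six stages, in this order, and records them in the
result's `provenance`:

1. **FOV estimation** (`estimate_fov()`). The paper-facing contract is
   geometric: the minimal enclosing circle of the largest connected bright
   region. We binarize at the global Otsu threshold (computed on the
   256-bin integer histogram; `otsu_threshold()`), take the largest
   4-connected component, and run Welzl's exact minimal-enclosing-circle
   algorithm on the convex hull of its boundary pixels. If no bright
   component covers ≥ 1 % of the frame the capture is rejected
   (`no_fov_error`). An explicit `fov_geometry()` can be supplied instead.
2. **Square crop** centered on the FOV, side `min(2r, height, width)`,
   shifted minimally to stay in bounds.
3. **Grayscale** using BT.601 luma weights (0.299, 0.587, 0.114).
4. **Masking and min–max normalization** over the FOV pixels only:
   the masked range is mapped to [0, 255]; a constant FOV raises
   `degenerate_image_error` (a blank capture), while a range of one
   intensity unit still stretches to {0, 255}.
5. **Tracked resize** to the 501 × 501 working image. Downscaling uses an
   exact area (box) average implemented as two sparse weight-matrix
   products; the mask is resampled with a ≥ 0.5 coverage rule. The
   physical scale is tracked exactly:
   `effective_px_per_um = raw_px_per_um × (501 / crop_side)`. With default
   synthetic frames (3000 px raw, FOV 90 % of the half-side) this gives
   4.88 px/µm. Upscaling (rare) falls back to bilinear interpolation with
   a warning.
6. **Enhancement** (`enhance()`): Gaussian blur (5 × 5), sharpening with
   the all −1 / center 9 stencil (sums to 1, so constants are preserved),
   5 × 5 median filter, CLAHE (clip 1.0, 8 × 8 grid), then
   `(v + 7) × 1.02` with clipping after each step. The FOV mask is
   re-applied at the end, so pixels outside the FOV are exactly zero.

Numerical conventions, used consistently everywhere:

* (row, col) coordinates, 1-based, pixel centers at integer coordinates
  (the R convention; all circle geometry lives in this frame);
* half-up rounding (`floor(x + 0.5)`) at every 8-bit re-quantization;
* reflect-101 borders (edge pixel not duplicated) for every filter;
* the Gaussian σ is derived from the kernel size as
  `0.3·((k−1)/2 − 1) + 0.8` (1.1 for k = 5), overridable.

**CLAHE variant.** The clip limit is interpreted as a multiple of the
uniform per-tile histogram level (`clip_limit × tile_pixels / 256`), with
the clipped excess redistributed uniformly in one pass, and bilinear
interpolation between the mappings of the four surrounding tile centers.
The per-tile mapping is the *midpoint* (center-of-bin) scaled CDF,
`map(v) = round(255 · (cdf(v) − h(v)/2) / n)`. This choice matters: it is
exactly the identity on a flat histogram, so a constant image passes
through CLAHE unchanged (with the plain CDF lookup, constants drift by one
level at the extremes). Degenerate single-bin tiles keep the identity map
outright. At clip limit 1.0 the clipped histogram is nearly flat, so this
stage applies only mild local contrast — consistent with its role as a
gentle touch-up between the median filter and the brightness step.

## Detection model

Detection is parameterized in micrometres (`detection_params_um()`:
radius gate [2.5, 5] µm, minimum separation 4.5 µm) and converted to
pixels with the *effective* post-resize resolution, since detection runs
on the working image. Rounding is conservative — floor for the minimum
radius, ceiling for the maximum — so the stated micrometre interval stays
covered; if the minimum radius falls below 1 px the image is too coarse
for the cell size and `scale_error` is raised. At 4.88 px/µm the gate
becomes 12–25 px with a 22 px separation.

`hough_gradient()` is the production detector, a standard two-stage
gradient Hough: Canny edges (Sobel gradients, non-maximum suppression,
hysteresis at 100/50 on unnormalized gradient magnitudes), votes cast
along each edge pixel's gradient direction (both senses) at distances
within the radius gate, candidate centers as 3 × 3 accumulator maxima with
at least 18 votes, and the radius as the mode of in-range edge distances
(ties to the smaller radius). The 18-vote default is set so that a
half-occluded minimum-size cell still passes; it, and the Canny
thresholds, are exposed in the configuration.

`hough_bruteforce()` is the reference implementation kept for testing:
every edge pixel votes for its full rasterized perimeter (1° steps,
deduplicated per edge pixel) in a complete 3-D accumulator. Note the two
variants count votes on different scales — a true center collects roughly
the perimeter length (≈ 2πr) in the exhaustive accumulator but only
ray-aligned hits (tens) in the gradient one — so equivalence checks run
each variant at its own vote threshold (18 for gradient votes,
`round(π · min_radius)` for the exhaustive accumulator, the same
half-occlusion rationale).

`suppress_min_distance()` greedily accepts candidates in vote order
(ties: smaller row, then column — a total order, so results are fully
deterministic) and drops any candidate closer than the minimum separation
to an accepted one. `count_cells()` composes conversion, detection,
FOV-mask filtering and suppression.

Design choices worth knowing:

* no sub-pixel refinement: centers are reported at vote-grid resolution;
* detections whose centers fall outside the FOV mask are discarded;
* a configuration flag (`use_raw_scale`) converts µm parameters with the
  raw rather than effective resolution, for pipelines that skip resizing.

## Validation protocol

`match_circles()` pairs detections with ground truth greedily by
ascending center distance, one-to-one, accepting pairs within a tolerance
(default 3 µm ≈ one cell radius; a flag in the configuration). Unmatched
detections are false positives; unmatched truths, false negatives.
`prf_aggregate()` reports per-image precision `tp/(tp+fp)` and recall
`tp/(tp+fn)` as mean ± sample SD (n − 1 denominator; a single image
reports SD 0 with a note; an image with no detections counts precision 1
if it also has no truths, else 0). Pooled (micro) precision and recall
are reported alongside. `count_error_metrics()` gives MAE and MSE of the
per-image counts, and `linear_r2()` fits algorithm counts on reference
counts by ordinary least squares (`stats::lm`), with
R² = 1 − SS_res/SS_tot; datasets with fewer than three images (or
constant reference counts) report `NA` for the fit rather than failing,
since per-image metrics remain meaningful.

## Synthetic study conditions

`generate_scene()` / `render_scene()` emulate the µ-scope image character
with exact ground truth. Defaults define the package's reference study:

| parameter | default | meaning |
|---|---|---|
| `raw_side` | 3000 px | raw frame side; ≈ scale at which 26.3 px/µm and the ~6× resize to 501 px are mutually consistent |
| `px_per_um` | 26.3 | raw calibration of the reference device |
| `fov_radius_frac` | 0.9 | FOV radius as fraction of the half-side |
| `n_cells_range` | 15–45 | cells per image |
| `cell_radius_range_um` | 2.8–4.2 µm | strictly inside the 2.5–5 µm gate, so radius gating is not the limiting factor in clean regimes |
| `min_center_separation_um` | 9 µm | > 2 × max radius: no overlaps (no rouleaux) |
| `ring_contrast` / `center_pallor` | 60 / 35 | rim darkness below background; interior above rim |
| `vignette_strength` | 0.25 | cosine falloff: `I(ρ) = 190·(1 − s·(1 − cos(πρ/2R)))` |
| `noise_sigma` | 5 | additive Gaussian sensor noise |
| `n_dirt_range`, `dirt_radius_range_um` | 0–3, 0.5–1.8 µm | dark speckles, below the minimum cell radius |

Cell layout is drawn in micrometre coordinates relative to the FOV center,
so one seed yields the same physical scene at any calibration — this is
what makes the two-calibration consistency tests meaningful. Placement is
rejection sampling (≤ 10 000 attempts per cell) behind a disk-packing
feasibility pre-check; infeasible densities raise `placement_error`.
Cells render as anti-aliased two-tone rings: rim at the local vignetted
background minus `ring_contrast`, interior (inside 0.55 r, a plausible
pallor fraction that also keeps the inner edge below the detector's
minimum radius) brighter by `center_pallor`. Noise uses a sub-seed derived
from the scene seed, so rendering is byte-reproducible. The single
channel is replicated to RGB with a slight warm tint (R + 6, B − 6).

**What the generator does not emulate:** overlapping or clumped cells
(rouleaux), white cells and platelets, real point-spread functions and
chromatic aberration, and the true (unpublished) noise statistics of the
device, for which Gaussian noise is a stand-in. Consequently, passing the
synthetic validation shows the chain is internally correct and robust to
the modelled nuisances — vignetting, moderate noise, dirt — but it does
not bound performance on real captures, where cell clumping and focus
variation dominate the error budget.

## Reference study and problem sizes

The package's reference validation (in `scripts/acceptance.R` and the
acceptance test) uses 22 images at the default conditions above, matched
at 3 µm. On this clean-but-nontrivial regime the detector saturates the
reference floors (recall and precision 1.0, R² 1.0, MAE and MSE 0):
well-separated anti-aliased cells inside a conservative radius gate leave
the Hough stage little room to fail, and dirt speckles are excluded by
the gate itself. Property sweeps (recall across 50 seeds, noise
monotonicity at σ ∈ {0, 15, 40}) run on 1200 px frames with 3–6 cells —
the same optics and cell sizes in a smaller field — to keep many-seed
panels affordable; the invariants they check are scale-free.

## Known limitations

* The Hough radius estimate is quantized to integer pixels and reported
  without sub-pixel refinement; at 4.88 px/µm one pixel is ≈ 0.2 µm.
* Vote thresholds are absolute counts; drastically different image sizes
  or edge densities may need re-tuning via the configuration.
* The FOV estimator assumes a single dominant bright region; multi-FOV
  or heavily occluded captures are out of scope.
* Evaluation against real manual counts inherits the ambiguity of the
  manual protocol (who counted, at what tolerance); results on real data
  are reported, not asserted.
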