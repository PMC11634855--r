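# smearcount

Automated red blood cell counting for photographs taken through low-cost
clip-on smartphone microscopes.

Point-of-care blood analysis with a phone-mounted ball-lens microscope
produces images with a characteristic look: a bright circular field of view
(FOV) on a dark surround, uneven flashlight backlighting, dirt speckles
from the unsealed optics, and erythrocytes that appear as rings (their
biconcave shape leaves a paler center) of roughly 2.5–5 µm radius at a
pixel resolution of about 26.3 px/µm. `smearcount` implements the full
analysis chain for such captures, for researchers and developers of
smartphone microscopy pipelines:

1. **Preprocessing** — FOV isolation (Otsu threshold, largest connected
   component, minimal enclosing circle), square crop, BT.601 grayscale,
   min–max normalization over the FOV, tracked downscale to a 501 × 501
   working image, then Gaussian smoothing (5 × 5), sharpening with the
   stencil

   ```
   -1 -1 -1
   -1  9 -1
   -1 -1 -1
   ```

   a 5 × 5 median filter, CLAHE (clip limit 1.0, 8 × 8 tiles), and
   brightness/contrast adjustment `(v + 7) × 1.02`.
2. **Detection** — a Hough circle transform parameterized in micrometres.
   Radii are gated to [2.5, 5] µm and detections must be ≥ 4.5 µm apart;
   the µm→px conversion uses the *effective* resolution tracked through
   resizing (`effective_px_per_um = raw_px_per_um × resize_factor`). The
   production detector votes along Canny gradient directions; an
   exhaustive 3-D accumulator (`hough_bruteforce()`) is kept as the
   reference implementation.
3. **Validation** — detections are matched one-to-one to ground truth by
   center distance; the report gives precision and recall (per-image
   mean ± SD and pooled), count MAE = mean|ŷ−y| and MSE = mean(ŷ−y)²,
   and the OLS fit ŷ = a·y + b with R² = 1 − SS_res/SS_tot.
4. **Synthetic data** — a seeded generator of µ-scope-like smears with
   exact ground truth (vignetting, ring-profile cells with central pallor,
   sensor noise, dirt speckles), so the whole pipeline is testable with no
   external data.

## Worked example

```r
library(smearcount)

# a synthetic capture with known ground truth
scene <- generate_scene(synth_params(), seed = 101)
img   <- render_scene(scene)               # 3000 x 3000 RGB, 26.3 px/um

proc  <- preprocess(img, optical_calibration(), enhance_params())
proc
#> <processed_image 501 x 501, 4.88 px/um effective, stages: crop -> grayscale -> fov_mask -> normalize -> resize -> enhance>

res <- count_cells(proc, detection_params_um())
res
#> <cell_count_result: 23 cells, radius gate [12, 25] px, min separation 22 px>

nrow(scene$cells)
#> [1] 23
```

The processed image keeps 4.88 px/µm after the ~6× downscale, so the
2.5–5 µm physiological radius gate becomes 12–25 px and the 4.5 µm
separation becomes 22 px. Here the detector finds exactly the 23 rendered
cells.

A shell interface wraps the same functions:

```sh
inst/cli/smearcount synth --n 22 --seed 42 --out data/
inst/cli/smearcount count --out results/ data/*.png
inst/cli/smearcount evaluate --detections results/detections.csv \
    --counts results/counts.csv --truth data/ --out eval/
```

`evaluate` prints the validation report and writes `report.json` plus a
manual-vs-algorithm scatter plot.

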