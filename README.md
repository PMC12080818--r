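# fhcdsr

Unsupervised change detection for bi-temporal hyperspectral images of
agricultural scenes — for remote-sensing practitioners who have two
co-registered hyperspectral cubes of the same fields at different dates and
want a per-pixel change map without training data.

## The method

Given cubes $I^{T1}, I^{T2} \in \mathbb{R}^{rows \times cols \times bands}$,
the pipeline is:

1. **Mirror padding** — each band plane is enlarged by one pixel per side
   (edge-inclusive reflection) so every pixel has a full 3×3 window.
2. **Spatial reconstruction** — each spectrum $X_0$ is replaced by the
   solution of the weighted zero-Laplacian constraint over its 4-neighbors,
   $w_0 X_0 - \sum_{i=1}^{4}\tilde w_i X_i = 0$, where the normalized
   weights $\tilde w_i = w_i / \sum_j w_j$ come from spectral similarity
   (cosine by default) between the center and each neighbor. Alike neighbors
   dominate, so noise inside homogeneous fields is smoothed while boundary
   neighbors contribute little. Both dates are reconstructed independently
   in a single deterministic pass.
3. **Windowed detection** — each pixel is scored by the 3×3-window
   band-energy difference weighted by a modified spectral angle of the
   center spectra:

   $$D = \Big|\sum_{k=0}^{8}\sum_{b=1}^{bands}\big(y_{kb}^2 - x_{kb}^2\big)\Big|
         \cdot \arctan\!\Big(\big(\tfrac{\langle X_c,Y_c\rangle}{\lVert X_c\rVert \lVert Y_c\rVert}\big)^2\Big)$$

4. **Evaluation** — threshold-free ROC/AUC against a ground-truth mask
   (Mann–Whitney tie handling), plus Otsu/quantile/fixed thresholding for
   binary maps.

Per-pixel baselines **AD** (L2 norm of the spectral difference) and **AAD**
(band-mean absolute difference) are included for comparison. Cubes are read
from ENVI (`.hdr` + binary, any interleave), GeoTIFF, or MATLAB MAT v5
containers, with 1-based band-exclusion preprocessing for uncalibrated bands
(e.g. `exclude_bands(cube, c("1-7", "58-76", "225-242"))` takes a 242-band
Hyperion cube to the 198 calibrated bands). A seeded synthetic scene
generator provides benchmark scenes with known truth.

## Worked example

```r
library(fhcdsr)

scene  <- generate_scene(scene_spec())       # standard benchmark, seed 17
scene
#> Synthetic bi-temporal scene: 64 x 64 x 40, 4 classes, seed 17
#>   changed pixels: 409 of 4096 (9.99%)
#>   noise_sigma = 0.05, gain_t2 = 1.05

scores <- detect_change(scene$t1, scene$t2, method = "fhcdsr")
scores
#> Change score map (fhcdsr): 64 x 64 pixels, min-max normalized
#>   scores: min 0, median 0.06327, max 1

roc(scores, scene$truth)
#> ROC curve: 409 positives, 3687 negatives, 4096 threshold steps
#> AUC = 94.366%

auc_report(list(
  fhcdsr = roc(scores, scene$truth),
  ad     = roc(detect_change(scene$t1, scene$t2, method = "ad"),  scene$truth),
  aad    = roc(detect_change(scene$t1, scene$t2, method = "aad"), scene$truth)))
#> AUC comparison
#>   fhcdsr         94.366
#>   ad             99.989
#>   aad            99.992  *best*

mask <- threshold_map(scores, "otsu")        # binary change map
sum(mask)
#> [1] 186
```

The AUC row is the fraction of (changed, unchanged) pixel pairs the detector
ranks correctly, as a percentage. On this low-noise scene the per-pixel
baselines win: the 5% inter-date gain hands every unchanged pixel an energy
drift the windowed statistic sees at full angle weight. The reconstruction's
value shows in the noise-limited regime — rerun with
`scene_spec(noise_sigma = 0.2)` and fhcdsr beats AD by ~7 AUC points (the
acceptance script below computes both regimes). See the methods vignette
(`vignettes/fhcdsr-methods.Rmd`) for the full analysis.

Real benchmark pairs (e.g. the Hermiston Hyperion scenes) distributed as
MAT files run through the same calls:

```r
t1 <- exclude_bands(read_cube("hermiston_2004.mat"), c("1-7", "58-76", "225-242"))
t2 <- exclude_bands(read_cube("hermiston_2007.mat"), c("1-7", "58-76", "225-242"))
roc(detect_change(t1, t2), read_mask("hermiston_truth.mat"))
```

A command-line wrapper with `simulate | detect | eval | run` subcommands is
installed at `system.file("scripts", "fhcdsr", package = "fhcdsr")`, e.g.

```sh
fhcdsr detect --t1 t1.mat --t2 t2.mat --truth gt.png \
       --exclude-bands "1-7,58-76,225-242" --threshold otsu --out-dir out/
```

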