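# curvseg

Automated offline analysis of scanning electron microscope (SEM)
micrographs. Manual measurement of particle fields — drawing grids over a
print and counting — is slow and subjective; `curvseg` replaces it with a
reproducible pipeline that enhances, segments and quantifies a micrograph
without operator intervention, reporting every measurement in pixel units.

The pipeline, for a gray-level image $I \in [0,1]^{H \times W}$:

1. **Denoise**: adaptive local-statistics Wiener filter,
   $\hat I = m + \frac{\max(v-\nu,0)}{\max(v,\nu)}(I - m)$, giving $I_W$.
2. **Enhance**: forward discrete curvelet transform (a tight frame of
   smooth dyadic radial annuli × angular wedges in the frequency plane);
   the inverse transform of the finest scale alone gives the detail image
   $I_{HP}$, and $I_e = \mathrm{clip}(I_W + I_{HP})$ sharpens the curved
   edges SEM objects typically have.
3. **Segment**: local Shannon entropy $E = -\sum_i p_i \log_2 p_i$ over a
   9×9 window marks textured particles; Otsu thresholding, morphological
   opening, small-object removal and hole filling yield the mask, whose
   8-neighbour boundary is overlaid on $I_e$ as the segmented image $I_S$.
4. **Quantify**: per region, area (pixel count), boundary-box perimeter
   (boxes of the filled shape touching its complement), and box-counting
   fractal dimension — the slope of $\ln N(r)$ versus $\ln(1/r)$ for an
   origin-anchored tiling with boxes of side $r$.

A conventional gradient-flooding watershed baseline and a deterministic
synthetic SEM-scene generator with exact ground truth support validation
and method comparison. See `vignettes/curvseg-methods.Rmd` for the full
methods account.

## Worked example

Generate a noise-free textured disk of radius 50 and push it through the
full pipeline:

```r
library(curvseg)

sc <- generate_scene(scene_spec(
  list(list(kind = "disk", center = c(128, 128), radius = 50,
            intensity = 0.7)),
  size = c(256L, 256L), noise_sigma = 0, seed = 7L))

res <- run_pipeline(sc$image, pipeline_config())
res$stats[, 1:4]
#>   label area_px perimeter_px fractal_dimension
#> 1     1    7644          284          1.809025

sc$truth$regions[, c("area_px", "perimeter_px")]
#>   area_px perimeter_px
#> 1    7845          280
```

One region is found. Its measured area (7644 px) is within 2.6% of the
rasterized ground truth (7845 px; the analytic $\pi \cdot 50^2 = 7854$),
and the boundary-box perimeter (284) within 1.4% of the true boundary-box
count (280). The fractal dimension 1.81 is the finite-scale box-count slope
of a solid disk — near, but below, the asymptotic planar value 2, as
expected for an object of this size.

The method-vs-baseline experiment mirrors a manual/proposed/watershed
comparison on synthetic scenes of overlapping textured particles:

```r
cmp <- run_comparison(seed = 1, n_scenes = 20)
cmp$summary
```

reporting mean relative area/perimeter errors for both methods and the
fraction of heavily overlapping scenes the watershed under-segments.

## Command line

A thin CLI over the same functions ships in `inst/scripts/`:

```sh
Rscript inst/scripts/curvseg.R run IN.png --out-dir out/
Rscript inst/scripts/curvseg.R segment IN.png --out seg.png --mask-out mask.png
Rscript inst/scripts/curvseg.R compare --seed 1 --n-scenes 20 --out-dir cmp/
```

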