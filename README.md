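# bioinkr

Quantitative tools for two workhorse measurements around suspension-cultured
human induced pluripotent stem cell (hiPSC) aggregates and the wholly
cellular bioinks compacted from them:

- **Aggregate morphometry.** Stirred-tank cultures grow near-spherical
  multicellular aggregates whose size and shape determine what they are good
  for (roughly 250–300 µm for differentiation, larger for passaging; loss of
  circularity flags fusion or shear damage). `bioinkr` segments dark
  aggregates in 8-bit brightfield images with a multi-pass rough circular
  Hough transform — votes over circle hypotheses
  `(x − A)² + (y − B)² = R²`, five radius windows with increasing
  *sensitivity* biasing split votes toward larger radii, cross-pass
  deduplication — and reports diameters, circularity, distribution
  summaries, Mann–Whitney comparisons between conditions and
  sampling-corrected fold expansion.
- **Bioink rheology.** Centrifuged aggregate slurries are jammed granular
  yield-stress materials. The package models steady shear with a thixotropic
  Herschel–Bulkley law,

  σ(γ̇) = σ₀ / (1 + λγ̇) + K γ̇ⁿ,

  and linear viscoelasticity with a five-parameter fractional Jeffrey model
  (two spring-pots in series, a Newtonian dashpot in parallel), providing
  forward evaluation, bounded multi-start least-squares fitting with
  broom-style `tidy()`/`glance()` output, yield-stress and critical-strain
  extraction, exponential flow-recovery fitting and the parallel-plate
  rim-stress correction σ_true = σ_app (3 + d ln σ/d ln γ̇)/4.

Every stage is testable offline: a seeded synthetic-data module renders
ground-truthed brightfield fields (known centers, radii, aspect ratios,
blur, noise) and rheograms (model curves under multiplicative lognormal
noise).

Two circularity scores are provided on purpose: the isoperimetric
`4πA/P²` (exactly 1 for an ideal circle) and the harmonic-mean area-ratio
variant computed from the segmentation (a perfect disk of radius r scores
`2(r−4)²/((r−4)² + r²)` ≈ 0.917 at r = 50 px). The methods vignette
(`vignettes/aggregate-morphometry-and-bioink-rheology.Rmd`) explains both,
along with every model, default and numerical choice.

## Worked example

```r
library(bioinkr)

# a synthetic brightfield field with 8 aggregates and known ground truth
field <- sim_field(n_aggregates = 8, width_px = 512, height_px = 512,
                   radius_range_px = c(20, 60), seed = 42)

# five-pass Hough segmentation, then per-aggregate morphometry at 2.5 um/px
morpho <- measure_aggregates(multi_pass_segment(field$image),
                             binarize(field$image), um_per_px = 2.5)
morpho[, c("radius_px", "votes", "diameter_um", "circ_harmonic")]
#> # A tibble: 8 × 4
#>   radius_px votes diameter_um circ_harmonic
#>       <dbl> <int>       <dbl>         <dbl>
#> 1        54   222         270         0.937
#> 2        40   190         200         0.915
#> 3        49   155         245         0.915
#> 4        38   125         190         0.894
#> 5        32   120         160         0.891
#> 6        34   114         170         0.887
#> 7        26    98         130         0.845
#> 8        21    69         105         0.798

summarize_distribution(morpho)
#>       n median_diameter_um iqr_diameter_um median_circ iqr_circ frac_diameter_le_300um frac_circ_ge_0p73
#>       8                180           58.75       0.892   0.0387                      1                 1
```

All eight aggregates are recovered (their true semi-major axes are in
`field$truth`); diameters are `2R` times the micron calibration, and the
median circularity of 0.89 with every aggregate at or above 0.73 is what a
healthy, well-stirred culture looks like. Fitting a noisy steady-shear flow
curve recovers the intrinsic yield stress:

```r
curve <- sim_flow_curve(sigma0 = 29.9, lam = 0.5, K = 8, n = 0.6,
                        noise_cv = 0.05, seed = 7)
fit <- fit_hb(curve)
tidy(fit)
#> # A tibble: 4 × 5
#>   term   estimate std.error conf.low conf.high
#> 1 sigma0   29.6       4.96    19.1       40.2
#> 2 lam       1.01      0.961   -1.03       3.04
#> 3 K        12.8       9.12    -6.54      32.1
#> 4 n         0.417     0.340   -0.304      1.14
```

The generating yield stress of 29.9 Pa (the magnitude measured for
compacted aggregate bioinks, an order above single-cell slurries) is
recovered as 29.6 Pa with the 5% noise reflected in the interval.
`autoplot(fit)` overlays data and fit; `fit_fjm()`, `critical_strain()`,
`fit_recovery()` and `parallel_plate_correct()` cover the oscillatory and
recovery protocols the same way, and `run_morphometry_pipeline()` runs the
whole imaging chain over a directory of PNG/TIFF files from a single YAML
configuration.

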