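# phlimr

Quantitative sub-cellular pH mapping from phasor FLIM images of the mApple
biosensor (pHLIM), as a tested R pipeline.

## The problem and who this is for

The pH of endo/lysosomal compartments (cytosol ~7.4 down to lysosomes <5)
controls degradation, trafficking, and the release of therapeutic cargo.
Intensity-based pH sensors confound pH with sensor concentration and lose
precision exactly at acidic pH, where their signal collapses. pHLIM instead
reads out the fluorescence *lifetime* of mApple, which falls linearly from
2.2 ns (pH 7.4) to 1.3 ns (pH 4.6): lifetime is concentration-independent,
needs no reference fluorophore, and a linear calibration keeps uncertainty
flat across the physiological range.

`phlimr` is for microscopists and image analysts with fast-FLIM (TCSPC)
data of mApple-family sensors, and for method developers who want a fully
synthetic, ground-truthed testbed of the analysis chain.

## The method

Each pixel's photon-arrival histogram is mapped to its fit-free phasor
coordinates

    G = Σ c_t cos(ωt) / Σ c_t,   S = Σ c_t sin(ωt) / Σ c_t,   ω = 2π f_rep,

with the phase lifetime τ_φ = S/(ωG). For mApple, G rises linearly with
acidity; pH follows from a linear calibration (the reference line through
the sensor's anchor pairs is pH = 11.3 − 10 G). Vesicles are detected in
the photon image (multi-scale LoG + watershed, or any external star-convex
model via an adapter), post-filtered (15 photons/pixel threshold, 2 µm²
area cutoff, optional label-wise erosion), and each vesicle's pH comes from
its photon-weighted mean G:

    Ḡ_vesicle = Σ (pixel photons × pixel G) / Σ pixel photons.

Image summaries report the unweighted mean, modal pH, and the 0.125/0.875
quantile "majority interval"; treatment arms are compared per timepoint by
the classic two-sample t-test; cargo load vs pH is reported as Pearson and
Spearman correlations. A synthetic generator (bi-exponential decays matched
exactly to the published lifetime/G/intensity anchors, Poisson photons,
vesicle scenes with ground truth) makes the whole pipeline testable without
a microscope. See `vignettes/phlim-methods.Rmd` for the full account.

## Worked example

```r
library(phlimr)

# The reference G-to-pH line and a conversion with its 95% prediction band
cal <- default_g_calibration()
cal
#> <g_calibration> pH = 11.3 -10 * G  (n = 5, resid SD = 4.93e-16 pH, G in [0.39, 0.62])
g_to_ph(c(0.60, 0.48), cal)
#> # A tibble: 2 × 3
#>       g    ph half_width_95
#>   <dbl> <dbl>         <dbl>
#> 1  0.6    5.3      1.88e-15
#> 2  0.48   6.5      1.74e-15

# Simulate a 100-vesicle scene and analyse it end to end
model <- photophysics_model()
scene <- simulate_cell_scene(scene_spec(n_vesicles = 100, seed = 1), model)
res <- analyze_scene(scene)
res$summary
#> # A tibble: 1 × 7
#>   mean_ph modal_ph majority_low majority_high n_vesicles timepoint condition
#>     <dbl>    <dbl>        <dbl>         <dbl>      <int>     <dbl> <chr>
#> 1    5.99     7.25         4.86          7.04        100        NA <NA>

head(res$vesicles[, c("label", "area_um2", "total_photons", "weighted_g", "ph", "ph_sd")], 4)
#> # A tibble: 4 × 6
#>   label area_um2 total_photons weighted_g    ph ph_sd
#>   <int>    <dbl>         <dbl>      <dbl> <dbl> <dbl>
#> 1     1    0.371         29772      0.378  7.52 0.175
#> 2     2    0.354         20722      0.502  6.28 0.115
#> 3     3    0.478         29247      0.403  7.27 0.198
#> 4     4    0.531         29432      0.400  7.30 0.277
```

The summary row reads: across the 100 detected vesicles (programmed pH
uniform over 4.6–7.4), the mean vesicle pH is 5.99, the most common pH bin
is 7.25, and the middle 75% of vesicles fall between pH 4.86 and 7.04. Per
vesicle, `weighted_g` is the photon-weighted phasor coordinate, `ph` its
calibrated conversion, and `ph_sd` the intra-vesicle spread of per-pixel pH.

Figures: `autoplot()` on phasor images and calibrations,
`plot_ph_histogram()`, `plot_ph_mask()`, `plot_timecourse()`.

A thin command-line front end is installed with the package
(`exec/phlim`): `phlim simulate|calibrate|phasor|segment|quantify|
timecourse|coincidence`, each a direct wrapper over the functions above.

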