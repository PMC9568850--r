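# colonychannels

Quantifies the **nutrient-transporting channels inside bacterial colony
biofilms** from calibrated fluorescence images. In mature *E. coli*
colonies expressing GFP, these channels appear as dark curves radiating
from the colony centre; their width (≈10–20 µm) and its radial trend
describe how the colony provisions its interior. The package is for
microbiologists and image analysts who have widefield or confocal images
of single colonies and want per-channel widths, radial trend fits, and
nonparametric comparisons across growth conditions — plus a synthetic
colony generator with programmable ground truth to validate every stage.

## Method

For a colony with centroid **c** and mask *M* (threshold = mean gray
level, foreground ≥ mean, largest 8-connected component, holes filled):

* the image is unwrapped about **c** into polar coordinates, *I*(r, θ_k),
  θ_k = 2πk/7200 (20 samples per degree), bilinearly interpolated;
* on each circumference (treated as circular), channels are detected as
  intensity peaks (after inversion) with topographic prominence
  ≥ 0.20 · (max − min) and pairwise distance ≥ 9 angular samples;
* each peak's width is the full width at half maximum, at level
  *h* = peak − prominence/2, with linear interpolation, converted to
  micrometres by arc length

  *w* = Δpx / 7200 · 2π r ;

* circumferences are sampled at r = 200, 250, 300, … µm, only where the
  full circle lies inside *M* (full-circumference exclusion);
* per-colony widths are filtered by the modified z-score
  *M_i* = 0.6745 (x_i − med) / MAD, removing |*M_i*| > 3;
* per-radius mean widths are fitted with w = β₀ + β₁ r and
  w = a·e^{b r} (log-linear least squares), compared by R²;
* groups are compared with Mann–Whitney U tests at normalised radial
  positions (20%, 50%, 100% of each colony's measurable radius) and on
  base areas.

CLAHE (block 60, slope 3, 256 bins) and a 3 × 3 despeckle are applied
before measurement by default — needed for faint channels in real
images. On high-contrast images CLAHE perturbs the half-maximum
crossings, so quantitative validation against ground truth runs with
`clahe = FALSE` (see the methods vignette,
`vignettes/channel-width-measurement.Rmd`).

## Worked example

```r
library(colonychannels)

# render a synthetic colony: radius 500 um, twelve 12-um channels
spec <- synthetic_spec(image_size_px = 800, colony_radius_um = 500,
                       n_channels = 12, seed = 7)
g <- synth_colony(spec)

cfg <- default_config()
cfg$clahe <- FALSE                      # high-contrast synthetic input
m <- measure_channels(g$image, cfg, biofilm_id = "demo",
                      condition = "synthetic")
m
#> channel_measurement 'demo' (synthetic)
#>   base area: 785456 um^2, centre (400.5, 400.5) px, max full radius: 498 um
#>   72 detections (71 retained) over 6 radii; 0 discarded at profile boundaries
#>   linear R^2 = 0.777; exponential R^2 = 0.777 (exponential trend)

head(m$series, 4)
#>   radius_um mean_width_um  n
#> 1       200      12.24681 12
#> 2       250      12.34269 12
#> 3       300      12.31976 12
#> 4       350      12.46543 12
```

Reading the output: the recovered base area (785 456 µm²) is within
0.01% of the programmed π·500² ≈ 785 398 µm²; full circumferences fit up
to 498 µm of the programmed 500 µm; all 12 channels are found on every
circumference, with mean widths within ~4% of the programmed 12 µm (the
small positive bias comes from the 0.5 px rendering blur); one detection
was dropped by the MAD outlier rule. The R² values are near-equal
because a constant width law fits both trend models equally well.

`plot(m)` draws the width-versus-radius box summary;
`write_measurement(m, "out/")` writes the per-detection table, per-radius
series, fits and a run log with every parameter. `compare_groups()`
performs the cross-condition Mann–Whitney comparisons. A thin CLI over
the same functions is in `inst/cli/colonychannels.R`
(`synth | measure | compare`).

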