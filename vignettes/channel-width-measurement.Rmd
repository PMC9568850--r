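---
title: "Measuring intra-colony channel width in biofilm images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intra-colony channel width in biofilm images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonychannels)
```

## The measurement problem

Mature colony biofilms of *E. coli* contain a network of cell-free,
nutrient-transporting channels that appear as dark curves radiating from
the colony centre in fluorescence images of GFP-expressing cells. Their
width — around 10–20 µm — and how it changes with radial position carry
information about how the colony supplies its interior with nutrients.
`colonychannels` measures those widths from calibrated grayscale images
and characterises their radial trend.

The chain of operations is:

1. **Segmentation.** The colony footprint is thresholded at the arithmetic
   mean of all gray levels (foreground = pixels ≥ mean — the tie rule is
   stated once and used everywhere). The largest 8-connected component is
   kept and interior holes are filled. The base area is the foreground
   count times the squared pixel size; the centre is the mask centroid,
   reported at sub-pixel precision.
2. **Polar unwrap.** The image is resampled about the centre so that
   circles become rows: row *i* holds the circle of radius *i − 1* source
   pixels, sampled bilinearly at 7200 angular positions (20 per degree).
   Samples falling outside the frame are flagged invalid rather than
   zero-filled.
3. **Enhancement.** Contrast-limited adaptive histogram equalisation
   (tiles of ≈60 px, slope limit 3, 256 bins), a 3 × 3 median
   ("despeckle"), and bit-range inversion so channels become bright peaks
   on circumferential profiles.
4. **Width measurement.** On each circumference (a *circular* profile —
   it has no endpoints, so maxima, prominences, distances and width
   crossings all wrap around), peaks with topographic prominence of at
   least 20% of the profile's range are kept; among peaks closer than
   9 angular samples the higher survives. Each peak's full width at half
   maximum is measured at the level `peak − prominence/2` with linear
   interpolation between samples, and converted to micrometres by arc
   length: `w = Δpx / 7200 · 2πr`.
5. **Radial analysis.** Circumferences are sampled every 50 µm from
   200 µm outward (closer to the centre the unwrap is too distorted),
   and only radii whose full circle lies inside the colony are used.
   Widths are filtered per colony with the modified z-score rule
   `M = 0.6745 (x − median)/MAD`, removing `|M| > 3` (strictly greater).
   Per-radius *mean* widths are fitted with a line and with
   `y = a·e^{bx}` (log-linear least squares), and compared by R².
6. **Group comparison.** Widths at normalised radial positions (20%,
   50%, 100% of each colony's largest measurable radius, nearest sampled
   grid radius) and base areas are compared across conditions with
   Mann–Whitney U tests (exact when `n_a·n_b ≤ 400` with no ties, normal
   approximation with tie and continuity correction otherwise).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pixel_size_um` | *(none — always explicit)* | µm/px | metadata cannot be trusted for custom mesoscale optics; never guessed |
| `n_angular` | 7200 | samples/turn | 20 samples per degree; oversamples the circumference so FWHM interpolation error is negligible |
| `clahe_block_size`, `clahe_max_slope`, `clahe_bins` | 60, 3, 256 | px, –, – | the standard FIJI CLAHE parameterisation for these images |
| `prominence_fraction` | 0.20 | of profile range | rejects noise peaks while keeping faint channels |
| `min_distance_px` | 9 | angular samples | about one *E. coli* cell length (2 µm) at the source image scale; kept fixed at every radius even though its µm equivalent grows with radius — fidelity to the described method |
| `radius_start_um`, `radius_step_um` | 200, 50 | µm | below 200 µm the polar raster is visibly distorted |
| `zscore_threshold` | 3 | modified z-score | standard MAD outlier cutoff; applied once per colony |

## When to disable CLAHE

CLAHE exists to make faint, low-contrast channels in real images
detectable at all. It is, however, a *rank-based, locally renormalising*
transform: on high-contrast images it measurably moves the half-maximum
crossings. The package's characterization tests show the two regimes on
synthetic ground truth: where a channel is wider than one contextual tile
(inner radii: a 12 µm channel spans ≈69 angular samples against a
60-sample tile), within-channel equalisation narrows the measured width
below truth; where a channel is much narrower than a tile (outer radii),
edge steepening widens it. The un-enhanced chain recovers programmed
widths within a few percent at every radius (the acceptance suite asserts
±10%).

Consequently `default_config()` keeps `clahe = TRUE` (the right choice
for dim real data — and the parameter values are fixed as above whenever
it runs), while all quantitative validation against synthetic ground
truth sets `clahe = FALSE`. Users measuring high-contrast or synthetic
images should do the same. This also means published absolute widths
obtained *with* CLAHE carry a radius-dependent bias of either sign; the
radial *trend* direction is preserved (the monotonicity checks pass with
either setting), but cross-study comparison of absolute widths should
state the enhancement setting.

## The synthetic colony generator

`synthetic_spec()` / `synth_colony()` render what the measurement chain
assumes: a roughly elliptical, dome-profiled bright colony
(`rim + (1 − rim)(1 − ρ^p)`, rim 0.35, p = 2) on a dark background,
carved with dark channels whose cross-section is a raised half-cosine —
chosen so that the programmed local width *is* the FWHM by construction,
making ground truth unambiguous. Channel trajectories are evenly spaced
radial rays with a small random angular jitter; `meander_amplitude > 0`
adds a smoothed random angular walk (the wandering, sharply turning
regime seen on nutrient-rich substrates; 0 gives the straight radial
regime of nutrient-limited growth). Channels fade in between 60 and
140 µm (solid centre) and fade out at 92–95% of the elliptical rim:
channels are interior structures, and a rim breached by sub-threshold
slits would corrupt both the mean-threshold mask and the
full-circumference exclusion. Gaussian blur is applied before Gaussian
and/or Poisson noise; renders are bit-identical for a fixed seed.

Defaults are chosen to emulate the study system at a tractable scale:
2 µm/px calibration, colony radius 1100 µm (so the 200–1000 µm radial
range is measurable), 24 channels, width laws spanning 12–22 µm
(constant 12; linear 12 + 0.008 r; exponential 12·e^{0.0006 r}), blur
σ = 0.5 px, Gaussian noise σ = 1% of the bit range.

What the generator does **not** emulate: cell-scale granular texture
(real GFP colonies are speckled at the ≈2 µm cell scale), sectoring,
out-of-focus haze, uneven illumination, or physically realistic channel
branching. Passing the synthetic acceptance checks therefore validates
the *geometry* of the measurement chain — unwrap, peak finding, FWHM,
arc-length conversion, exclusion rules, fits and tests — not robustness
to every real-data artefact.

## Numerical choices

* **Bilinear interpolation** for the unwrap; the angular axis oversamples
  the circumference (≈0.09 source px per sample at r = 200 µm), so
  interpolation smoothing is negligible against channel widths.
* **Invalid samples** (`NA`) propagate through the enhancement chain.
  CLAHE's tile code cannot skip pixels, so invalid samples are filled by
  replicating the last valid value along the radial axis, equalised, and
  re-masked — the frame edge never contaminates histograms near the rim.
  CLAHE tiles must divide the raster evenly, so the raster is padded by
  edge replication and cropped back.
* **FWHM reference level** is `peak − prominence/2`, not the global
  minimum: robust to sloping baselines (the dome makes baselines slope
  along ellipse circumferences). On a circular profile with a genuine
  peak the level is always crossed on both sides; the discard-with-warning
  path exists for degenerate indices.
* **Plateau peaks** (rectangular pulses) count once, at the plateau
  middle; equal-height maxima tie-break by index after sorting by height
  for the distance rule.
* **Degenerate fits:** a constant response defines R² := 0; exponential
  fits require strictly positive means and report log-space R² (the
  spreadsheet-trendline convention; original-space R² is available via
  `r_squared_space = "original"`).
* **Quartiles** use linear interpolation (R type 7, the NumPy default —
  the convention of the plotting stack these summaries mirror); whiskers
  are Q1 − 1.5·IQR and Q3 + 1.5·IQR clamped to the observed data.
* **Outlier filtering is single-pass** (applied once per colony). It is
  *not* exactly idempotent: removing gross outliers shrinks the MAD and
  can newly flag borderline points; a second pass removes nothing in the
  large majority of random draws, and the retained flags stored in the
  output are exactly the first-pass decision.

## Validation design and problem sizes

The test suite validates each operator against an independent brute-force
oracle (exhaustive neighbourhood medians, literal prominence walks, full
enumeration of Mann–Whitney labelings, a literal single-tile CLAHE
reference) and the chain end-to-end against synthetic ground truth:
constant 12 µm channels recovered within ±10% at every radius
200–1000 µm (blur σ ≤ 1 px) on 1600² px colonies; base areas of plain
ellipse colonies within 2% across axis ratios 0.7–1.0; no measurement
beyond the analytic full-circumference limit of an off-centre ellipse;
Mann–Whitney power ≥95% for a 25% width difference (lognormal, CV 0.3,
n = 500/group) with a type-I rate within 5% ± 2%.

For model discrimination, series are simulated from the generating laws
with multiplicative noise at the level the pipeline's per-radius means
actually exhibit — estimated in the acceptance run itself from the
residual scatter of the constant-law series (≈0.5%; a mean of ≥24
channel widths is stable, SE ≈ CV/√n). At that level the R² comparison
identifies the generating law in ≥90% of replicates in both directions.
At substantially higher noise (several percent) it does not: log-space
R² for the exponential versus original-space R² for the line is an
asymmetric comparison, intrinsically generous to the exponential — a
limitation of R²-only model choice worth knowing when interpreting small
R² differences on real data.

## Known limitations

* CLAHE-on width bias (above): absolute widths depend on the enhancement
  setting; record it alongside results.
* The 9-sample minimum peak distance is an *angular* distance, so its
  physical equivalent grows with radius; at large radii two channels
  closer than ≈`9/7200·2πr` µm would merge. This mirrors the described
  method; a µm-based distance would need a per-radius conversion of the
  detector parameters.
* No multiple-testing correction is applied across positions or condition
  pairs (none is part of the method); with many comparisons, adjust
  externally.
* Thickness estimation expects a z-profile with two clear minima; it uses
  a 3-point moving average (switchable) before locating them.

## A complete run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_channels = 24, seed = 11)
g <- synth_colony(spec)

cfg <- default_config()
cfg$clahe <- FALSE            # synthetic data are high-contrast
m <- measure_channels(g$image, cfg, biofilm_id = "demo",
                      condition = "synthetic")
m
plot(m)
write_measurement(m, "demo_run")
```
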