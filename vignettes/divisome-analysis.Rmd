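---
title: "Quantifying layered divisome structures from localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying layered divisome structures from localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(divlayers)
library(dplyr)
```

## The measurement problem

In *E. coli*, cytokinesis is driven by a multi-layered protein network at
midcell: the membrane-proximal FtsZ-ring, the FtsZ-binding protein ZapA at a
similar radial plane, the more internal ZapB layer, and MatP, which condenses
the chromosomal *ter* macrodomain and anchors ZapB to the nucleoid.
Single-molecule localization microscopy (PALM and its interferometric 3D
variant, iPALM) resolves these layers, but turning coordinate lists into
radial distances, displacements and turnover rates requires a chain of
quantitative procedures. `divlayers` implements that chain as composable,
tested functions:

* ring **morphometry** — band width and diameter of ring-like structures;
* **two-color colocalization** — channel registration from fiducial beads and
  a coordinate-based cross-correlation apparent displacement;
* **iPALM z-estimation** — surface-referenced mean axial positions;
* **radial models** — inferring a true radial distance from its 2-D
  projection;
* **FRAP** — turnover half-times with bootstrap errors;
* **expression calibration** — fluorescence to copy numbers and fractions.

Raw localization data for such studies are rarely deposited, so the package
carries a first-class synthetic-data module. Every generator produces data
with the statistical structure its analysis assumes and a known ground
truth, which is how the pipeline is validated end to end.

## Coordinate conventions

All coordinates are continuous nanometres. Analyses run in a *cell frame*:
origin at the cell center, x along the long axis, y along the short axis,
right-handed ([`cell_frame()`], [`to_cell_frame()`]). Displacements are
reported as absolute values where the underlying quantity is a magnitude
(apparent displacements, projected radial distances). Rendered images use
half-open 15 nm pixels with the origin at the minimum data corner — a
deterministic choice shared with common SMLM renderers.

## Ring morphometry

A division-protein "band" seen in a 2-D projection is modeled as a
cylindrical shell of diameter $d$ about the long axis whose long-axis
profile is Gaussian. Two measurements characterize it:

**Band width** is *defined* as the FWHM ($2\sqrt{2\ln 2}\,\sigma$) of a
Gaussian fitted by least squares to the binned long-axis density. The
definition is shared with the generator, so recovery is self-consistent.
Because the observed density is the true density convolved with
localization noise and the histogram kernel, the fitted variance is
corrected by subtracting, in quadrature, the mean localization precision
(when a `precision_nm` column is present) and the binning variance
$\mathrm{bin}^2/12$. Without this correction a 115 nm band imaged at 20 nm
precision reads ~124 nm — the measurement would report the blur, not the
structure.

**Diameter** follows the distal-peak procedure: project localizations onto
the short axis, bin at 15 nm, smooth with a 1-bin Gaussian, find local
maxima with topographic prominence at least 10% of the profile maximum, and
take the distance between the two *outermost* (not tallest) peaks. The
projection of a shell has one-sided edge singularities at $\pm d/2$, so
noise shifts the observed peaks systematically *inward*: at an effective
blur of ~25 nm the population-level peak sits ~22 nm inside the true edge,
a ~6% underestimate of $d$. `measure_band_diameter()` therefore inverts, by
default, the peak position of the noise-convolved projected-annulus density
$g(y) = \tfrac{1}{\pi}\int_0^{\pi} \phi_\sigma(y - R\cos t)\,dt$ at the
known noise scale
$\sigma_\mathrm{eff}^2 = \mathrm{precision}^2 + \mathrm{bin}^2/12 +
(\mathrm{smooth\_sd}\cdot\mathrm{bin})^2$. Set `deconvolve = FALSE` for the
raw peak distance.

```{r morpho}
cells <- lapply(1:8, function(s) {
  simulate_ring_band(diameter = 689, band_width = 115, n_molecules = 600,
                     loc_precision = 20, seed = s)
})
ring_morphometry(cells) |> summarize_rings()
```

Paired diameters of two species imaged in the same cells are related by
ordinary least squares (`fit_diameter_correlation()`); with a slope of 1 the
x-intercept is a constant diameter offset and half of it the radial
separation between the layers. Group comparisons use Welch's two-sample
t-test — the original comparisons do not name a test, and Welch's makes no
equal-variance assumption across strains.

## Two-color cross-correlation

Channel registration is a least-squares affine transform fitted to bead
control points (`fit_registration()`); with ~9 nm noise per channel and
axis, the post-fit RMS pair distance is ~18 nm, which is the registration
error floor this kind of setup reports. The apparent displacement between
two registered species is the $\Delta$ maximizing

$$C(\Delta) = \frac{1}{n_1 n_2}\sum_{i,j}
  \exp\!\left(-\frac{(x_i-x_j)^2 + (y_i-y_j-\Delta)^2}{2h^2}\right),$$

computed on coordinates, not pixels. Defaults: bandwidth $h = 30$ nm (near
the localization precision — smaller underweights true pairs, larger blurs
distinct layers together), grid $\pm 300$ nm in 5 nm steps (covers observed
inter-layer displacements). Ties break toward smaller $|\Delta|$, and the
per-cell result is $|\Delta|$; the magnitude convention means even two
identical structures report a positive mean displacement at finite
precision, which is why a same-species control pair defines the resolution
floor.

## iPALM z-positions

The coverslip surface, coated with a fluorescent dye, is located by a
Gaussian fit to the 1-nm-binned z histogram of the surface channel (sharp
surfaces fit with ~10 nm FWHM; above 50 nm the fit warns). Molecule
z-positions are then averaged inside a box at the bottom of the cell —
defaults 150 nm deep and 200 nm wide, avoiding curved side regions — and
referenced to the surface. Species are compared with the two ~4 nm
fluorescent-protein label sizes combined in quadrature
($\sqrt{4^2+4^2} = 5.7$ nm); standard errors join the quadrature by default
(`include_se = FALSE` reproduces the label-only 5.7 exactly). The box is
placed by the surface fit rather than by hand, making a manual step
reproducible.

## Radial models for chromosome-anchored clusters

A cluster at radius $r$ from the cell axis with uniform angular position
$\phi$ projects onto the short axis at $r' = |r\cos\phi|$, so
$E[r'] = \tfrac{2}{\pi}E[r]$ — a cluster population at mean radius 280 nm
shows a mean projected displacement of only ~180 nm. Two models are fitted
to an observed $r'$ sample, both on 60 nm histograms normalized to unit
area:

* **Gaussian radius**: $r \sim N(\mu_r, \sigma_r)$ with negative draws
  rejected (~1% rejection at 280/120; negligible bias). The fit is
  simulation-based over a $(\mu, \sigma)$ grid with 1000 simulated
  projections per candidate; a common seed across candidates (common random
  numbers) keeps the least-squares surface smooth enough for a grid argmin.
* **Uniform disk**: $(y,z)$ uniform on a disk of radius $R$, giving the
  analytic projected density $f(r') = \frac{4}{\pi R^2}\sqrt{R^2-r'^2}$,
  integrated exactly per bin; moments $E[r]=2R/3$, $\mathrm{sd}(r) =
  R/\sqrt{18}$.

Cluster candidates come from `detect_clusters()`: threshold at a fraction of
the image maximum, 8-connected components, intensity-weighted centroid and
second-moment ellipse (major axis $= 4\sqrt{\lambda_1}$, the standard
region-properties convention). Long-axis positions are summarized as binned
means by cell length; no parametric model is imposed on the migration.

```{r radial}
obs <- simulate_radial_clusters(613, "gaussian", mu_r = 280, sigma_r = 120,
                                seed = 11)
fit_uniform_disk(obs$r_proj) |> tidy()
```

## FRAP turnover

Traces follow the acquisition used for slow-growth divisome turnover: 120
frames at 2 s (30 frames/min for 4 min), bleach during frame 2, so frame 3
is the first post-bleach acquisition. Screening keeps traces whose bleach
ratio $(I_B(1) - I_B(3))/I_B(1)$ exceeds 40%. Normalization pins $I_B(3)$
to 0 and uses the mean of the last 60 midcell-ROI frames as the maximum,
because the midcell ROI is far more stable than the bleach-ROI tail.
Accepted traces are averaged *then* fitted — the same order as the original
procedure — to $R(t') = A(1 - e^{-kt'})$ with the amplitude free in
$(0, 1.2]$ (observed plateaus sit below full recovery); $\tau_{1/2} =
\ln 2/k$. Bootstrap standard errors resample whole traces 3000 times,
refitting the averaged resample each time.

## Expression calibration

With a reference fusion known to be a fraction $f$ of total (wt + fusion)
protein, the per-molecule intensity is $k = I_\mathrm{ref} \big/
\left(\tfrac{f}{1-f} N_\mathrm{endog}\right)$; any other fusion's intensity
then converts to copies and a fraction of total. The fraction-of-total
reading of "$f$ of the total" is the default; a fraction-of-wild-type mode
is available. Fractions are reported to 0.1% — coarser statements usually
round to the nearest 5%.

## What the simulations do and do not show

The generators reproduce the statistical structure the analyses rely on:
shell geometry with Gaussian axial profiles, independent two-channel
detection with registration error, projection geometry for radial models,
Gaussian axial noise over a sharp dye surface, single-exponential recovery
with stable midcell reference. They deliberately omit fluorophore
photophysics (blinking and re-localization of single molecules), camera
noise, drift, segmentation error in defining cell frames, and any
background structure. Passing recovery tests therefore demonstrates that
the estimators are unbiased and self-consistent under the stated model —
not that real images are free of those omitted effects.

Default problem sizes mirror the study conditions (54 ring cells at 600
molecules, 613 clusters, 59 FRAP traces, 125/315 iPALM cells) and run in
seconds to a couple of minutes on one core; validation tests use smaller
replicate counts where only an ordering or a ratio is being checked.

## Numerical choices and limitations

* Histogram bins: 15 nm for profiles (display pixel), 60 nm for radial
  models, 1 nm for surface fits. All binning is half-open with deterministic
  origins.
* Degenerate inputs: single-coordinate bands report width 0 with a warning;
  unimodal profiles raise a typed no-diameter condition so callers can score
  cells unmeasurable; empty iPALM boxes yield `NA` and drop from cross-cell
  means; zero-variance group comparisons use the p = 1 / p = 0 convention.
* The diameter deconvolution assumes an annular cross-section; for genuinely
  non-annular profiles use `deconvolve = FALSE`.
* The cross-correlation kernel form is a faithful but non-unique reading of
  coordinate-based colocalization analysis; its bandwidth trades resolution
  against variance and is exposed as a parameter.
* The Gaussian-radius fit is a grid search; its resolution is the grid step,
  and the objective, while smoothed by common random numbers, remains a
  simulation-based least squares rather than a likelihood.
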