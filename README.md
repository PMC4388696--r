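# divlayers

Quantitative analysis of the multi-layered bacterial division machinery
from single-molecule localization microscopy (PALM/iPALM) data.

In *E. coli*, division proteins organize into concentric layers at midcell:
the membrane-proximal FtsZ-ring, ZapA at a similar radial plane, a more
internal ZapB layer, and MatP anchoring the chromosomal *ter* macrodomain
~280 nm from the cell axis. `divlayers` provides the measurement chain for
characterizing such layered structures from localization coordinates:

- **Ring morphometry** — band width as the Gaussian FWHM
  (2√(2 ln 2)·σ) of the long-axis density, and ring diameter as the
  distance between the two most distal peaks of the short-axis projection,
  both with principled deconvolution of localization noise.
- **Two-color colocalization** — affine channel registration from fiducial
  beads, and the coordinate-based cross-correlation apparent displacement
  C(Δ) = (n₁n₂)⁻¹ Σᵢⱼ exp(−[(xᵢ−xⱼ)² + (yᵢ−yⱼ−Δ)²]/2h²), maximized over Δ
  along the short axis.
- **iPALM z-positions** — coverslip-surface location from a Gaussian fit to
  the dye-layer z histogram, boxed per-cell mean z above the surface, and
  species displacements with label sizes combined in quadrature.
- **Radial projection models** — a cluster at radius r with uniform angle φ
  projects to r′ = |r cos φ| (so E[r′] = (2/π)E[r]); fits for a Gaussian
  radius N(μᵣ, σᵣ) (simulation-based grid search) and a uniform disk of
  radius R with analytic density f(r′) = 4/(πR²)·√(R²−r′²) and moments
  2R/3, R/√18.
- **FRAP turnover** — 40% bleach-ratio screening, two-ROI normalization,
  average-then-fit single exponential R(t′) = A(1−e^(−kt′)), τ½ = ln2/k,
  and 3000-resample bootstrap standard errors.
- **Expression calibration** — integrated fluorescence to copy numbers and
  fraction of total (wt + fusion) protein via a reference fusion.
- **Synthetic data** — seeded generators for every analysis (ring bands,
  two-color pairs, radial clusters, iPALM layers, bead control points,
  FRAP traces) with known ground truth.

Functions take data frames (localization tables with `x_nm`, `y_nm`,
optional `z_nm`, `frame`, `channel`, `precision_nm`) and return tibbles or
small fitted objects with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Measure 54 synthetic ring cells generated at a 115 nm band width and
689 nm diameter with 20 nm localization precision:

```r
library(divlayers)
library(dplyr)

cells <- lapply(1:54, function(s) {
  simulate_ring_band(diameter = 689, band_width = 115, n_molecules = 600,
                     loc_precision = 20, seed = s)
})
ring_morphometry(cells) |> summarize_rings()
#> # A tibble: 1 × 5
#>   n_cells width_nm se_width diameter_nm se_diameter
#>     <int>    <dbl>    <dbl>       <dbl>       <dbl>
#> 1      54     117.    0.883        687.        1.59
```

The per-cell mean width (117 ± 0.9 nm) and diameter (687 ± 1.6 nm) recover
the generating values. A two-color pair with a 97 nm short-axis offset and
18 nm registration error:

```r
tc <- simulate_two_color(613, 161, 500, loc_precision = 20, shift_y = 97,
                         registration_sd = 18, seed = 1)
crosscorr_displacement(filter(tc, channel == "1"),
                       filter(tc, channel == "2"))
#> <xcorr_result> apparent displacement 95.0 nm (h = 30 nm, step 5 nm)
```

FRAP turnover from 59 simulated traces at a 19.8 s half-time:

```r
traces <- simulate_frap(19.8, n_traces = 59, noise_sd = 0.05, seed = 2)
frap_pipeline(traces, n_boot = 200, seed = 3)
#> <frap_fit> half-time 19.56 s (k = 0.0354 1/s, A = 0.75, 59 traces)
```

Radial placement of chromosome-anchored clusters from their projected
short-axis displacements:

```r
obs <- simulate_radial_clusters(613, "gaussian", mu_r = 280, sigma_r = 120,
                                seed = 4)
fit_uniform_disk(obs$r_proj)
#> <radial_fit disk> r_max = 405 nm -> r = 270 +/- 95 nm (sse 4.21e-07, n = 613)
```

Expression fraction of a fusion measured at 94,000 intensity units against
a reference calibration (46,000 units = 30% of total at 5,000 endogenous
copies):

```r
calib <- expression_calibration(46000, 0.30, 5000)
fusion_fraction(94000, calib, endog = 5000)
#> # A tibble: 1 × 2
#>   copies fraction_pct
#>    <dbl>        <dbl>
#> 1  4379.         46.7
```

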