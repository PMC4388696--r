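Package: divlayers
Title: Quantitative Analysis of Multi-Layered Bacterial Division Structures from Single-Molecule Localization Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the spatial organization and dynamics of the
    bacterial divisome from single-molecule localization microscopy (PALM/iPALM)
    coordinate tables. Provides ring-structure morphometry (band width and
    diameter), coordinate-based two-color cross-correlation displacement
    analysis with fiducial-bead channel registration, surface-referenced
    axial (z) position estimation for interferometric PALM, radial-projection
    model fitting for chromosome-anchored protein clusters (Gaussian-radius
    and uniform-disk models), FRAP recovery-curve screening, normalization and
    single-exponential half-time fitting with bootstrap standard errors, and
    fluorescence-based expression-fraction calibration. A synthetic-data module
    generates ground-truth localization tables, two-color pairs, bead control
    points, iPALM layers and FRAP traces with known parameters for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
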