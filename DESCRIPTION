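Package: kneescale
Title: Label-Free Standardization of Direct-Infusion Mass Spectra by
    Knee-Point Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw peak intensities of direct-infusion mass spectra
    (e.g. blood-plasma metabolomics fingerprints) to a dimensionless,
    instrument-independent scale without chemical calibration standards.
    A window of fixed m/z width slides across the spectrum; within each
    window the peak intensities are ranked in descending order and fitted
    with a power curve y = a*x^b + c, whose knee (maximum-curvature) point
    serves as an internal standard.  A smoothing spline through the
    per-window knee values forms a normalization curve, and every peak
    intensity is divided by the curve value at its m/z.  The package also
    provides a synthetic plasma-like spectrum simulator, biological-noise
    and distortion models for validating the procedure, and
    method-comparison statistics (linear concordance, Spearman correlation,
    Passing-Bablok regression) for standardized spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
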