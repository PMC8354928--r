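Package: striamark
Title: Striated Tool-Mark Signature Analysis for Cartilage-Analogue Test Materials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative examination of striated cut marks in cartilage-analogue
    test materials. Converts 3D surface scans (STL meshes, delimited height
    grids or 16-bit rasters) of marks and casts into per-row striation
    profiles, detrends them with a moving average, aligns them by normalized
    cross-correlation with an exhaustive lag search, and averages them into a
    mark signature with the quality metrics X_max and L_Xmax. Signatures are
    compared in known-match / known-non-match studies via the score X_C.
    Companion tools cover the image-contrast metric of casting materials under
    oblique illumination, Young's modulus estimation from Hertzian spherical
    indentation curves, a cleaning-score scheme with summary-statistic t-tests,
    and a synthetic generator for knives, marks, grain-like dot artifacts and
    whole comparison studies so the complete pipeline runs without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
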