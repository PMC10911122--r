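Package: echorange
Title: Quantitative Ultrasonogram Echotexture Analysis and
    Correlation-Maximizing Intensity-Range Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: First-order echotexture analysis of 8-bit grayscale
    ultrasonograms over polygonal regions of interest: per-image affine
    intensity normalization, echointensity (EI) band statistics (pixel
    frequency, mean numerical pixel value, heterogeneity) with the standard
    50- and 25-unit band presets, and an exhaustive search over all
    contiguous grayscale intensity ranges for the range whose per-subject
    mean pixel value correlates most strongly with an external per-subject
    measurement (e.g., protein expression of inflammatory mediators).
    Includes a greedy scattered-intensity-set heuristic, threshold mapping
    of selected ranges, a permutation test that corrects the selection bias
    of the searched maximum correlation, and a seeded synthetic
    speckle-cohort generator with planted range/marker coupling for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
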