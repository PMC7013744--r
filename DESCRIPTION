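Package: uniftex
Title: Universal Texture Feature Selection for Multi-Setting Ultrasound
    Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for selecting a single "universal" texture feature
    subset that classifies breast-lesion ultrasound regions of interest
    consistently across several scanner acquisition settings.  Provides a
    126-feature texture bank (histogram, gray-level co-occurrence,
    statistical feature matrix, run-length, Laws energy, neighboring
    gray-level dependence, neighborhood gray-tone difference, wavelet
    LL-subband and local Fourier descriptors) computed on small grayscale
    blocks; three cross-dataset filter scores (an augmented Sorensen-Dice
    ratio, a dispersion-normalized multi-dataset t-score, and a paired
    Pearson consistency score); a genetic-algorithm wrapper whose fitness
    combines per-setting support-vector-machine cross-validation
    accuracies with a penalty on their spread; a paired multi-setting
    synthetic data generator; and an end-to-end selection pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
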