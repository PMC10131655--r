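Package: tileppg
Title: Tile-Based Region-of-Interest Selection and Aggregation for Remote
    Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for dynamic region-of-interest selection in remote
    photoplethysmography (rPPG). Facial-video tile signals are scored with
    a frequency-domain signal-to-noise metric (SNR-F: spectral power at
    the pulse rate +/- 0.15 Hz against the remainder of the 0.5-5 Hz
    band), and the best-scoring 20x20-pixel tiles are aggregated into a
    single pulse signal by weighted, best-n, and time-segmented
    algorithms. Includes signal-quality category modelling from labelled
    SNR-F scores with transition and promotion analyses, and a synthetic
    facial-video generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
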