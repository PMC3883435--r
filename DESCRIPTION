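Package: chipcode
Title: Colorimetric Sensing-Array Image Analysis, Binary Fingerprint Coding
    and Concentration Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for colorimetric sensing arrays run in
    96-well plates (eight dye sensors DC1-DC8 under multiple buffer
    conditions). Reads flatbed plate scans, sums red, green and blue pixel
    values over a fixed region of interest in each well, differences
    analyte wells against paired control wells, converts the differences
    into binary identification codes via a significance threshold,
    matches codes against a library by Hamming distance, and fits linear
    standard curves that invert averaged color differences (or UV-Vis
    absorbance changes and peak shifts) into analyte concentration
    estimates. Includes seeded synthetic generators for plate scans,
    replicate difference tables and absorbance spectra so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
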