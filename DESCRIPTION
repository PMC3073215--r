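Package: fishdots
Title: Fluorescent Dot Counting and HER2/CEP17 Scoring for Two-Probe FISH Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates HER2/neu amplification status from two-probe fluorescence
    in situ hybridization (FISH) microscopy images. Nuclei are segmented from
    the DAPI (blue) channel with Otsu thresholding and marker-controlled
    watershed; HER2 (red/orange) and CEP17 (green) probe signals are detected
    inside nuclei with two independent engines: a combined top-hat/bottom-hat
    morphological contrast enhancement, and an inverse multifractal selection
    built on per-pixel Hoelder exponents and the box-counting multifractal
    spectrum. Per-nucleus HER2/CEP17 ratios are averaged over scorable nuclei
    and the case is classified against the 1.8/2.2 decision bands. A seeded
    synthetic image generator with exact ground truth supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
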