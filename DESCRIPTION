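Package: lapqc
Title: Semi-Automated Image-Quality Analysis for Surgical Camera Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the four semi-automated optical image-quality
    analyses used to validate manufactured laparoscope cameras: limit of
    resolution on a USAF-1951 bar target (2:1 peak-to-trough contrast
    criterion), depth of field on a 5 line-pairs-per-millimetre ladder
    (half-initial-range failure rule with a 20-pair validation window),
    colour accuracy as CIE76 delta-E*ab and delta-C*ab against a reference
    CIELAB patch table, and SMIA TV geometric distortion from six grid
    landmarks. A synthetic test-chart generator with parametric optical
    degradations (Gaussian blur, one-term Brown-Conrady radial distortion,
    CIELAB colour offsets, sensor noise) provides machine-readable ground
    truth so every metric is validated without captured images.
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
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
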