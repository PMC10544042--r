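Package: dectspr
Title: Noise Sensitivity of Dual-Energy CT Proton Stopping-Power Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how image noise in dual-energy computed
    tomography (DECT) propagates into proton stopping-power-ratio (SPR)
    maps and simulated proton range. Implements three voxel-wise SPR
    mapping methods (a Jackson-Hawkes virtual-monoenergetic-image
    inversion, a Landry-Saito calibration method, and an alpha-blending
    superposition method), a virtual monoenergetic image pair optimizer,
    a synthetic cylindrical multi-insert phantom and repeated-acquisition
    noise simulator, region-of-interest noise statistics, and a simplified
    water-equivalent-path-length proton range model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    RNifti,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
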