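Package: lumipipe
Title: Post-Processing Pipeline for Cleared-Tissue Light-Sheet Microscopy Stacks
Version: 0.1.0
Authors@R: person("lumipipe", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational post-processing of light-sheet (ultramicroscopy)
    image stacks of cleared tissue: 16-bit contrast-limited adaptive histogram
    equalization (CLAHE), directional stripe-artefact removal with a pie-slice
    (wedge) notch filter in the 2D Fourier domain, unsharp masking,
    intensity-threshold segmentation and brightness-to-colour mapping.
    Includes a synthetic phantom generator with ground-truth masks (tubular
    vessels, dark nuclei, occluder shadows at a known angle) so the whole
    chain is testable without real recordings, plus small calculators for
    clearing-protocol arithmetic (chemical dehydration stoichiometry,
    section undersampling, volume shrinkage). Stacks are read and written as
    uncompressed grayscale multi-page TIFF or numbered slice sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
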