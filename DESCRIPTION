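Package: hawkmanr
Title: Multi-Scale Structural Error Mapping for Single-Molecule
    Localisation Microscopy Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects artificial-sharpening artefacts in single-molecule
    localisation microscopy (SMLM) reconstructions by comparing a test
    super-resolution image against a reference reconstruction across a
    Gaussian scale space of length scales.  At each scale both images are
    adaptively thresholded (Wellner local-mean method), binarised and
    skeletonised; windowed Pearson correlations of the resulting sharpening
    and structure representations are combined into a per-pixel confidence
    score, a set of colour diagnostic maps (sharpening, structure,
    confidence), global correlation metrics, and an artefact scale map
    giving the smallest length scale at which each image region can be
    trusted.  Includes a synthetic SMLM fixture generator that emulates
    density-induced localisation bias, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
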