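Package: geomrep
Title: Representational Analyses of Geometric Shape Regularity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how geometric regularity shapes the perception
    of quadrilaterals. Builds regularity-graded quadrilateral stimulus sets and
    corner-displacement deviants, extracts a discrete geometric feature code
    (right angles, equal angles, equal sides, parallel sides, up to a
    tolerance), estimates behavioral dissimilarity matrices from visual-search
    trials, and analyses multivariate neural patterns with cross-validated
    Mahalanobis (crossnobis) distances, whitened RDM correlations,
    time-resolved oddball decoding, volumetric searchlights, and cluster-based
    sign-flip permutation inference. A synthetic-data module generates
    behavioral trials, oddball miniblock designs, MEG-like epochs, and
    fMRI-like beta volumes with planted representational structure so that
    every analysis stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
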