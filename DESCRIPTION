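Package: distapp
Title: Distributional Learning of Visual Appearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether word-appearance knowledge can be
    acquired distributionally, i.e. whether words that occur in similar
    linguistic contexts tend to have referents of similar visual appearance,
    and whether that tendency supports zero-shot identification and naming
    of unfamiliar categories.  The package computes COALS-style
    distributional word distances from a token corpus, encodes images as
    Basic-Colour and oriented Basic Image Feature (oBIF) texton histograms
    compared with the Bhattacharyya distance, and decides two-alternative
    and multi-rival forced-choice trials with MIRRORING, PROXY and FOIL
    strategies.  A synthetic world generator couples linguistic and visual
    category structure with tunable strength so that the whole pipeline can
    be exercised and validated without external corpora or image
    collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    png,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
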