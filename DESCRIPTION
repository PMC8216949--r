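Package: pigmentr
Title: Decomposition of Insect Body Pigmentation into Color and Pattern
    Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies dorsal body pigmentation of flies from RGB images by
    sampling landmark-defined transects and decomposing each color profile
    into five component traits: overall darkness, pattern fraction, color
    range, background color angle, and pattern-element color angle.  The two
    enveloping lines of the darkness profile are estimated by iterative peak
    clipping (SNIP), and their median line separates darker pattern elements
    (thoracic trident, abdominal bands) from the lighter background cuticle.
    Includes a synthetic transect and fly-image generator with recorded
    ground truth for validation, trait-table summaries (group means, Pearson
    correlations with Holm adjustment), and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
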