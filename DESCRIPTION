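Package: segsel
Title: Integrated Multi-Criteria Selection of Semantic Segmentation Models
Version: 1.0.0
Authors@R:
    person("segsel", "authors", email = "maintainer@segsel.org", role = c("aut", "cre"))
Description: Pixel-level evaluation of binary segmentation masks (IoU, accuracy,
    recall, precision, F1 from confusion counts) and multi-criteria
    decision-making (MCDM) machinery for choosing among candidate models:
    benefit/cost min-max normalization of a decision matrix, CRITIC objective
    weighting (contrast intensity times inter-criteria conflict), expert
    subjective weighting, and a convex combination of both scores with
    deterministic ranking. Ships a 21-model x 8-criterion reference decision
    matrix from a gastric-polyp segmentation benchmark together with a
    command-line interface and synthetic mask/matrix generators for offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
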