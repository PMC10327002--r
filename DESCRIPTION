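Package: punctacoloc
Title: Object-Based Synapse Quantification by Puncta Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated quantification of structural synapses in multi-channel
    fluorescence images. Detects pre- and post-synaptic puncta as connected
    components of thresholded channel masks, counts red/green (and optionally
    blue) colocalizations by either a circular-approximation geometry or a
    pixel-overlap method, and performs grouped maximum-intensity projection of
    confocal z-stacks. Includes a simulated-synapse image generator with exact
    ground truth and precision/recall scoring for end-to-end validation, plus
    a batch driver that emits reproducible per-image CSV summaries, threshold
    audit tables, overlay images and thresholded masks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
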