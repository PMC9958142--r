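Package: pedicleSSM
Title: Statistical Shape Modelling of Vertebrae for Pedicle Screw Guide Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical shape models of vertebral surfaces from
    unordered 3D point sets. Implements rigid and non-rigid coherent point
    drift registration, relevance-based subsampling, dense correspondence with
    local refinement, projection-pursuit principal component analysis, mean and
    plus/minus-k-SD shape synthesis with per-vertex distance maps,
    leave-one-out generalisability analysis, partial-shape completion, and the
    pedicle morphometry protocol (width, height, transverse and sagittal
    pedicle angles) with guide-envelope summaries. Includes a parametric
    synthetic vertebra population generator with known ground-truth modes and
    landmarks for end-to-end validation, plus PLY/STL/OBJ mesh input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
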