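Package: rcnets
Title: Reverse-Complement Equivariant Networks for DNA Sequence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Convolutional sequence classifiers that are exactly symmetric
    under reverse complementation, obtained by tying convolution filter
    weights, pooling over reverse-complement orbits, and sampling symmetric
    Monte Carlo dropout masks. Includes a position-weight-matrix motif
    injection simulator for generating labelled regulatory-sequence datasets,
    a two-state hidden Markov model with exponential emissions for segmenting
    recombination-rate tracks into hotspots and coldspots (with GC-matched
    control extraction), degenerate motif scanning with binomial enrichment
    statistics, and harvesting of position weight matrices from trained
    first-layer filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
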