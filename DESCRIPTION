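Package: lysinITSS
Title: Screening Phage Endolysin Genes for Internal Translation Start Sites
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterising in-frame internal
    translation start sites (iTSSs) in phage lytic-enzyme genes. Provides a
    simplified Shine-Dalgarno translation-initiation-rate scorer with a
    precomputed-table override, a four-step filter cascade (background
    outlier, gene extremities, conserved-domain overlap, phage tail
    domains), percent-identity clustering with iTSS positional consensus,
    derivation and architecture classification of the full-length and
    C-terminal protein products, gel-filtration calibration via the
    partition coefficient, charge-state-series mass inversion for native
    mass spectrometry, and exhaustive heteromultimer stoichiometry
    enumeration. A synthetic cohort generator with ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
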