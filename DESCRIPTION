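Package: scTCRdog
Title: Single-Cell T-Cell Receptor Repertoire Analysis for the Dog
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for canine single-cell T-cell receptor (TRA/TRB)
    repertoire analysis. Provides an annotated V(D)J segment reference
    model with IMGT-style functional classes and CDR3 anchor discovery,
    a synthetic single-cell repertoire generator with junctional
    diversity, clonal-expansion profiles, chain-pairing noise and
    plantable germline defect rescues, a contig annotator (segment
    assignment, CDR3 extraction, productivity calling), clonotype
    construction with pairing taxonomy and Inverse Simpson diversity
    (including permutation downsampling), pseudogene-rescue sequence
    analysis with re-annotation proposals, and expanded-versus-
    non-expanded marker testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Transcriptomics, SingleCell, ImmunoOncology, Sequencing
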