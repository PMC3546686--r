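Package: sRNAtim
Title: Translation Initiation Modelling Under Small RNA Influence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Qualitative equilibrium modelling of bacterial translation
    initiation under the influence of a trans-acting small RNA (sRNA). From an
    mRNA with an annotated translation start, an sRNA sequence and per-gene
    copy-number estimates, the package locates the ribosome recognition site,
    enumerates filtered sRNA binding sites, computes constrained and
    unconstrained ribosome-docking-site accessibilities with a partition
    function over secondary structures, solves the mass-action equilibrium of
    the mRNA/sRNA/ribosome reaction network for overlapping and
    non-overlapping site topologies, and reports the signed fold change in
    translation-initiation complex formation for every candidate site. Sites
    changing initiation more than two-fold are classified as putatively
    regulatory. A deterministic synthetic-fixture generator provides
    repression, activation and null scenarios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
biocViews: Software, Transcription, GeneRegulation, StructuralPrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'energy-params.R'
    'sequence-io.R'
    'backend.R'
    'duplex.R'
    'accessibility.R'
    'equilibrium.R'
    'oracles.R'
    'expression.R'
    'screening.R'
    'fixtures.R'
    'cli.R'
    'sRNAtim-package.R'
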