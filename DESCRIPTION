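Package: mitonet
Title: Brain-Wide Mitochondrial Phenotyping and Mito-Based Brain Networks
Version: 0.1.0
Authors@R:
    person("Mitonet", "Developers", email = "mitonet@example.org",
           role = c("aut", "cre"))
Description: Tools for brain-wide mitochondrial phenotyping: quality control
    and derivation of mitochondrial features (respiratory-chain enzyme
    activities, mtDNA density and copy number, and the mitochondrial health
    index MHI) from raw plate and qPCR readouts; composite behavioral
    anxiety scores; mitochondrial connectivity matrices across brain areas;
    Mapper-based topological analysis of stress-induced mitochondrial
    recalibrations with a participation-coefficient segregation statistic
    and phase-randomized null testing; categorical multi-slice community
    detection with module allegiance and iterative consensus clustering to
    define mitochondria-based brain networks; cross-modal permutation
    validation of partitions against gene co-expression and structural
    connectome matrices; network-level mitochondria-behavior correlation;
    and MitoCarta-style pathway scoring of transcriptional mitotypes. A
    synthetic cohort generator with planted community structure makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
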