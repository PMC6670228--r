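Package: gliadinCRISPR
Title: Guide RNA Design and Edit Simulation for Wheat Gliadin Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing CRISPR/Cas9 single-guide RNAs against the
    tandem-arrayed alpha- and gamma-gliadin multigene families of hexaploid
    bread wheat and for quantifying the resulting mutation screens. The
    package annotates intronless gliadin coding sequences (translation,
    pseudogene calls, domain segmentation, coeliac-disease epitope scanning),
    classifies genes into epitope-signature subgroups with subgenome
    assignment, evaluates protospacer matches, PAM-dependent cut sites,
    family-wide coverage, off-targets and oligo secondary-structure
    heuristics, simulates multiplexed cutting and repair on tandem loci
    including intervening-gene deletion, and computes screening summary
    tables with chi-square heterogeneity tests. A seeded synthetic
    gliadin-family generator makes the whole pipeline testable without
    external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CRISPR, SequenceMatching, Annotation, Classification
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'classification.R'
    'utils.R'
    'synthetic.R'
    'defaults.R'
    'guides.R'
    'editsim.R'
    'io.R'
    'stats.R'
    'pipeline.R'
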