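Package: casematch
Title: Variant Watch-List Case Matching for Rare-Disease Diagnostics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A stand-alone, locally deployable case-matching engine for
    clinical genetics. Cases combine candidate ("in limbo") DNA variants
    with Human Phenotype Ontology (HPO) annotations. Each new submission
    is validated, left-normalized to minimal VCF-style representation,
    annotated against local gene models, checked against a local
    known-variant store, and matched against all previously submitted
    cases using a four-level genomic proximity scheme (identical variant,
    same position, same codon, same gene) refined by a path-based
    ontology similarity that rewards deep-rooted phenotype annotations.
    Includes synthetic-fixture generators (mini ontologies, toy genomes
    with gene models, case cohorts with planted match structure) so the
    whole engine is testable offline, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
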