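Package: taxrefiner
Title: Neural Refinement of Metagenomic Contig Taxonomy from Composition and Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines and completes per-contig taxonomic annotations from any
    metagenomic classifier by training, per dataset, a multilayer perceptron
    on tetranucleotide-frequency and multi-sample abundance features under a
    hierarchical softmax loss over the taxonomy tree observed in the
    annotations. Emits per-rank labels with likelihood scores, supports
    score-threshold filtering, a five-fold annotation self-consistency
    benchmark for ranking classifiers without ground truth, a novel-taxon
    (species-deletion) experiment, and a synthetic community generator for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
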