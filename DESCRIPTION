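Package: apmscout
Title: Spectral-Count Enrichment, Clustering and Network Analysis for AP-MS Interactomics
Version: 0.1.0
Authors@R: person("Adhesion Proteomics", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of affinity-purification mass-spectrometry
    (AP-MS) experiments quantified by spectral counting. Provides bait
    versus control enrichment ratios with a mean-plus-one-standard-deviation
    specificity threshold, hierarchical clustering of protein enrichment
    profiles under a Pearson correlation distance with rule-based cluster
    selection, protein-protein interaction subnetwork assembly with Venn-set
    partitioning across receptor variants, Gene Ontology style term rollup
    and hypergeometric overrepresentation analysis with Bonferroni
    correction, peptide-to-region construct validation, and a synthetic-data
    generator emulating a three-cell-line integrin adhesion complex
    experiment so that every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
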