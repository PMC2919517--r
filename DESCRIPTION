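Package: funset
Title: Over-Representation Analysis of Gene Lists Across Functional
    Vocabularies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Offline functional profiling of gene lists against a
    background list, driven entirely by local flat files.  Provides
    identifier validation and normalization against a local alias
    mapping table; over-representation analysis with a binomial
    upper-tail statistic and Benjamini-Yekutieli false discovery rate
    control across Gene Ontology, pathway, homology and chromosome
    vocabularies; parsing of OBO 1.2 ontology subsets into a rooted
    directed acyclic graph with annotation propagation (true-path
    rule), level computation and pruning to a user-chosen depth;
    Tanimoto (Jaccard) ranking of a local literature corpus against
    the study list; grouping of prior expression-study annotations;
    seeded synthetic study generators with planted enrichment signal
    for validation; and a command-line pipeline wiring the steps
    together with deterministic text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
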