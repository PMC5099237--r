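Package: defenseprofiler
Title: Defense-Feature Profiling of Assembled Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and quantifies prokaryotic defense systems in assembled
    metagenomes. Provides a seed-and-extend detector for CRISPR repeat-spacer
    arrays with a multi-profile consensus and validation protocol, cas gene
    identification and CRISPR-Cas type assignment from domain-annotation
    tables, spacer and direct-repeat analytics with a seeded local aligner
    for protospacer target search, restriction-modification system
    completeness calling and cluster merging from REBASE-role hits,
    coverage-based copies-per-megabase normalization with fold-change
    enrichment calls, community profiling (lowest-common-ancestor taxonomy,
    Bray-Curtis dissimilarity, complete-linkage clustering, GC content), and
    a synthetic-metagenome generator that plants ground-truth features for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    ape
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
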