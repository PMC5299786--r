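Package: funcvar
Title: Uncovering Functional Variation in Metagenomic Gene-Family Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying functional variation across metagenomic
    samples from gene-family (KEGG Orthology style) abundance tables.
    Implements single-copy marker-gene normalization of abundance profiles,
    identification and filtering of genome-prevalent gene families by
    copy-number coefficient of variation, genome co-occurrence-based
    aggregation of gene families (Jaccard distance plus complete-linkage
    clustering), uniform and support-based non-uniform mapping of gene
    families to pathways, variation and association statistics
    (coefficient of variation, Bray-Curtis distances, Mantel tests,
    Wilcoxon rank-sum pathway association), per-individual functional
    metagenomic fingerprint codes, and a seeded synthetic community
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
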