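Package: termlinker
Title: Non-Redundant Metagroups of Genes and Co-Annotated Functional Terms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processes functional-enrichment output into compact,
    significance-ranked metagroups of genes and co-annotated biological
    terms. Annotation catalogs (GO, KEGG, InterPro and similar, supplied
    as GMT or two-column TSV) are profiled for promiscuous generic terms
    by a Z-score outlier rule; gene/term frequent-itemset elements are
    generated by singular or concurrent (closed-itemset) hypergeometric
    enrichment; elements are filtered, clustered by Ward linkage on
    cosine distances over gene-occurrence vectors, merged by shared
    terms, compacted by a complete-cover redundancy rule and scored
    (FDR-adjusted hypergeometric test, silhouette width, diameter,
    similarity coefficient). Includes pair-based Rand/Jaccard and
    precision/recall/F-score benchmarking with a random-noise protocol,
    a synthetic annotation-space generator with planted gene modules,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
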