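Package: mirlink
Title: miRNA:mRNA Anti-Correlation Networks with Locus-Level Co-Expression Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative small-RNA and mRNA transcriptomics of
    disease subgroups: count filtering, TMM normalisation, negative-binomial
    likelihood-ratio differential expression, expression analytics for
    clustered (polycistronic) miRNA loci, construction of bipartite
    miRNA:mRNA anti-correlation networks intersected with target-prediction
    databases, and a resampling null model that tests whether a network
    carries more database-supported edges than size-matched random feature
    sets. A synthetic-data generator with planted ground truth makes every
    stage verifiable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
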