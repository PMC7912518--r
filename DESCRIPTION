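Package: citann
Title: Annotation Sharing Across Citation Neighborhoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how strongly biomedical articles share database
    annotations (genes, MeSH headings, variants) with their citation
    neighbors. Builds citation graphs from delimited citation-pair files,
    aggregates neighborhood annotations into frequency-ranked profiles, and
    evaluates them against each article's own annotations with recall,
    precision and average precision, stratified by the number of annotated
    neighbors, by neighborhood degree and by citation direction. Includes an
    edge-shuffle randomized null, coverage statistics, sigmoidal
    recall-versus-neighbors fits with bootstrap confidence intervals, and a
    seeded generator of topic-clustered synthetic citation corpora for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    igraph,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
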