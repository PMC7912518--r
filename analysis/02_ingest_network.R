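#!/usr/bin/env Rscript

# Stage 2: ingest the simulated text files through the production readers,
# build the citation graphs, and report dataset sizes and neighborhood
# coverage. Coverage answers: what fraction of the corpus has enough
# annotated neighbors for neighborhood-based annotation at all, and how much
# does widening to second-degree neighbors help?

suppressPackageStartupMessages(library(citann))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

summary_rows <- list()
coverage_rows <- list()
for (name in c("clustered", "uniform")) {
  base <- file.path("results/data", name)
  pairs <- read_citation_pairs(file.path(base, "citation_pairs.csv"))
  store <- read_annotation_table(file.path(base, "annotations.tsv"),
                                 dialect = "generic", dataset_name = name)
  graph <- build_graph(pairs)
  write_graph(graph, file.path(base, "graph.tsv"))
  s <- summarize_store(store)
  summary_rows[[name]] <- data.frame(
    dataset = name, annotations = s$n_annotation_rows, articles = s$n_articles,
    vocabulary = length(store$vocabulary), nodes = length(graph$nodes),
    citation_pairs = nrow(graph$edges)
  )
  universe <- graph$nodes
  for (deg in 1:2) {
    for (m in 1:2) {
      coverage_rows[[paste(name, deg, m)]] <- data.frame(
        dataset = name, degree = deg, min_annotated_neighbors = m,
        coverage = coverage(graph, store, universe, m, degree = deg)
      )
    }
  }
}

summary_tab <- do.call(rbind, summary_rows)
coverage_tab <- do.call(rbind, coverage_rows)
write.table(summary_tab, "results/tables/dataset_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(coverage_tab, "results/tables/coverage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary_tab, row.names = FALSE)
print(coverage_tab, row.names = FALSE)
cat("\nIn the clustered corpus nearly every article has annotated neighbors;",
    "second-degree neighborhoods raise coverage further.\n")
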