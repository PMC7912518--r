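#!/usr/bin/env Rscript

# Stage 1: simulate the study corpora.
#
# Two synthetic corpora are written as plain-text inputs for the rest of the
# workflow:
#   * clustered - topic-clustered citations (10 topics, 95% within-topic
#     citation) with Zipf-weighted annotations from 50-token topic
#     vocabularies; this is the corpus on which annotation sharing should be
#     strong, the synthetic counterpart of a gene-annotation database over a
#     real citation network.
#   * uniform - a single topic with a 2000-token vocabulary and uniform
#     annotation draws; here sharing can only arise by chance, so the corpus
#     provides the analytic-null baseline.

suppressPackageStartupMessages(library(citann))

SEED <- 1234L
out_dir <- "results/data"

clustered <- generate_corpus(synthetic_config(
  n_articles = 5000, n_topics = 10, p_within = 0.95, mean_citations = 5,
  mean_annots = 3, topic_vocab_size = 50, shared_vocab_frac = 0.1,
  annot_frac = 0.8, zipf_exponent = 1, seed = SEED
))
uniform <- generate_corpus(synthetic_config(
  n_articles = 5000, n_topics = 1, topic_vocab_size = 2000, mean_annots = 4,
  mean_citations = 5, annot_frac = 0.8, zipf_exponent = 0, seed = SEED + 1L
))

for (name in c("clustered", "uniform")) {
  corp <- get(name)
  paths <- write_corpus(corp, file.path(out_dir, name))
  s <- summarize_store(corp$store)
  cat(sprintf(
    "%s corpus: %d articles, %d citation pairs, %d annotated articles, %d (article, annotation) pairs\n",
    name, length(corp$truth$ids), nrow(corp$pairs), s$n_articles,
    s$n_annotation_rows
  ))
}
cat("corpora written under", out_dir, "\n")
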