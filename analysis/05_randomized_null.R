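#!/usr/bin/env Rscript

# Stage 5: null models. Two complementary baselines show that the sharing
# measured in stages 3-4 comes from citation structure, not chance:
#   * the clustered corpus re-evaluated on a randomized graph (citing-side
#     shuffle) - recall collapses;
#   * the uniform corpus compared per bin against the closed-form null
#     expectation 1 - (1 - m/V)^k.

suppressPackageStartupMessages(library(citann))

SEED <- 1234L

base <- "results/data/clustered"
pairs <- read_citation_pairs(file.path(base, "citation_pairs.csv"))
store <- read_annotation_table(file.path(base, "annotations.tsv"),
                               dialect = "generic", dataset_name = "clustered")

rgraph <- randomize_graph(pairs, seed = SEED + 2L)
write_graph(rgraph, file.path(base, "graph_randomized.tsv"))
rrec <- evaluate_corpus(rgraph, store)
write_overlap_records(rrec, "results/tables/records_randomized.tsv")
write_curve(stratify(rrec, max_bin = 20),
            "results/tables/curve_randomized.tsv")

obs <- utils::read.delim("results/tables/records_undirected_degree1.tsv")
cat(sprintf(
  "clustered graph: mean recall %.3f, corpus recall %.3f, full-recall fraction %.3f\n",
  mean(obs$recall), corpus_recall(obs), fraction_full_recall(obs)
))
cat(sprintf(
  "randomized graph: mean recall %.3f, corpus recall %.3f, full-recall fraction %.3f\n",
  mean(rrec$recall), corpus_recall(rrec), fraction_full_recall(rrec)
))

# uniform corpus vs analytic expectation
ubase <- "results/data/uniform"
upairs <- read_citation_pairs(file.path(ubase, "citation_pairs.csv"))
ustore <- read_annotation_table(file.path(ubase, "annotations.tsv"),
                                dialect = "generic", dataset_name = "uniform")
urec <- evaluate_corpus(build_graph(upairs), ustore)
ucur <- stratify(urec, max_bin = 12)
ucur$expected <- expected_null_recall(2000, 4, ucur$bin)
ucur$expected[ucur$pooled] <- NA
write.table(ucur, "results/tables/uniform_null_vs_expected.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(ucur[, c("bin", "n_records", "mean_recall", "expected")],
      row.names = FALSE, digits = 3)
cat("\nUniform-annotation recall tracks the analytic null; the clustered",
    "corpus sits far above it until its graph is randomized.\n")
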