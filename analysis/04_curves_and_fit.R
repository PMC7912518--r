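#!/usr/bin/env Rscript

# Stage 4: recall/precision/MAP curves stratified by annotated-neighbor
# count, and the sigmoidal recall extrapolation. The sigmoid (monotone,
# bounded in [0, 1]) is fitted to per-article recall against the number of
# annotated neighbors and then evaluated at a hypothetical count of exactly
# 5 annotated neighbors - the "what if every article had 5 annotated
# neighbors" extrapolation.

suppressPackageStartupMessages(library(citann))

SEED <- 1234L
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

read_records <- function(name) {
  utils::read.delim(sprintf("results/tables/records_%s.tsv", name),
                    colClasses = c(focal = "character"))
}

for (name in c("undirected_degree1", "undirected_degree2",
               "citing_degree1", "cited_degree1")) {
  rec <- read_records(name)
  write_curve(stratify(rec, max_bin = 20),
              sprintf("results/tables/curve_%s.tsv", name))
}

rec <- read_records("undirected_degree1")
fit <- fit_sigmoid(rec$n_annotated_neighbors, rec$recall, n_boot = 500,
                   seed = SEED)
write_fit(fit, "results/tables/sigmoid_fit.json")
print(fit)
pred <- predict_recall(fit, c(3, 5, 10, 20))
write.table(pred, "results/tables/sigmoid_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "extrapolated recall with exactly 5 annotated neighbors: %.3f [%.3f, %.3f]\n",
  pred$fit[pred$x == 5], pred$lwr[pred$x == 5], pred$upr[pred$x == 5]
))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  cur <- stratify(rec, max_bin = 20)
  cur <- cur[!cur$pooled, ]
  long <- rbind(
    data.frame(bin = cur$bin, metric = "recall", value = cur$mean_recall),
    data.frame(bin = cur$bin, metric = "precision", value = cur$mean_precision),
    data.frame(bin = cur$bin, metric = "MAP", value = cur$map)
  )
  p <- ggplot(long, aes(bin, value, colour = metric)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "annotated neighbors", y = NULL,
         title = "Annotation sharing vs annotated-neighbor count") +
    theme_minimal()
  ggsave("results/figures/curves_undirected_degree1.pdf", p,
         width = 6, height = 4)
  cat("figure written to results/figures/\n")
}
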