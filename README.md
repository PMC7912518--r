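# citann — annotation sharing across citation neighborhoods

Biomedical annotation databases (gene–article links, MeSH headings, variant
references) cover only a fraction of the literature, yet the articles they do
cover are embedded in a citation network. citann measures how far an
article's annotations are already present in its *citation neighborhood* —
the articles it cites and the articles citing it — and hence how useful
neighborhood annotations are as ranked candidates for annotating the article
itself. It is aimed at literature-mining and curation-support work:
given citation pairs and an article→annotation table, it answers "how much of
each article's annotation could its neighbors have told us?"

## The measurement

For a focal article with annotation set $A$ and unique neighborhood
annotation set $U$ (from neighbors annotated in the database under study):

- recall $= |A \cap U| / |A|$, precision $= |A \cap U| / |U|$;
- the neighborhood annotations are ranked by document frequency (number of
  distinct annotated neighbors carrying the token) and scored with average
  precision $AP = \sum_k P(k)\,\Delta R(k)$, relevant set $= A$; MAP is the
  mean over articles.

Per-article records are stratified by annotated-neighbor count, compared
between first- and second-degree (inclusive) neighborhoods and between
citation directions, contrasted against a citing-side edge-shuffle null and
the closed-form expectation $1-(1-m/V)^k$, and summarized by a bounded
sigmoid fit of recall versus annotated-neighbor count with bootstrap
confidence intervals, used to extrapolate recall at a hypothetical neighbor
count. A seeded generator of topic-clustered synthetic corpora drives the
whole pipeline end-to-end; see the vignette
(`vignettes/annotation-neighborhoods.Rmd`) for the model and its
assumptions.

## Worked example

```r
library(citann)

cfg  <- synthetic_config(n_articles = 5000, n_topics = 10, p_within = 0.95,
                         topic_vocab_size = 50, seed = 1234)
corp <- generate_corpus(cfg)
rec  <- evaluate_corpus(corp$graph, corp$store)   # one row per evaluated article

mean(rec$recall);  corpus_recall(rec);  fraction_full_recall(rec)
#> [1] 0.553       [1] 0.549            [1] 0.232
```

On this clustered corpus, 55% of an average article's annotations appear in
its first-degree neighborhood; weighting every annotation equally gives a
corpus-wide recall of 0.549, and 23% of articles have *every* annotation
recovered. Widening to inclusive second-degree neighborhoods
(`evaluate_corpus(..., degree = 2)`) raises corpus recall to 0.929 and the
full-recall fraction to 0.817, at the cost of precision (0.122 → 0.052) —
bigger neighborhoods see more, and more irrelevant, annotation. Restricting
to one citation direction (`mode = "citing"` or `"cited"`) lowers recall to
about 0.42: half the neighborhood is simply missing.

```r
fit <- fit_sigmoid(rec$n_annotated_neighbors, rec$recall, n_boot = 500, seed = 1234)
fit
#> <sigmoid_fit: L = 0.7575, k = 0.2578, x0 = 2.8552, R^2 = 0.1372 (n = 3979, 500 bootstrap draws)>
predict_recall(fit, 5)
#>   x       fit       lwr       upr
#> 1 5 0.4808567 0.4696435 0.4920889
```

The fitted sigmoid extrapolates that articles with exactly 5 annotated
neighbors reach about 48% recall on this corpus. Randomizing the citation
graph (`randomize_graph(corp$pairs, seed)`) collapses mean recall from 0.55
to 0.14 — the sharing is a property of citation structure, not of annotation
frequencies alone.

The `analysis/` directory runs this as a five-stage narrative workflow
(simulate → ingest → evaluate → curves/fit → nulls), writing tables under
`results/tables/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_ingest_network.R && \
Rscript analysis/03_evaluate.R && Rscript analysis/04_curves_and_fit.R && \
Rscript analysis/05_randomized_null.R
```

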