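---
title: "Measuring annotation sharing across citation neighborhoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring annotation sharing across citation neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(citann)
```

## The question

Biomedical databases annotate articles with controlled tokens — NCBI Gene
IDs, MeSH headings, dbSNP variant IDs. Curating these annotations is
expensive, and most of the literature is unannotated. citann quantifies a
simple observation with large practical consequences: articles tend to carry
the same annotations as the articles they are connected to by citations. If
that tendency is strong, the annotations already present in an article's
citation neighborhood are a cheap, ranked list of candidate annotations for
the article itself.

The unit of analysis is a *focal article* and its *citation neighborhood*:
the articles that cite it or that it cites, treated as undirected links by
default. First-degree neighbors are directly connected; the second-degree
neighborhood is inclusive — everything within two steps. Two direction-
restricted modes exist because the two edge directions are not symmetric in
practice: `citing` neighbors (articles citing the focal one) keep
accumulating after publication, while `cited` neighbors (the focal article's
own reference list) are frozen at publication time.

## The measurement

For a focal article with annotation set $A$ and a neighborhood whose
annotated members contribute the unique annotation set $U$:

* **recall** $= |A \cap U| / |A|$ — how much of the article's own annotation
  the neighborhood could have supplied;
* **precision** $= |A \cap U| / |U|$ — how much of the neighborhood's
  annotation diversity the article shares.

Both use unique annotations only. To exploit frequency, the neighborhood
annotations are ranked by *document frequency* — the number of distinct
annotated neighbors carrying the token — and the ranking is scored with
**average precision**:

$$AP = \sum_{k=1}^{N} P(k)\,\Delta R(k),$$

where $P(k)$ is the precision of the top-$k$ predictions and $\Delta R(k)$
the change in recall between ranks $k-1$ and $k$, with $R(0) = 0$. The mean
AP over articles (MAP) summarizes a corpus. Two definitional choices matter
and are deliberate:

* The AP recall denominator is the article's **full** annotation set, not
  just the recoverable part. An annotation the neighborhood never surfaces
  therefore caps AP below 1; MAP = 1 means the top of the ranking *is* the
  article's annotation set.
* Ties in document frequency are broken by ascending annotation token. This
  makes every ranking deterministic and platform-independent;
  `average_precision_tie_expected()` estimates the expected AP over random
  tie resolutions for sensitivity analysis, and agrees with the
  deterministic rule whenever frequencies are distinct.

Articles with no annotations of their own, or with zero annotated neighbors,
carry no signal in either direction; they are excluded from the per-article
records and counted separately (they matter for the coverage statistics
below). Corpus-level summaries come in two deliberately different flavors:
`corpus_recall()` is annotation-weighted (total recovered over total
annotations), while curve points average per-article values.
`fraction_full_recall()` compares integers (`n_shared ==
n_article_annots`), never floating-point recall values.

## Stratification, coverage, extrapolation

Recall, precision and MAP all depend strongly on how many annotated
neighbors an article has, so `stratify()` bins records by the exact
annotated-neighbor count from 1 up to a cut-off (default 20), pooling the
rest into a flagged open bin that is reported but left out of curve plots.

`coverage()` measures the other side of the coin: the fraction of an
article universe with at least `min_annotated_neighbors` annotated
neighbors at a given degree — i.e. how much of a corpus the
neighborhood-annotation idea can reach at all. It is non-increasing in the
threshold and non-decreasing in the degree.

To ask "what recall would articles reach if they all had exactly $x$
annotated neighbors", `fit_sigmoid()` fits

$$y = \frac{L}{1 + e^{-k (x - x_0)}}$$

to the per-article points (recall vs annotated-neighbor count). A sigmoid is
used because recall is monotone in neighborhood annotation and bounded; $L$
is constrained to $[0, 1]$. Fitting per-record rather than to binned means
weights bins by their population; binned-mean fitting is available by simply
passing a curve's columns. Numerical details:

* Levenberg–Marquardt least squares (via minpack.lm) from **two starts** —
  the natural one ($L = \max y$ pulled inside the bound at 0.95, $x_0 =
  \mathrm{median}(x)$, $k = 1$) and a mid-range one ($L = 0.5$) — keeping
  the lower-RSS solution. The second start exists because a bounded LM
  search that begins on the $L = 1$ boundary can stall there even when the
  interior optimum is better.
* Uncertainty by seeded parametric bootstrap: residual variance is
  re-simulated around the fitted curve and the model refitted; parameter and
  prediction intervals are percentile intervals over the refits. Percentile
  intervals were retained after comparing calibration against basic and
  normal-theory intervals on simulated data with known parameters.
* A constant response (zero total sum of squares) returns a degenerate fit
  object rather than an error; fewer than 4 distinct $x$ values is an error.

`predict_recall()` evaluates the fitted curve (clipped to $[0,1]$) with
bootstrap bounds.

## Null models

Observed sharing is only meaningful against chance. Two nulls are built in:

* **Randomized network** (`randomize_graph()`): the multiset of citing-side
  identifiers is permuted across all pairs while cited identifiers stay in
  place, destroying topical structure but preserving both marginal count
  distributions. The shuffle acts on the *raw* pair list; deduplication and
  self-loop removal are applied afterwards, exactly as in normal graph
  construction, and the permuted pair list is kept as an attribute so the
  permutation property is auditable. One seeded shuffle is the default;
  repeating with different seeds gives variance estimates.
* **Analytic expectation** (`expected_null_recall()`): if a focal article's
  $k$ annotated neighbors each carry about $m$ annotations drawn uniformly
  from a vocabulary of size $V$, each focal annotation is recovered with
  probability $1 - (1 - m/V)^k$. This closed form is what the uniform
  synthetic corpus (below) must match bin by bin, and what a randomized
  graph collapses toward.

## The synthetic corpus generator

No desk-scale dataset reproduces literature-scale citation and annotation
databases, so the workflow runs on synthetic corpora whose generative
structure isolates the two forces the measurement responds to:

* **Citation clustering.** Articles are assigned uniformly to `n_topics`
  topics; article $i$ cites `Poisson(mean_citations)` earlier articles
  (acyclic, mimicking publication time — invisible to undirected analysis
  but keeping the citing/cited modes meaningful). Each citation stays
  within-topic with probability `p_within`, otherwise targets any earlier
  article. A within-topic draw with no same-topic predecessor is dropped,
  never redirected, so `p_within = 1` guarantees purely intra-topic
  neighborhoods.
* **Annotation vocabulary.** Each topic owns `topic_vocab_size` tokens, a
  fraction `shared_vocab_frac` of them common to all topics. A fraction
  `annot_frac` of articles receives `1 + Poisson(mean_annots - 1)` distinct
  annotations (every annotated article has at least one), sampled with rank
  weights $1/\mathrm{rank}^{s}$. The default $s = 1$ (Zipf) reflects the
  heavy-tailed annotation frequencies of real databases; $s = 0$ gives the
  uniform sampling assumed by the analytic null. Vocabulary size is the
  dial that reproduces the empirical pattern that databases with larger
  vocabularies (variant IDs) share less than compact ones (gene IDs).

Defaults (5000 articles in the analysis workflow, 10 topics, `p_within` =
0.95, mean out-degree 5, mean 3 annotations on 80% of articles, 50-token
topic vocabularies with 10% shared) are chosen so that a mid-sized corpus
shows strong but not saturated sharing: recall climbing from roughly 0.2 at
one annotated neighbor toward saturation past ten, precision falling as
neighborhoods grow — the qualitative shape the measurement is designed to
expose. All randomness flows from the single config seed; a config
reproduces its corpus byte for byte, and ground truth (topic assignments,
vocabularies) is always returned for structural tests.

What the generator does **not** emulate: real degree distributions
(citation counts are Poisson, not heavy-tailed), citation bursts in time,
correlated multi-database annotation, or annotator inconsistency. Passing
tests on synthetic corpora therefore validate the *machinery and its
qualitative behavior* — monotone recall curves, null collapse, direction
asymmetry — not any absolute level of sharing in real literature, which
depends on the annotation database and citation coverage at hand.

## Problem sizes and determinism

The test suite and the acceptance workflow use corpora of 60–5000 articles:
small graphs for exhaustive oracle comparisons (every ranking of up to six
items is enumerated against the literal AP definition), mid-sized ones for
distributional checks (the uniform corpus is compared to the analytic null
within three standard errors per bin, with the standard error computed
under the null), and 50 seeded replicates for bootstrap-coverage checks of
the sigmoid fit. These sizes give stable statistics while keeping a full
run in minutes on one core. Every stochastic step — generation, shuffling,
bootstrap — takes an explicit integer seed, and identical seeds reproduce
corpora, evaluations and fits exactly.

## Known limitations

* Ingestion supports pre-extracted delimited tables (citation pairs, ID
  mappings, two-column annotation dumps, gold-standard lists); native XML
  or flat-file database dumps must be converted upstream.
* The randomized null is the citing-side shuffle only; degree-preserving
  rewiring or configuration-model nulls are out of scope.
* The ranking is evaluated in full; no threshold converts it into a
  predicted annotation set.
* Whether a second-degree analysis should count annotated neighbors of the
  combined neighborhood or of the first degree only is a genuine
  convention choice; citann counts the combined (inclusive) neighborhood,
  and the degree-1 column of every record keeps the alternative
  computable.
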