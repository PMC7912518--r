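# Seeded generator of annotated citation corpora with topic clustering. It
# emulates the structure that drives annotation sharing in the literature:
# articles cluster into topics, citations fall mostly within a topic, and
# each topic draws its annotations from a limited, heavy-tailed vocabulary.
# Every pipeline stage can therefore be exercised end-to-end, with known
# ground truth, and with dials for the two forces the analysis measures -
# citation clustering (p_within) and annotation-vocabulary diversity
# (topic_vocab_size, zipf_exponent).

#' Configuration of a synthetic annotated citation corpus
#'
#' @param n_articles number of articles (indexed in publication order).
#' @param n_topics number of topics; articles are assigned uniformly.
#' @param p_within probability that a citation targets an earlier article of
#'   the SAME topic (the citation is dropped when no same-topic predecessor
#'   exists yet, so cross-topic edges only ever come from the complementary
#'   branch); with the remaining probability the target is uniform over all
#'   earlier articles.
#' @param mean_citations mean out-degree; each article cites
#'   `Poisson(mean_citations)` earlier articles.
#' @param mean_annots mean annotations per annotated article; per-article
#'   counts are `1 + Poisson(mean_annots - 1)`, so every annotated article
#'   has at least one annotation.
#' @param topic_vocab_size annotation tokens available to each topic.
#' @param shared_vocab_frac fraction of each topic's vocabulary drawn from a
#'   pool common to all topics.
#' @param annot_frac fraction of articles that carry annotations.
#' @param zipf_exponent exponent `s` of the rank-frequency weights
#'   `1 / rank^s` used when sampling annotations from a topic vocabulary;
#'   1 gives the usual heavy-tailed annotation frequencies, 0 gives uniform
#'   sampling (the analytic null of [expected_null_recall()]).
#' @param seed integer seed; a config plus its seed reproduces the corpus
#'   byte for byte.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_articles = 2000L, n_topics = 10L,
                             p_within = 0.95, mean_citations = 5,
                             mean_annots = 3, topic_vocab_size = 50L,
                             shared_vocab_frac = 0.1, annot_frac = 0.8,
                             zipf_exponent = 1, seed = 1L) {
  cfg <- list(n_articles = as.integer(n_articles),
              n_topics = as.integer(n_topics),
              p_within = p_within, mean_citations = mean_citations,
              mean_annots = mean_annots,
              topic_vocab_size = as.integer(topic_vocab_size),
              shared_vocab_frac = shared_vocab_frac,
              annot_frac = annot_frac, zipf_exponent = zipf_exponent,
              seed = as.integer(seed))
  stopifnot(
    cfg$n_articles >= 2L, cfg$n_topics >= 1L,
    cfg$p_within >= 0, cfg$p_within <= 1,
    cfg$mean_citations > 0, cfg$mean_annots >= 1,
    cfg$topic_vocab_size >= 1L,
    cfg$shared_vocab_frac >= 0, cfg$shared_vocab_frac <= 1,
    cfg$annot_frac >= 0, cfg$annot_frac <= 1,
    cfg$zipf_exponent >= 0
  )
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic annotated citation corpus
#'
#' Articles are assigned topics uniformly. Article `i` cites
#' `Poisson(mean_citations)` earlier articles (citations point backwards in
#' publication order, so the raw pair list is acyclic); each citation lands
#' within the citing article's topic with probability `p_within`, otherwise
#' uniformly among all earlier articles. A fraction `annot_frac` of articles
#' receives `1 + Poisson(mean_annots - 1)` distinct annotations sampled with
#' rank weights `1 / rank^zipf_exponent` from the article's topic
#' vocabulary. Topic vocabularies share a common sub-pool of size
#' `round(shared_vocab_frac * topic_vocab_size)`.
#'
#' @param config a [synthetic_config()].
#' @return list with `pairs` (raw citing/cited data.frame, suitable for
#'   [build_graph()] and [randomize_graph()]), `graph` (the built
#'   `citation_graph`), `store` (the `annotation_store`), and `truth`
#'   (article IDs, topic assignments, topic vocabularies, the config).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_articles
  ids <- sprintf("SYN%06d", seq_len(n))
  withr::with_seed(config$seed, {
    topics <- sample.int(config$n_topics, n, replace = TRUE)

    n_shared <- round(config$shared_vocab_frac * config$topic_vocab_size)
    n_own <- config$topic_vocab_size - n_shared
    shared_pool <- if (n_shared > 0) sprintf("SHARED%05d", seq_len(n_shared))
                   else character(0)
    pools <- lapply(seq_len(config$n_topics), function(t) {
      own <- if (n_own > 0) sprintf("T%03d_%05d", t, seq_len(n_own))
             else character(0)
      c(own, shared_pool)
    })
    w <- 1 / seq_len(config$topic_vocab_size)^config$zipf_exponent

    # citations: article i cites earlier articles, mostly within topic
    citing_idx <- integer(0); cited_idx <- integer(0)
    same_topic_earlier <- vector("list", config$n_topics)
    for (i in seq_len(n)) {
      ti <- topics[i]
      if (i > 1L) {
        d <- stats::rpois(1L, config$mean_citations)
        if (d > 0L) {
          pool_same <- same_topic_earlier[[ti]]
          within <- stats::runif(d) < config$p_within
          tgt <- rep(NA_integer_, d)
          if (any(within) && length(pool_same) > 0L) {
            tgt[within] <- pool_same[sample.int(length(pool_same),
                                                sum(within), replace = TRUE)]
          }
          # within-topic draws with no same-topic predecessor are dropped,
          # never redirected: cross-topic edges arise only from the
          # (1 - p_within) branch
          if (any(!within)) {
            tgt[!within] <- sample.int(i - 1L, sum(!within), replace = TRUE)
          }
          ok <- !is.na(tgt)
          citing_idx <- c(citing_idx, rep.int(i, sum(ok)))
          cited_idx <- c(cited_idx, tgt[ok])
        }
      }
      same_topic_earlier[[ti]] <- c(same_topic_earlier[[ti]], i)
    }
    pairs <- data.frame(citing = ids[citing_idx], cited = ids[cited_idx],
                        stringsAsFactors = FALSE)

    # annotations: Zipf-weighted draws from the article's topic vocabulary
    is_annotated <- stats::runif(n) < config$annot_frac
    m <- 1L + stats::rpois(n, config$mean_annots - 1)
    m <- pmin(m, config$topic_vocab_size)
    records <- lapply(which(is_annotated), function(i) {
      pool <- pools[[topics[i]]]
      pool[sample.int(length(pool), m[i], prob = w)]
    })
    names(records) <- ids[is_annotated]
  })
  store <- annotation_store(records, dataset_name = "synthetic")
  list(
    pairs = pairs,
    graph = build_graph(pairs),
    store = store,
    truth = list(ids = ids, topics = topics, pools = pools, config = config)
  )
}

#' Expected recall under uniform-random neighborhood annotations
#'
#' Closed-form null expectation for the recall of an article with `k`
#' annotated neighbors when every neighbor carries about `mean_annots`
#' annotations drawn uniformly from a vocabulary of size `vocab_size`: the
#' probability that any one focal annotation appears in at least one
#' neighbor is `1 - (1 - m/V)^k`. This is the analytic counterpart of the
#' randomized-network null, where topical structure is destroyed and
#' neighborhood annotations are effectively random draws.
#'
#' @param vocab_size vocabulary size `V` (>= 1).
#' @param mean_annots mean annotations per annotated neighbor `m`; values
#'   above `V` are clamped with a warning.
#' @param k annotated-neighbor count (vectorized; `k = 0` gives 0).
#' @return expected recall in `[0, 1]`.
#' @export
expected_null_recall <- function(vocab_size, mean_annots, k) {
  stopifnot(vocab_size >= 1)
  if (mean_annots > vocab_size) {
    warning("mean_annots exceeds vocab_size; clamped")
    mean_annots <- vocab_size
  }
  1 - (1 - mean_annots / vocab_size)^k
}

#' Write a synthetic corpus through the pipeline's text dialects
#'
#' Emits the citation pairs as a CSV the citation reader ingests and the
#' annotation store as a generic-dialect table, plus a JSON sidecar with the
#' generating configuration, so synthetic corpora exercise the real I/O
#' path.
#'
#' @param corpus list from [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    pairs = file.path(dir, "citation_pairs.csv"),
    annotations = file.path(dir, "annotations.tsv"),
    meta = file.path(dir, "corpus_meta.json")
  )
  write_citation_pairs(corpus$pairs, paths$pairs)
  write_annotation_store(corpus$store, paths$annotations)
  jsonlite::write_json(
    c(unclass(corpus$truth$config),
      list(n_citation_pairs = nrow(corpus$pairs),
           n_annotated_articles = length(corpus$store$records))),
    paths$meta, auto_unbox = TRUE, pretty = TRUE
  )
  paths
}
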