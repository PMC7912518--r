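# Per-article overlap metrics between an article's own annotations and its
# citation neighborhood. Recall: fraction of the article's annotations seen
# in at least one neighbor. Precision: fraction of the unique neighborhood
# annotations the article itself carries. Average precision scores the
# frequency-ranked neighborhood annotations against the article's
# annotations, with the article's full annotation count as the recall
# denominator, so annotations the neighborhood never surfaces penalize the
# score.

exclusion <- function(msg) {
  stop(errorCondition(msg, class = c("citann_exclusion", "error")))
}

#' Recall and precision of a neighborhood against an article's annotations
#'
#' With `A` the article's annotation set and `U` the unique annotations in
#' its neighborhood profile: recall = |A intersect U| / |A|, precision =
#' |A intersect U| / |U|. Articles with empty `A` or a neighborhood with no
#' annotated neighbors carry no signal and raise an exclusion condition
#' (class `citann_exclusion`) instead of returning a number; corpus
#' evaluation counts them separately.
#'
#' @param article_annots character vector, the article's own annotations.
#' @param profile a `neighborhood_profile` (or character vector of unique
#'   neighborhood annotations).
#' @return list with `recall`, `precision`, `n_shared`.
#' @export
overlap <- function(article_annots, profile) {
  u <- if (inherits(profile, "neighborhood_profile")) names(profile$freq)
       else unique(as.character(profile))
  a <- unique(as.character(article_annots))
  if (length(a) == 0L) exclusion("article has no annotations")
  if (length(u) == 0L) exclusion("neighborhood has no annotated neighbors")
  n_shared <- length(intersect(a, u))
  list(recall = n_shared / length(a), precision = n_shared / length(u),
       n_shared = n_shared)
}

#' Frequency ranking of neighborhood annotations
#'
#' Orders the unique annotations of a neighborhood profile by descending
#' document frequency; ties break by ascending annotation token, which makes
#' the ranking deterministic and reproducible across platforms.
#'
#' @param profile a `neighborhood_profile`.
#' @return character vector: the full ordering of unique neighborhood
#'   annotations (empty for an empty profile).
#' @export
rank_annotations <- function(profile) {
  freq <- profile$freq
  if (length(freq) == 0L) return(character(0))
  names(freq)[order(-freq, names(freq), method = "radix")]
}

#' Average precision of a ranked annotation list
#'
#' `AP = sum_k P(k) * dR(k)` over ranks `k = 1..N`, where `P(k)` is the
#' precision of the top-k predictions and `dR(k)` the change in recall at
#' rank `k` with `R(0) = 0`. The recall denominator is the full relevant set,
#' so relevant annotations absent from the ranking contribute nothing and
#' cap AP below 1.
#'
#' @param ranking character vector, ranked predictions (best first).
#' @param relevant character vector, the relevant set (the article's own
#'   annotations); must be non-empty.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(ranking, relevant) {
  relevant <- unique(as.character(relevant))
  if (length(relevant) == 0L) exclusion("relevant set is empty")
  if (length(ranking) == 0L) return(0)
  hit <- ranking %in% relevant
  if (!any(hit)) return(0)
  prec_at_k <- cumsum(hit) / seq_along(hit)
  sum(prec_at_k[hit]) / length(relevant)
}

#' Expected average precision under random tie resolution
#'
#' The frequency ranking is only defined up to permutations within ties.
#' [rank_annotations()] breaks ties lexicographically; this helper instead
#' estimates the expected AP over random permutations of each tie block by
#' Monte Carlo, for sensitivity checks of the tie rule.
#'
#' @param profile a `neighborhood_profile`.
#' @param relevant relevant annotation set.
#' @param n_perm number of random tie resolutions.
#' @param seed integer seed.
#' @return mean AP over the sampled tie resolutions.
#' @export
average_precision_tie_expected <- function(profile, relevant, n_perm = 100L,
                                           seed = 1L) {
  freq <- profile$freq
  if (length(freq) == 0L) return(0)
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_perm), function(i) {
      jitter_order <- sample.int(length(freq))
      ranking <- names(freq)[order(-freq, jitter_order)]
      average_precision(ranking, relevant)
    }, numeric(1)))
  })
}

#' Evaluate annotation sharing over a corpus of target articles
#'
#' For every target article with at least one annotated neighbor, computes
#' the overlap record: recall, precision and the average precision of the
#' frequency-ranked neighborhood annotations against the article's own
#' annotations. Neighbor annotations come from `neighbor_store`, target
#' annotations from `target_store`; the two may differ (cross-source
#' evaluation, e.g. gold-standard targets scored against a large annotation
#' database). Targets without annotations in `target_store` or without
#' annotated neighbors are excluded and counted.
#'
#' @param graph a `citation_graph`.
#' @param neighbor_store `annotation_store` supplying neighborhood
#'   annotations.
#' @param target_store `annotation_store` supplying the target articles' own
#'   annotations (defaults to `neighbor_store`).
#' @param targets character vector of target article IDs (defaults to all
#'   articles of `target_store`).
#' @inheritParams neighbors_of
#' @return data.frame with one row per evaluated article: `focal`,
#'   `n_total_neighbors`, `n_annotated_neighbors`, `n_article_annots`,
#'   `n_neighborhood_annots`, `n_shared`, `recall`, `precision`, `ap`.
#'   Attribute `"exclusions"` counts `no_annotation` and
#'   `no_annotated_neighbors` targets.
#' @export
evaluate_corpus <- function(graph, neighbor_store, target_store = neighbor_store,
                            targets = names(target_store$records),
                            mode = c("undirected", "citing", "cited"),
                            degree = 1L) {
  mode <- match.arg(mode)
  if (length(targets) == 0L) {
    warning("no target articles supplied")
  }
  n <- length(targets)
  rows <- vector("list", n)
  excl_no_annot <- 0L
  excl_no_nbr <- 0L
  for (i in seq_len(n)) {
    t <- targets[[i]]
    a <- target_store$records[[t]]
    if (is.null(a) || length(a) == 0L) {
      excl_no_annot <- excl_no_annot + 1L
      next
    }
    prof <- neighborhood_profile(graph, neighbor_store, t, mode = mode,
                                 degree = degree)
    if (prof$annotated_neighbors == 0L) {
      excl_no_nbr <- excl_no_nbr + 1L
      next
    }
    ov <- overlap(a, prof)
    ap <- average_precision(rank_annotations(prof), a)
    rows[[i]] <- data.frame(
      focal = t,
      n_total_neighbors = prof$total_neighbors,
      n_annotated_neighbors = prof$annotated_neighbors,
      n_article_annots = length(a),
      n_neighborhood_annots = length(prof$freq),
      n_shared = ov$n_shared,
      recall = ov$recall,
      precision = ov$precision,
      ap = ap,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(
      focal = character(0), n_total_neighbors = integer(0),
      n_annotated_neighbors = integer(0), n_article_annots = integer(0),
      n_neighborhood_annots = integer(0), n_shared = integer(0),
      recall = numeric(0), precision = numeric(0), ap = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(no_annotation = excl_no_annot,
                                  no_annotated_neighbors = excl_no_nbr)
  out
}

#' Write per-article overlap records as TSV
#'
#' @param records data.frame from [evaluate_corpus()].
#' @param path output TSV path.
#' @export
write_overlap_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
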