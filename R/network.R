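# The citation graph and its neighborhood queries. Citations are stored as
# directed (citing, cited) pairs but the headline analysis treats them as
# undirected links; direction-restricted modes exist because citing and cited
# neighborhoods carry different amounts of annotation signal. Second-degree
# neighborhoods are expanded lazily per focal article (breadth-first, depth
# 2, inclusive of first-degree) - corpus-wide materialization of the
# second-degree pair set is intractable at literature scale.

#' Build a citation graph from directed article pairs
#'
#' Duplicate directed pairs collapse and self-citations are dropped (both are
#' counted in the `cleanup` element). Adjacency lists in both directions are
#' derived once at build time so neighborhood queries are list lookups.
#'
#' @param pairs data.frame (or 2-column matrix) of (citing, cited) article
#'   IDs.
#' @return object of class `citation_graph` with elements `nodes` (sorted
#'   character), `edges` (deduplicated directed pair data.frame), `out_adj` /
#'   `in_adj` (named lists: article -> neighbor IDs) and `cleanup`
#'   (`n_self_loops`, `n_duplicates`).
#' @export
build_graph <- function(pairs) {
  if (is.matrix(pairs)) {
    pairs <- data.frame(citing = pairs[, 1], cited = pairs[, 2],
                        stringsAsFactors = FALSE)
  }
  citing <- as.character(pairs$citing)
  cited <- as.character(pairs$cited)
  # the node set covers every endpoint, including articles whose only
  # citation row was a (dropped) self-loop
  nodes <- sort(unique(c(citing, cited)))
  self <- citing == cited
  citing <- citing[!self]; cited <- cited[!self]
  dup <- duplicated(paste0(citing, "\r", cited))
  citing <- citing[!dup]; cited <- cited[!dup]
  structure(
    list(
      nodes = nodes,
      edges = data.frame(citing = citing, cited = cited,
                         stringsAsFactors = FALSE),
      out_adj = split(cited, citing),
      in_adj = split(citing, cited),
      cleanup = list(n_self_loops = sum(self), n_duplicates = sum(dup))
    ),
    class = "citation_graph"
  )
}

#' @export
print.citation_graph <- function(x, ...) {
  cat(sprintf("<citation_graph: %d nodes, %d directed citation pairs>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

step_neighbors <- function(graph, ids, mode) {
  nb <- switch(mode,
    undirected = c(unlist(graph$out_adj[ids], use.names = FALSE),
                   unlist(graph$in_adj[ids], use.names = FALSE)),
    citing = unlist(graph$in_adj[ids], use.names = FALSE),
    cited = unlist(graph$out_adj[ids], use.names = FALSE)
  )
  if (is.null(nb)) character(0) else unique(nb)
}

#' Neighborhood of an article in the citation graph
#'
#' Direction modes follow citation semantics: `"citing"` returns articles
#' that cite the focal article (its in-edges), `"cited"` returns the focal
#' article's own references (out-edges), and `"undirected"` their union.
#' `degree = 2` returns the inclusive two-step neighborhood, i.e. first-degree
#' neighbors plus their neighbors (same mode applied at each step), minus the
#' focal article itself.
#'
#' @param graph a `citation_graph`.
#' @param focal article ID; an ID absent from the graph yields an empty set.
#' @param mode `"undirected"`, `"citing"` or `"cited"`.
#' @param degree 1 or 2.
#' @return character vector of neighbor IDs (never containing `focal`).
#' @export
neighbors_of <- function(graph, focal,
                         mode = c("undirected", "citing", "cited"),
                         degree = 1L) {
  mode <- match.arg(mode)
  stopifnot(degree %in% c(1L, 2L))
  focal <- as.character(focal)
  n1 <- step_neighbors(graph, focal, mode)
  if (degree == 1L) return(setdiff(n1, focal))
  setdiff(union(n1, step_neighbors(graph, n1, mode)), focal)
}

#' Randomize a citation graph by shuffling citing-side identifiers
#'
#' The null model permutes the multiset of first (citing) elements across all
#' pairs while every cited element stays in place, destroying topical
#' structure but preserving the marginal counts on both sides. The shuffled
#' pairs then pass through the usual [build_graph()] cleanup, so self-loops
#' created by the shuffle are dropped and coinciding pairs collapse.
#'
#' @param pairs data.frame of raw (citing, cited) pairs.
#' @param seed integer seed; identical seeds give identical graphs.
#' @return a `citation_graph` with attributes `seed`, `n_pairs_input` and
#'   `shuffled_pairs` (the permuted pair list before cleanup, for auditing
#'   the permutation).
#' @export
randomize_graph <- function(pairs, seed) {
  stopifnot(nrow(pairs) > 0L)
  shuffled <- data.frame(
    citing = withr::with_seed(seed, sample(as.character(pairs$citing))),
    cited = as.character(pairs$cited),
    stringsAsFactors = FALSE
  )
  g <- build_graph(shuffled)
  attr(g, "seed") <- seed
  attr(g, "n_pairs_input") <- nrow(pairs)
  attr(g, "shuffled_pairs") <- shuffled
  g
}

#' Annotation frequency profile of a citation neighborhood
#'
#' Collects the annotations of every annotated neighbor of a focal article
#' and tabulates their document frequency: the number of distinct annotated
#' neighbors carrying each token. The focal article's own annotations are
#' never part of its profile.
#'
#' @param graph a `citation_graph`.
#' @param store an `annotation_store` providing neighbor annotations.
#' @param focal article ID.
#' @inheritParams neighbors_of
#' @return object of class `neighborhood_profile` with elements `focal`,
#'   `mode`, `degree`, `total_neighbors`, `annotated_neighbors` and `freq`
#'   (named integer vector, document frequency per annotation token).
#' @export
neighborhood_profile <- function(graph, store, focal,
                                 mode = c("undirected", "citing", "cited"),
                                 degree = 1L) {
  mode <- match.arg(mode)
  nbrs <- neighbors_of(graph, focal, mode = mode, degree = degree)
  sets <- store$records[nbrs]
  sets <- sets[!vapply(sets, is.null, logical(1))]
  tokens <- unlist(sets, use.names = FALSE)
  freq <- if (length(tokens) == 0L) {
    integer(0)
  } else {
    tab <- table(tokens)
    setNames(as.integer(tab), names(tab))
  }
  structure(
    list(focal = as.character(focal), mode = mode, degree = as.integer(degree),
         total_neighbors = length(nbrs), annotated_neighbors = length(sets),
         freq = freq),
    class = "neighborhood_profile"
  )
}

#' @export
print.neighborhood_profile <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_profile %s (%s, degree %d): %d/%d neighbors annotated, %d unique annotations>\n",
    x$focal, x$mode, x$degree, x$annotated_neighbors, x$total_neighbors,
    length(x$freq)
  ))
  invisible(x)
}

#' Persist a citation graph as a two-column TSV of directed pairs
#'
#' A JSON sidecar (`<path>.meta.json`) records node/edge counts, cleanup
#' statistics and, for randomized graphs, the shuffle seed, so null-model
#' runs are auditable.
#'
#' @param graph a `citation_graph`.
#' @param path output TSV path.
#' @export
write_graph <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(n_nodes = length(graph$nodes), n_edges = nrow(graph$edges),
               cleanup = graph$cleanup)
  if (!is.null(attr(graph, "seed"))) meta$shuffle_seed <- attr(graph, "seed")
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
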