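#' Construct an annotation store
#'
#' An annotation store maps article identifiers (PMID-like tokens) to sets of
#' annotation tokens (gene IDs, MeSH headings, variant IDs, ...). It is the
#' central container every evaluation step consumes: articles with an empty
#' annotation set are never stored, and the vocabulary is always the union of
#' all stored sets.
#'
#' @param records named list; names are article IDs, elements are character
#'   vectors of annotation tokens. Duplicate tokens within an article collapse
#'   into a set; articles with zero (non-empty) tokens are dropped.
#' @param dataset_name label carried through summaries and reports.
#' @return An object of class `annotation_store` with elements `dataset_name`,
#'   `records` (named list of sorted unique character vectors) and
#'   `vocabulary` (sorted union of all tokens).
#' @export
annotation_store <- function(records, dataset_name = "unnamed") {
  if (length(records) == 0L) {
    return(structure(
      list(dataset_name = dataset_name, records = setNames(list(), character(0)),
           vocabulary = character(0)),
      class = "annotation_store"
    ))
  }
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("every record must be named by a non-empty article ID")
  }
  records <- lapply(records, function(x) {
    x <- as.character(x)
    sort(unique(x[nzchar(x)]))
  })
  records <- records[lengths(records) > 0L]
  records <- records[order(names(records))]
  structure(
    list(
      dataset_name = dataset_name,
      records = records,
      vocabulary = sort(unique(unlist(records, use.names = FALSE)))
    ),
    class = "annotation_store"
  )
}

#' @export
print.annotation_store <- function(x, ...) {
  s <- summarize_store(x)
  cat(sprintf(
    "<annotation_store '%s': %d articles, %d (article, annotation) pairs, vocabulary %d>\n",
    x$dataset_name, s$n_articles, s$n_annotation_rows, length(x$vocabulary)
  ))
  invisible(x)
}

#' Dataset-size summary of an annotation store
#'
#' Counts match the usual dataset-size table semantics: the number of
#' (article, annotation) pairs and the number of distinct annotated articles.
#'
#' @param store an `annotation_store`.
#' @return list with `n_annotation_rows` and `n_articles`.
#' @export
summarize_store <- function(store) {
  stopifnot(inherits(store, "annotation_store"))
  list(
    n_annotation_rows = sum(lengths(store$records)),
    n_articles = length(store$records)
  )
}

#' Retrieve the annotation set of one article
#'
#' @param store an `annotation_store`.
#' @param article article ID.
#' @return character vector of annotations (empty if the article is absent).
#' @export
annotations_of <- function(store, article) {
  a <- store$records[[article]]
  if (is.null(a)) character(0) else a
}

#' Write an annotation store as a two-column TSV dump
#'
#' The dump uses the generic dialect (`article<TAB>annotation`, with header),
#' so a store round-trips through [read_annotation_table()].
#'
#' @param store an `annotation_store`.
#' @param path output file path (a `.gz` suffix triggers gzip compression).
#' @export
write_annotation_store <- function(store, path) {
  stopifnot(inherits(store, "annotation_store"))
  df <- data.frame(
    article = rep(names(store$records), lengths(store$records)),
    annotation = unlist(store$records, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
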