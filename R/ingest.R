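# Readers for the delimited-text inputs of the pipeline: citation pairs
# (COCI-style CSV), DOI-PMID mapping tables, annotation tables in three
# dialects, and gold-standard article->annotation lists. All readers accept
# gzip-compressed files and emit row-attrition reports, because identifier
# mapping loss is material at corpus scale.

read_delim_chr <- function(path, sep, header = TRUE, comment_header = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- gzfile(path, "r")
  on.exit(close(con))
  if (comment_header) {
    # gene2pubmed-style: header line prefixed with '#'
    first <- readLines(con, n = 1L)
    cols <- strsplit(sub("^#\\s*", "", first), sep, fixed = TRUE)[[1]]
    df <- utils::read.table(con, sep = sep, header = FALSE, quote = "",
                            colClasses = "character", fill = TRUE,
                            comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) != length(cols)) {
      cols <- cols[seq_len(min(length(cols), ncol(df)))]
    }
    names(df)[seq_along(cols)] <- trimws(cols)
  } else {
    df <- utils::read.table(con, sep = sep, header = header, quote = "\"",
                            colClasses = "character", fill = TRUE,
                            comment.char = "", stringsAsFactors = FALSE)
  }
  df
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("column(s) %s not found in %s; available: %s",
                 paste(missing, collapse = ", "), path,
                 paste(names(df), collapse = ", ")))
  }
}

#' Normalize identifier tokens
#'
#' Whitespace is stripped from every ID. DOIs are additionally case-folded to
#' lower case (DOIs are case-insensitive by definition, and mixed-case DOIs
#' otherwise cause silent join misses); PMID-like tokens are left verbatim.
#'
#' @param x character vector of identifiers.
#' @param doi logical; treat the tokens as DOIs.
#' @return normalized character vector.
#' @export
normalize_id <- function(x, doi = FALSE) {
  x <- trimws(as.character(x))
  if (doi) tolower(x) else x
}

#' Read citation pairs from a delimited file
#'
#' Reads ordered (citing, cited) identifier pairs from a CSV with a header
#' row, selecting columns by name so that files with extra columns (COCI
#' exports carry five or more) or shuffled column orders read identically.
#'
#' @param path CSV file (optionally gzipped) with a header row.
#' @param citing_col,cited_col names of the citing / cited columns.
#' @param sep field separator.
#' @param doi logical; case-fold the identifiers as DOIs.
#' @return data.frame with character columns `citing` and `cited`, one row per
#'   complete data row, in file order. Rows with an empty cell in either
#'   column are skipped; the attrition is recorded in the `"load_report"`
#'   attribute (`rows_read`, `rows_kept`, `rows_skipped`).
#' @export
read_citation_pairs <- function(path, citing_col = "citing", cited_col = "cited",
                                sep = ",", doi = FALSE) {
  df <- read_delim_chr(path, sep = sep, header = TRUE)
  require_columns(df, c(citing_col, cited_col), path)
  citing <- normalize_id(df[[citing_col]], doi = doi)
  cited <- normalize_id(df[[cited_col]], doi = doi)
  keep <- nzchar(citing) & nzchar(cited) & !is.na(citing) & !is.na(cited)
  out <- data.frame(citing = citing[keep], cited = cited[keep],
                    stringsAsFactors = FALSE)
  report <- list(rows_read = nrow(df), rows_kept = sum(keep),
                 rows_skipped = sum(!keep))
  if (report$rows_skipped > 0L) {
    message(sprintf("read_citation_pairs: skipped %d incomplete row(s) of %d",
                    report$rows_skipped, report$rows_read))
  }
  attr(out, "load_report") <- report
  out
}

#' Write citation pairs in the dialect read_citation_pairs() reads
#'
#' @param pairs data.frame with `citing` and `cited` columns.
#' @param path output path (a `.gz` suffix triggers gzip compression).
#' @param sep field separator.
#' @export
write_citation_pairs <- function(pairs, path, sep = ",") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(pairs[, c("citing", "cited")], con, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an external-ID to article-ID mapping table
#'
#' Loads a PMID-PMCID-DOI style table into a lookup from external IDs
#' (DOI-like, case-folded) to article IDs. When an external ID maps to several
#' article IDs, the first occurrence wins and the conflict is counted.
#'
#' @param path delimited file with a header row.
#' @param external_col,article_col column names for the external ID and the
#'   article ID.
#' @param sep field separator.
#' @return named character vector (names = normalized external IDs, values =
#'   article IDs) of class `id_mapping`.
#' @export
read_id_mapping <- function(path, external_col = "DOI", article_col = "PMID",
                            sep = ",") {
  df <- read_delim_chr(path, sep = sep, header = TRUE)
  require_columns(df, c(external_col, article_col), path)
  ext <- normalize_id(df[[external_col]], doi = TRUE)
  art <- normalize_id(df[[article_col]])
  keep <- nzchar(ext) & nzchar(art)
  ext <- ext[keep]; art <- art[keep]
  dup <- duplicated(ext)
  if (any(dup)) {
    message(sprintf("read_id_mapping: %d duplicate external ID(s); first kept",
                    sum(dup)))
  }
  m <- art[!dup]
  names(m) <- ext[!dup]
  class(m) <- "id_mapping"
  m
}

#' Map DOI-level citation pairs to article-ID pairs
#'
#' Only pairs where BOTH endpoints have a mapping are retained; dropping the
#' rest mirrors the heavy attrition seen when open-citation DOI pairs are
#' joined to PMID space.
#'
#' @param pairs data.frame with `citing`/`cited` external-ID columns.
#' @param mapping an `id_mapping` from [read_id_mapping()].
#' @return data.frame of mapped `citing`/`cited` article-ID pairs with a
#'   `"map_report"` attribute (`n_input`, `n_kept`, `n_dropped`).
#' @export
map_citations <- function(pairs, mapping) {
  stopifnot(inherits(mapping, "id_mapping"))
  citing <- unname(unclass(mapping)[normalize_id(pairs$citing, doi = TRUE)])
  cited <- unname(unclass(mapping)[normalize_id(pairs$cited, doi = TRUE)])
  keep <- !is.na(citing) & !is.na(cited)
  out <- data.frame(citing = citing[keep], cited = cited[keep],
                    stringsAsFactors = FALSE)
  report <- list(n_input = nrow(pairs), n_kept = sum(keep),
                 n_dropped = sum(!keep))
  message(sprintf("map_citations: %d of %d pairs mapped on both endpoints",
                  report$n_kept, report$n_input))
  attr(out, "map_report") <- report
  out
}

#' Read an annotation table into an annotation store
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`gene2pubmed`}{TSV whose header line starts with `#`, columns
#'     `tax_id`, `GeneID`, `PubMed_ID`. Rows are restricted to `taxon_filter`
#'     (default `"9606"`, human) unless that filter is `NULL`.}
#'   \item{`generic`}{tab-delimited file with header columns `article` and
#'     `annotation` (the format [write_annotation_store()] dumps, so stores
#'     round-trip).}
#'   \item{`mesh`}{delimited file with header columns `article`, `annotation`
#'     and `major_topic` (`Y`/`N`); with `major_topic_only = TRUE` only
#'     major-topic rows are kept.}
#' }
#' Duplicate (article, annotation) rows collapse into the per-article set.
#'
#' @param path input file (optionally gzipped).
#' @param dialect one of `"generic"`, `"gene2pubmed"`, `"mesh"`.
#' @param taxon_filter taxon token for the gene2pubmed dialect; `NULL`
#'   disables the filter.
#' @param major_topic_only keep only major-topic rows in the mesh dialect.
#' @param sep field separator (defaults to tab for the gene2pubmed and
#'   generic dialects, comma for mesh).
#' @param dataset_name store label; defaults to the file name.
#' @return an [annotation_store()] with a `"load_report"` attribute
#'   (`rows_read`, `rows_kept`, `rows_filtered`, `rows_malformed`).
#' @export
read_annotation_table <- function(path,
                                  dialect = c("generic", "gene2pubmed", "mesh"),
                                  taxon_filter = "9606",
                                  major_topic_only = TRUE,
                                  sep = NULL,
                                  dataset_name = basename(path)) {
  dialect <- match.arg(dialect)
  if (is.null(sep)) sep <- if (dialect == "mesh") "," else "\t"
  df <- read_delim_chr(path, sep = sep, header = TRUE,
                       comment_header = dialect == "gene2pubmed")
  n_read <- nrow(df)
  if (dialect == "gene2pubmed") {
    require_columns(df, c("tax_id", "GeneID", "PubMed_ID"), path)
    article <- normalize_id(df[["PubMed_ID"]])
    annotation <- normalize_id(df[["GeneID"]])
    pass <- if (is.null(taxon_filter)) rep(TRUE, n_read) else
      normalize_id(df[["tax_id"]]) == as.character(taxon_filter)
  } else if (dialect == "mesh") {
    require_columns(df, c("article", "annotation", "major_topic"), path)
    article <- normalize_id(df[["article"]])
    annotation <- normalize_id(df[["annotation"]])
    pass <- if (major_topic_only)
      toupper(normalize_id(df[["major_topic"]])) %in% c("Y", "YES", "TRUE", "1")
    else rep(TRUE, n_read)
  } else {
    require_columns(df, c("article", "annotation"), path)
    article <- normalize_id(df[["article"]])
    annotation <- normalize_id(df[["annotation"]])
    pass <- rep(TRUE, n_read)
  }
  wellformed <- nzchar(article) & nzchar(annotation) &
    !is.na(article) & !is.na(annotation)
  keep <- wellformed & pass
  report <- list(rows_read = n_read, rows_kept = sum(keep),
                 rows_filtered = sum(wellformed & !pass),
                 rows_malformed = sum(!wellformed))
  if (report$rows_malformed > 0L) {
    message(sprintf("read_annotation_table: skipped %d malformed row(s)",
                    report$rows_malformed))
  }
  store <- annotation_store(split(annotation[keep], article[keep]),
                            dataset_name = dataset_name)
  attr(store, "load_report") <- report
  store
}

#' Read a gold-standard annotation set
#'
#' Gold-standard files are headerless two-column (article, annotation) lists,
#' tab- or whitespace-delimited, in the style of gene-normalization challenge
#' answer keys. Several files (e.g. training and test splits) can be given;
#' their records are unioned per article.
#'
#' @param paths one or more file paths.
#' @param dataset_name store label.
#' @return an [annotation_store()] restricted to the gold articles.
#' @export
read_gold_standard <- function(paths, dataset_name = "gold_standard") {
  art <- character(0); ann <- character(0)
  for (path in paths) {
    if (!file.exists(path)) stop("input file not found: ", path)
    con <- gzfile(path, "r")
    lines <- readLines(con)
    close(con)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("gold-standard file is empty: ", path)
    fields <- strsplit(lines, "[\t[:space:]]+")
    ok <- lengths(fields) >= 2L
    if (any(!ok)) {
      message(sprintf("read_gold_standard: skipped %d malformed line(s) in %s",
                      sum(!ok), path))
    }
    art <- c(art, vapply(fields[ok], `[`, "", 1L))
    ann <- c(ann, vapply(fields[ok], `[`, "", 2L))
  }
  if (length(art) == 0L) stop("no gold-standard records read")
  annotation_store(split(normalize_id(ann), normalize_id(art)),
                   dataset_name = dataset_name)
}
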