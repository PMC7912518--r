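test_that("citation pairs are read in file order with named column selection", {
  p <- write_tmp(c("citing,cited", "1,2", "3,4", "5,2"))
  pairs <- read_citation_pairs(p)
  expect_equal(pairs$citing, c("1", "3", "5"))
  expect_equal(pairs$cited, c("2", "4", "2"))
  expect_equal(attr(pairs, "load_report"),
               list(rows_read = 3L, rows_kept = 3L, rows_skipped = 0L))

  # incomplete row is skipped and counted
  p2 <- write_tmp(c("citing,cited", "1,"))
  expect_message(pairs2 <- read_citation_pairs(p2), "skipped 1")
  expect_equal(nrow(pairs2), 0L)
  expect_equal(attr(pairs2, "load_report")$rows_skipped, 1L)

  # COCI-style wide file: named columns picked regardless of position,
  # checked against a line-by-line split oracle
  lines <- c("oci,citing,cited,creation,timespan",
             sprintf("oci%d,10.1/a%d,10.2/b%d,2020,P1Y", 1:7, 1:7, 7:1))
  p3 <- write_tmp(lines)
  pairs3 <- read_citation_pairs(p3, doi = TRUE)
  split_fields <- strsplit(lines[-1], ",", fixed = TRUE)
  expect_equal(pairs3$citing, vapply(split_fields, `[`, "", 2L))
  expect_equal(pairs3$cited, vapply(split_fields, `[`, "", 3L))

  expect_error(read_citation_pairs(tempfile()), "not found")
  expect_error(read_citation_pairs(p3, citing_col = "nope"), "oci")
})

test_that("gzip-compressed input reads identically to plain text", {
  lines <- c("citing,cited", "10,20", "30,40")
  plain <- write_tmp(lines)
  gz <- tempfile(fileext = ".csv.gz")
  con <- gzfile(gz, "w"); writeLines(lines, con); close(con)
  expect_equal(read_citation_pairs(gz), read_citation_pairs(plain),
               ignore_attr = TRUE)
})

test_that("DOI mapping keeps only pairs with both endpoints mapped", {
  map_file <- write_tmp(c("DOI,PMID", "10.1/a,100", "10.1/b,200", "10.1/c,300"))
  m <- read_id_mapping(map_file)

  pairs <- data.frame(citing = c("10.1/a", "10.1/b"),
                      cited = c("10.1/b", "10.1/c"))
  expect_equal(suppressMessages(map_citations(pairs, m))$citing, c("100", "200"))

  # one unmapped endpoint drops the pair
  pairs2 <- data.frame(citing = c("10.1/a", "10.1/b"),
                       cited = c("10.1/b", "10.1/zz"))
  out2 <- suppressMessages(map_citations(pairs2, m))
  expect_equal(nrow(out2), 1L)
  expect_equal(attr(out2, "map_report")$n_dropped, 1L)

  # DOIs are case-insensitive: folded on both sides of the join
  pairs3 <- data.frame(citing = "10.1/A", cited = "10.1/B")
  expect_equal(suppressMessages(map_citations(pairs3, m))$cited, "200")

  # random pairs against a brute-force filter oracle
  dois <- sprintf("10.9/x%02d", 1:20)
  mapped <- dois[1:10]
  map_big <- write_tmp(c("DOI,PMID", sprintf("%s,%d", mapped, 1:10)))
  m2 <- read_id_mapping(map_big)
  rp <- withr::with_seed(4, data.frame(citing = sample(dois, 10, TRUE),
                                       cited = sample(dois, 10, TRUE)))
  out <- suppressMessages(map_citations(rp, m2))
  keep_oracle <- rp$citing %in% mapped & rp$cited %in% mapped
  expect_equal(nrow(out), sum(keep_oracle))
  rep <- attr(out, "map_report")
  expect_equal(rep$n_kept + rep$n_dropped, rep$n_input)
})

test_that("annotation dialects apply taxon and major-topic filters", {
  g2p <- write_tmp(c("#tax_id\tGeneID\tPubMed_ID",
                     "9606\tG1\tP1", "10090\tG2\tP1", "9606\tG1\tP2"),
                   ext = ".tsv")
  store <- read_annotation_table(g2p, dialect = "gene2pubmed")
  expect_equal(store$records, list(P1 = "G1", P2 = "G1"))
  expect_equal(attr(store, "load_report")$rows_filtered, 1L)
  # filter overridable
  store_m <- read_annotation_table(g2p, dialect = "gene2pubmed",
                                   taxon_filter = "10090")
  expect_equal(store_m$records, list(P1 = "G2"))

  mesh <- write_tmp(c("article,annotation,major_topic", "P1,M1,Y", "P1,M2,N"))
  expect_equal(read_annotation_table(mesh, dialect = "mesh")$records,
               list(P1 = "M1"))
  expect_equal(
    read_annotation_table(mesh, dialect = "mesh",
                          major_topic_only = FALSE)$records,
    list(P1 = c("M1", "M2"))
  )

  expect_error(read_annotation_table(mesh, dialect = "unknown"))
})

test_that("generic tables with duplicates collapse to the group-by sets", {
  rows <- withr::with_seed(9, data.frame(
    article = sample(sprintf("P%d", 1:8), 50, TRUE),
    annotation = sample(sprintf("A%d", 1:6), 50, TRUE)
  ))
  p <- write_tmp(c("article\tannotation",
                   sprintf("%s\t%s", rows$article, rows$annotation)),
                 ext = ".tsv")
  store <- read_annotation_table(p, dialect = "generic")
  oracle <- lapply(split(rows$annotation, rows$article),
                   function(x) sort(unique(x)))
  expect_equal(store$records, oracle[order(names(oracle))])
  expect_equal(store$vocabulary, sort(unique(rows$annotation)))
})

test_that("annotation stores round-trip through the generic dump dialect", {
  store <- random_store(25, sprintf("A%02d", 1:15), mean_size = 3, seed = 21,
                        name = "roundtrip")
  path <- tempfile(fileext = ".tsv")
  write_annotation_store(store, path)
  back <- read_annotation_table(path, dialect = "generic",
                                dataset_name = "roundtrip")
  expect_identical(back$records, store$records)
  expect_identical(back$vocabulary, store$vocabulary)
})

test_that("gold-standard files dedupe per article and union across splits", {
  f1 <- write_tmp(c("P1\tG1", "P1\tG2", "P2\tG1"), ext = ".txt")
  gs <- read_gold_standard(f1)
  expect_equal(gs$records, list(P1 = c("G1", "G2"), P2 = "G1"))

  # repeated (article, gene) row collapses
  f2 <- write_tmp(c("P9\tG5", "P9\tG5"), ext = ".txt")
  expect_equal(read_gold_standard(f2)$records, list(P9 = "G5"))

  # training + test splits union per article
  train <- write_tmp(c("P1\tG1", "P3\tG9"), ext = ".txt")
  test_f <- write_tmp(c("P1\tG2", "P4\tG1"), ext = ".txt")
  merged <- read_gold_standard(c(train, test_f))
  expect_equal(merged$records,
               list(P1 = c("G1", "G2"), P3 = "G9", P4 = "G1"))

  empty <- write_tmp(character(0), ext = ".txt")
  expect_error(read_gold_standard(empty), "empty")
})

test_that("store summaries count (article, annotation) pairs and articles", {
  s <- annotation_store(list(P1 = c("A", "B"), P2 = "A"))
  expect_equal(summarize_store(s), list(n_annotation_rows = 3L, n_articles = 2L))
  expect_equal(summarize_store(annotation_store(list())),
               list(n_annotation_rows = 0L, n_articles = 0L))

  big <- random_store(100, sprintf("A%03d", 1:40), mean_size = 4, seed = 3)
  n_pairs_oracle <- 0L
  for (r in big$records) n_pairs_oracle <- n_pairs_oracle + length(r)
  expect_equal(summarize_store(big),
               list(n_annotation_rows = n_pairs_oracle, n_articles = 100L))
})
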