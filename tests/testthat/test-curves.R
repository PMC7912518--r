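fake_records <- function(n, seed, max_neighbors = 30L) {
  withr::with_seed(seed, {
    n_ann <- 1L + stats::rpois(n, 2)
    n_shared <- vapply(n_ann, function(m) sample.int(m + 1L, 1L) - 1L, 0L)
    n_nb_ann <- n_shared + stats::rpois(n, 4)
    n_nb_ann[n_nb_ann == 0L] <- 1L
    data.frame(
      focal = sprintf("P%04d", seq_len(n)),
      n_total_neighbors = rep(max_neighbors, n),
      n_annotated_neighbors = sample.int(max_neighbors, n, replace = TRUE),
      n_article_annots = n_ann,
      n_neighborhood_annots = n_nb_ann,
      n_shared = n_shared,
      recall = n_shared / n_ann,
      precision = n_shared / n_nb_ann,
      ap = (n_shared / n_ann) * stats::runif(n)
    )
  })
}

test_that("stratification bins by exact annotated-neighbor count with pooled tail", {
  rec <- fake_records(2, seed = 1)
  rec$n_annotated_neighbors <- c(3L, 3L)
  rec$recall <- c(0.5, 1.0)
  cur <- stratify(rec)
  expect_equal(cur$bin, 3L)
  expect_equal(cur$n_records, 2L)
  expect_equal(cur$mean_recall, 0.75)

  one <- fake_records(1, seed = 2)
  cur1 <- stratify(one)
  expect_equal(cur1$mean_recall, one$recall)
  expect_equal(cur1$map, one$ap)

  # group-by-mean oracle over 500 records, including the pooled open bin
  rec5 <- fake_records(500, seed = 3)
  cur5 <- stratify(rec5, max_bin = 20)
  for (i in seq_len(nrow(cur5))) {
    b <- cur5$bin[i]
    sel <- if (cur5$pooled[i]) rec5$n_annotated_neighbors > 20
           else rec5$n_annotated_neighbors == b
    expect_equal(cur5$n_records[i], sum(sel))
    expect_equal(cur5$mean_recall[i], mean(rec5$recall[sel]))
    expect_equal(cur5$mean_precision[i], mean(rec5$precision[sel]))
    expect_equal(cur5$map[i], mean(rec5$ap[sel]))
  }
  expect_equal(sum(cur5$pooled), 1L)
  expect_equal(sum(cur5$n_records), 500L)
  expect_warning(stratify(fake_records(0, seed = 1)), "no records")
})

test_that("corpus recall is annotation-weighted, not an article mean", {
  rec <- fake_records(2, seed = 4)
  rec$n_article_annots <- c(2L, 3L)
  rec$n_shared <- c(1L, 3L)
  rec$recall <- rec$n_shared / rec$n_article_annots
  expect_equal(corpus_recall(rec), 4 / 5)
  expect_gt(abs(corpus_recall(rec) - mean(rec$recall)), 0.01)

  rec$n_shared <- rec$n_article_annots
  expect_equal(corpus_recall(rec), 1)

  big <- fake_records(200, seed = 5)
  flat_num <- 0L; flat_den <- 0L
  for (i in seq_len(nrow(big))) {
    flat_num <- flat_num + big$n_shared[i]
    flat_den <- flat_den + big$n_article_annots[i]
  }
  expect_equal(corpus_recall(big), flat_num / flat_den)
  expect_gte(corpus_recall(big), min(big$recall))
  expect_lte(corpus_recall(big), max(big$recall))

  # equal annotation counts collapse it onto the per-article mean
  eq <- big
  eq$n_article_annots <- 4L
  eq$n_shared <- withr::with_seed(6, sample.int(5, 200, TRUE) - 1L)
  eq$recall <- eq$n_shared / 4
  expect_equal(corpus_recall(eq), mean(eq$recall))

  none <- big[0, ]
  expect_error(corpus_recall(none), "undefined")
})

test_that("full-recall fraction compares integers exactly", {
  rec <- fake_records(4, seed = 7)
  rec$n_article_annots <- c(3L, 2L, 7L, 5L)
  rec$n_shared <- c(3L, 1L, 7L, 0L)
  expect_equal(fraction_full_recall(rec), 0.5)
  # excluded articles only enter through the explicit corpus denominator
  expect_equal(fraction_full_recall(rec, n_corpus = 8), 0.25)

  big <- fake_records(200, seed = 8)
  count <- 0L
  for (i in seq_len(nrow(big))) {
    if (big$n_shared[i] == big$n_article_annots[i]) count <- count + 1L
  }
  expect_equal(fraction_full_recall(big), count / 200)
})

test_that("coverage counts articles with enough annotated neighbors", {
  # chain A-B-C-D, only A annotated: just B has an annotated neighbor
  chain <- build_graph(data.frame(citing = c("A", "B", "C"),
                                  cited = c("B", "C", "D")))
  ann_a <- annotation_store(list(A = "G1"))
  expect_equal(coverage(chain, ann_a, c("A", "B", "C", "D")), 1 / 4)
  # at degree 2, C also reaches A
  expect_equal(coverage(chain, ann_a, c("A", "B", "C", "D"), degree = 2), 2 / 4)

  all_ann <- annotation_store(setNames(as.list(sprintf("G%d", 1:4)),
                                       c("A", "B", "C", "D")))
  expect_equal(coverage(chain, all_ann, c("A", "B", "C", "D")), 1)
  expect_error(coverage(chain, ann_a, character(0)), "empty")

  # per-node brute force plus monotonicity in threshold and degree
  corp <- generate_corpus(synthetic_config(n_articles = 120, seed = 9))
  universe <- corp$truth$ids
  annotated <- names(corp$store$records)
  for (m in 1:3) {
    brute <- mean(vapply(universe, function(id) {
      sum(neighbors_of(corp$graph, id) %in% annotated) >= m
    }, logical(1)))
    expect_equal(coverage(corp$graph, corp$store, universe,
                          min_annotated_neighbors = m), brute)
  }
  c1 <- coverage(corp$graph, corp$store, universe, 1)
  c2 <- coverage(corp$graph, corp$store, universe, 2)
  c1d2 <- coverage(corp$graph, corp$store, universe, 1, degree = 2)
  expect_lte(c2, c1)
  expect_gte(c1d2, c1)
})

test_that("sigmoid fit recovers exact parameters on noise-free data", {
  x <- 1:12
  y <- 0.9 / (1 + exp(-0.8 * (x - 4)))
  fit <- fit_sigmoid(x, y, n_boot = 20, seed = 1)
  expect_equal(fit$L, 0.9, tolerance = 1e-6)
  expect_equal(fit$k, 0.8, tolerance = 1e-6)
  expect_equal(fit$x0, 4, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- fit_sigmoid(x, rep(0.4, 12), n_boot = 5, seed = 1)
  expect_true(flat$degenerate)
  expect_equal(flat$L, 0.4)

  expect_error(fit_sigmoid(c(1, 1, 2, 2), c(0, 0, 1, 1)), "distinct")
})

test_that("sigmoid predictions respect midpoint, asymptote and monotonicity", {
  x <- withr::with_seed(2, sample(1:15, 300, replace = TRUE))
  y <- 0.85 / (1 + exp(-0.7 * (x - 5))) + withr::with_seed(3, rnorm(300, 0, 0.05))
  fit <- fit_sigmoid(x, y, n_boot = 100, seed = 4)
  expect_equal(predict_recall(fit, fit$x0)$fit, fit$L / 2, tolerance = 1e-9)
  expect_equal(predict_recall(fit, 1e4)$fit, fit$L, tolerance = 1e-6)
  preds <- predict_recall(fit, 1:20)
  expect_true(all(diff(preds$fit) >= 0))
  expect_true(all(preds$lwr <= preds$fit & preds$fit <= preds$upr))
  # closed-form check at a reference count
  expect_equal(predict_recall(fit, 5)$fit,
               min(max(fit$L / (1 + exp(-fit$k * (5 - fit$x0))), 0), 1))
})
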