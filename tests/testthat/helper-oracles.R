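# Independent oracles and fixture builders. Every oracle is a deliberately
# naive re-derivation (literal definition, nested loops, linear scans) kept
# separate from the package's code paths.

# Literal evaluation of AP = sum_k P(k) * (R(k) - R(k-1)), R(0) = 0.
oracle_ap <- function(ranking, relevant) {
  relevant <- unique(relevant)
  r_prev <- 0
  ap <- 0
  for (k in seq_along(ranking)) {
    topk <- ranking[seq_len(k)]
    p_k <- sum(topk %in% relevant) / k
    r_k <- sum(relevant %in% topk) / length(relevant)
    ap <- ap + p_k * (r_k - r_prev)
    r_prev <- r_k
  }
  ap
}

# Depth-limited breadth-first neighborhood over the raw pair list.
oracle_neighbors <- function(pairs, focal, mode = "undirected", degree = 1) {
  citing <- as.character(pairs$citing)
  cited <- as.character(pairs$cited)
  keep <- citing != cited
  citing <- citing[keep]
  cited <- cited[keep]
  step1 <- function(nodes) {
    out <- character(0)
    for (nd in nodes) {
      if (mode %in% c("undirected", "cited")) out <- c(out, cited[citing == nd])
      if (mode %in% c("undirected", "citing")) out <- c(out, citing[cited == nd])
    }
    unique(out)
  }
  n1 <- step1(focal)
  res <- if (degree == 1) n1 else union(n1, step1(n1))
  sort(setdiff(res, focal))
}

random_pair_df <- function(n_pairs, n_nodes, seed) {
  withr::with_seed(seed, data.frame(
    citing = sprintf("N%03d", sample.int(n_nodes, n_pairs, replace = TRUE)),
    cited = sprintf("N%03d", sample.int(n_nodes, n_pairs, replace = TRUE)),
    stringsAsFactors = FALSE
  ))
}

random_store <- function(n_articles, vocab, mean_size, seed, name = "random") {
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n_articles), function(i) {
      sample(vocab, min(1 + stats::rpois(1, mean_size - 1), length(vocab)))
    })
    names(recs) <- sprintf("N%03d", seq_len(n_articles))
    annotation_store(recs, name)
  })
}

# Bare neighborhood profile for metric-only tests.
make_profile <- function(freq, focal = "F", mode = "undirected", degree = 1L,
                         total_neighbors = max(c(freq, 0L)),
                         annotated_neighbors = max(c(freq, 0L))) {
  structure(
    list(focal = focal, mode = mode, degree = as.integer(degree),
         total_neighbors = total_neighbors,
         annotated_neighbors = annotated_neighbors,
         freq = freq),
    class = "neighborhood_profile"
  )
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

nonempty_subsets <- function(v) {
  n <- length(v)
  lapply(seq_len(2^n - 1L), function(mask) {
    v[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
  })
}

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
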