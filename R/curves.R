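# Corpus-level aggregation: recall/precision/MAP curves stratified by the
# number of annotated neighbors, annotation-weighted corpus recall, the
# fraction of articles at full recall, neighborhood coverage of an article
# universe, and a bounded sigmoidal fit of per-article recall against
# annotated-neighbor count used to extrapolate attainable recall.

#' Stratify overlap records by annotated-neighbor count
#'
#' Emits one curve point per exact annotated-neighbor count `1..max_bin`;
#' records with more annotated neighbors pool into a terminal open bin
#' (flagged by `pooled = TRUE`, positioned at `max_bin + 1`) which is
#' reported but conventionally left out of curve plots. The MAP of a bin is
#' the mean AP of its records.
#'
#' @param records data.frame from [evaluate_corpus()].
#' @param max_bin largest exact bin (default 20, the customary cut-off).
#' @return data.frame of curve points: `bin`, `pooled`, `n_records`,
#'   `mean_recall`, `mean_precision`, `map`. Only bins with at least one
#'   record are emitted.
#' @export
stratify <- function(records, max_bin = 20L) {
  if (nrow(records) == 0L) {
    warning("no records to stratify")
    return(data.frame(bin = integer(0), pooled = logical(0),
                      n_records = integer(0), mean_recall = numeric(0),
                      mean_precision = numeric(0), map = numeric(0)))
  }
  bin <- pmin(records$n_annotated_neighbors, max_bin + 1L)
  agg <- function(v) tapply(v, bin, mean)
  n <- tapply(rep(1L, nrow(records)), bin, sum)
  out <- data.frame(
    bin = as.integer(names(n)),
    pooled = as.integer(names(n)) > max_bin,
    n_records = as.integer(n),
    mean_recall = as.numeric(agg(records$recall)),
    mean_precision = as.numeric(agg(records$precision)),
    map = as.numeric(agg(records$ap))
  )
  out[order(out$bin), , drop = FALSE]
}

#' Annotation-weighted corpus recall
#'
#' Total annotations recovered across all target articles divided by the
#' total number of target annotations. This weights every annotation
#' equally, unlike the mean of per-article recalls, which weights every
#' article equally.
#'
#' @param records data.frame from [evaluate_corpus()].
#' @return fraction in `[0, 1]`.
#' @export
corpus_recall <- function(records) {
  total <- sum(records$n_article_annots)
  if (total == 0L) stop("corpus recall undefined: no target annotations")
  sum(records$n_shared) / total
}

#' Fraction of articles whose neighborhood recovers every annotation
#'
#' Full recall is tested exactly as `n_shared == n_article_annots` (recall is
#' a ratio of small integers; no floating-point tolerance is involved). The
#' default denominator is the evaluated records, i.e. articles with at least
#' one annotated neighbor; pass `n_corpus` to use the full target corpus
#' including excluded articles instead.
#'
#' @param records data.frame from [evaluate_corpus()].
#' @param n_corpus optional corpus-wide denominator.
#' @return fraction in `[0, 1]`.
#' @export
fraction_full_recall <- function(records, n_corpus = NULL) {
  hits <- sum(records$n_shared == records$n_article_annots)
  denom <- if (is.null(n_corpus)) nrow(records) else n_corpus
  if (denom == 0L) stop("no records")
  hits / denom
}

#' Coverage of an article universe by annotated neighborhoods
#'
#' Fraction of the universe whose citation neighborhood (at the given degree
#' and direction mode) contains at least `min_annotated_neighbors` articles
#' annotated in `store`. This measures how much of a corpus the
#' neighborhood-annotation approach can reach at all.
#'
#' @param graph a `citation_graph`.
#' @param store an `annotation_store`.
#' @param universe character vector of article IDs; must be non-empty.
#' @param min_annotated_neighbors threshold count (default 1).
#' @inheritParams neighbors_of
#' @return fraction in `[0, 1]`.
#' @export
coverage <- function(graph, store, universe, min_annotated_neighbors = 1L,
                     mode = "undirected", degree = 1L) {
  if (length(universe) == 0L) stop("empty universe")
  annotated <- names(store$records)
  hit <- vapply(universe, function(id) {
    nbrs <- neighbors_of(graph, id, mode = mode, degree = degree)
    sum(nbrs %in% annotated) >= min_annotated_neighbors
  }, logical(1))
  mean(hit)
}

sigmoid_eval <- function(x, L, k, x0) L / (1 + exp(-k * (x - x0)))

#' Fit a bounded sigmoid of recall against annotated-neighbor count
#'
#' Least-squares fit of `y = L / (1 + exp(-k (x - x0)))` to per-article
#' points (recall versus annotated-neighbor count). The sigmoid is used
#' because recall is monotone in neighborhood annotation and bounded in
#' `[0, 1]`; the upper asymptote `L` is constrained to that range.
#' Uncertainty comes from a seeded parametric bootstrap: residual variance is
#' re-simulated around the fitted curve and the model refitted `n_boot`
#' times.
#'
#' Initialization is `L = max(y)`, `x0 = median(x)`, `k = 1`. A constant
#' response (zero total sum of squares) yields a degenerate fit object with
#' `degenerate = TRUE` rather than an error.
#'
#' @param x numeric, annotated-neighbor counts.
#' @param y numeric, per-article recalls.
#' @param n_boot bootstrap replicates for the confidence intervals.
#' @param seed integer seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @return object of class `sigmoid_fit`: parameters `L`, `k`, `x0`,
#'   `r_squared`, residual `sigma`, `ci` (parameter bounds), `boot`
#'   (bootstrap parameter draws), `n`, `seed`, `degenerate`.
#' @export
fit_sigmoid <- function(x, y, n_boot = 200L, seed = 1L, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4L) stop("need >= 4 distinct x values to fit")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(structure(
      list(L = mean(y), k = NA_real_, x0 = NA_real_, r_squared = NA_real_,
           sigma = 0, ci = NULL, boot = NULL, n = length(x), seed = seed,
           degenerate = TRUE),
      class = "sigmoid_fit"
    ))
  }
  # Two starts: the natural one (L at the empirical maximum, pulled inside
  # the [0, 1] bound) and a mid-range one. The Levenberg-Marquardt search
  # can stall on the L = 1 boundary when started at or above it, so the
  # best-RSS fit over both starts is kept.
  fit_once <- function(xx, yy) {
    starts <- list(
      list(L = min(max(yy), 0.95), k = 1, x0 = stats::median(xx)),
      list(L = 0.5, k = 1, x0 = stats::median(xx))
    )
    fits <- lapply(starts, function(s) {
      tryCatch(
        minpack.lm::nlsLM(
          yy ~ L / (1 + exp(-k * (xx - x0))),
          start = s,
          lower = c(L = 1e-8, k = -50, x0 = min(xx) - diff(range(xx)) - 1),
          upper = c(L = 1, k = 50, x0 = max(xx) + diff(range(xx)) + 1),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (length(fits) == 0L) stop("sigmoid fit failed to converge from all starts")
    rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
    fits[[which.min(rss)]]
  }
  fit <- fit_once(x, y)
  p <- stats::coef(fit)
  resid <- y - sigmoid_eval(x, p["L"], p["k"], p["x0"])
  ss_res <- sum(resid^2)
  dfree <- max(length(x) - 3L, 1L)
  sigma <- sqrt(ss_res / dfree)
  boot <- withr::with_seed(seed, {
    fitted_y <- sigmoid_eval(x, p["L"], p["k"], p["x0"])
    draws <- lapply(seq_len(n_boot), function(b) {
      yb <- fitted_y + stats::rnorm(length(x), 0, sigma)
      fb <- tryCatch(fit_once(x, yb), error = function(e) NULL)
      if (is.null(fb)) NULL else stats::coef(fb)
    })
    do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  })
  alpha <- (1 - level) / 2
  ci <- if (!is.null(boot) && nrow(boot) > 0L) {
    apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  } else NULL
  structure(
    list(L = unname(p["L"]), k = unname(p["k"]), x0 = unname(p["x0"]),
         r_squared = 1 - ss_res / ss_tot, sigma = sigma, ci = ci, boot = boot,
         n = length(x), n_boot = n_boot, seed = seed, level = level,
         degenerate = FALSE),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("<sigmoid_fit: degenerate (constant response %.4f, n = %d)>\n",
                x$L, x$n))
  } else {
    cat(sprintf(
      "<sigmoid_fit: L = %.4f, k = %.4f, x0 = %.4f, R^2 = %.4f (n = %d, %d bootstrap draws)>\n",
      x$L, x$k, x$x0, x$r_squared, x$n,
      if (is.null(x$boot)) 0L else nrow(x$boot)
    ))
  }
  invisible(x)
}

#' Predict recall at a given annotated-neighbor count
#'
#' Evaluates the fitted sigmoid at `x`, clipped to `[0, 1]`, with bootstrap
#' prediction bounds for the curve. This is the extrapolation device: "what
#' recall would articles reach if they all had exactly x annotated
#' neighbors".
#'
#' @param fit a `sigmoid_fit`.
#' @param x numeric vector of annotated-neighbor counts.
#' @param level confidence level for the bounds.
#' @return data.frame with `x`, `fit`, `lwr`, `upr`.
#' @export
predict_recall <- function(fit, x, level = 0.95) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (isTRUE(fit$degenerate)) {
    return(data.frame(x = x, fit = rep(fit$L, length(x)),
                      lwr = rep(fit$L, length(x)), upr = rep(fit$L, length(x))))
  }
  clip01 <- function(v) pmin(pmax(v, 0), 1)
  est <- clip01(sigmoid_eval(x, fit$L, fit$k, fit$x0))
  alpha <- (1 - level) / 2
  if (!is.null(fit$boot) && nrow(fit$boot) > 0L) {
    bounds <- vapply(x, function(xi) {
      preds <- clip01(sigmoid_eval(xi, fit$boot[, "L"], fit$boot[, "k"],
                                   fit$boot[, "x0"]))
      stats::quantile(preds, probs = c(alpha, 1 - alpha), names = FALSE)
    }, numeric(2))
    data.frame(x = x, fit = est, lwr = bounds[1, ], upr = bounds[2, ])
  } else {
    data.frame(x = x, fit = est, lwr = NA_real_, upr = NA_real_)
  }
}

#' Write curve points as TSV and a sigmoid fit as JSON
#'
#' @param curve data.frame from [stratify()].
#' @param path output TSV path.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @param fit a `sigmoid_fit`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  out <- list(L = fit$L, k = fit$k, x0 = fit$x0, r_squared = fit$r_squared,
              sigma = fit$sigma, n = fit$n, seed = fit$seed,
              degenerate = isTRUE(fit$degenerate))
  if (!is.null(fit$ci)) {
    out$ci <- list(L = fit$ci[, "L"], k = fit$ci[, "k"], x0 = fit$ci[, "x0"])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
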