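# Assessment battery: precision-recall against gold-standard pairs,
# ROC/AUC, discovery rates, hypergeometric gene-set enrichment,
# degree-preserving null networks and paired Wilcoxon comparisons.

#' Precision-recall curve over ranked network edges
#'
#' Walks down the network's edges sorted by descending weight (ties by
#' pair id) and, every `step` edges (and at the final edge), records the
#' running precision and recall among the gold-labeled edges.  Edges
#' absent from the gold standard are skipped in the precision
#' denominator - only labeled pairs are benchmarked.  The x axis is the
#' number of pairs examined, or, in `"coverage"` mode, the fraction of
#' the gene universe seen as nodes so far (used when the positive set is
#' too large for recall to be meaningful).
#'
#' @param net a [gene_network()].
#' @param gold a [gold_standard()].
#' @param step recording interval in edges (default 1000).
#' @param x_axis `"pairs"` or `"coverage"`.
#' @param universe gene universe for coverage mode (default: the
#'   network's genes).
#' @return An object of class `pr_curve`: data frame `points` with
#'   columns `x`, `precision`, `recall`, plus `step` and `x_axis`.
#' @export
precision_recall_curve <- function(net, gold, step = 1000,
                                   x_axis = c("pairs", "coverage"),
                                   universe = NULL) {
  stopifnot(inherits(net, "gene_network"), inherits(gold, "gold_standard"),
            step >= 1)
  x_axis <- match.arg(x_axis)
  ed <- net$edges  # already sorted by descending weight, then pair
  lab <- .gold_labels(ed$gene_a, ed$gene_b, gold)
  if (!any(lab != 0)) {
    stop("no gold-labeled edge in the network", call. = FALSE)
  }
  cum_pos <- cumsum(lab == 1)
  cum_neg <- cumsum(lab == -1)
  n_pos_total <- nrow(gold$positives)
  at <- unique(c(seq_len(nrow(ed) %/% step) * step, nrow(ed)))
  labeled <- cum_pos[at] + cum_neg[at]
  precision <- ifelse(labeled > 0, cum_pos[at] / labeled, NA_real_)
  recall <- cum_pos[at] / n_pos_total
  x <- if (x_axis == "pairs") {
    at
  } else {
    if (is.null(universe)) universe <- net$genes
    # cumulative distinct nodes after each edge
    ids <- c(rbind(ed$gene_a, ed$gene_b))
    cum_nodes <- cumsum(!duplicated(ids))[seq(2, length(ids), by = 2)]
    cum_nodes[at] / length(unique(universe))
  }
  structure(list(points = data.frame(x = x, precision = precision,
                                     recall = recall, row.names = NULL),
                 step = step, x_axis = x_axis),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("pr_curve (%s axis, step %d): %d points\n",
              x$x_axis, x$step, nrow(x$points)))
  print(utils::head(x$points, 5))
  if (nrow(x$points) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  xl <- if (x$x_axis == "pairs") "pairs examined" else "genome coverage"
  graphics::plot(x$points$x, x$points$precision, type = "l",
                 xlab = xl, ylab = "precision", ylim = c(0, 1), ...)
  invisible(x)
}

#' Precision-recall AUC (average precision)
#'
#' Summarizes the ranking of gold-labeled edges by average precision:
#' the sum, over the gold positives retained in the network, of the
#' running precision at each positive, divided by the *total* number of
#' gold positives - so a network that retains few positives cannot
#' outscore one that ranks them all well.  Used to compare component
#' and integrated networks and to tune integration parameters.
#'
#' @param net a [gene_network()].
#' @param gold a [gold_standard()].
#' @return Average precision in `[0, 1]`.
#' @export
pr_auc <- function(net, gold) {
  stopifnot(inherits(net, "gene_network"), inherits(gold, "gold_standard"))
  lab <- .gold_labels(net$edges$gene_a, net$edges$gene_b, gold)
  lab <- lab[lab != 0]
  if (!any(lab == 1)) {
    stop("no gold positive edge in the network", call. = FALSE)
  }
  cum_pos <- cumsum(lab == 1)
  prec_at <- cum_pos / seq_along(lab)
  sum(prec_at[lab == 1]) / nrow(gold$positives)
}

#' ROC AUC by the rank-sum formula
#'
#' Area under the ROC curve for separating positive from negative
#' genes by score, computed with the Mann-Whitney rank-sum identity;
#' tied scores contribute 1/2.
#'
#' @param scores named numeric vector covering both gene sets.
#' @param positives,negatives disjoint character vectors of gene ids
#'   (both non-empty).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(positives) == 0 || length(negatives) == 0) {
    stop("both the positive and negative class must be non-empty",
         call. = FALSE)
  }
  if (length(intersect(positives, negatives)) > 0) {
    stop("positive and negative sets overlap", call. = FALSE)
  }
  all_ids <- c(positives, negatives)
  if (!all(all_ids %in% names(scores))) {
    stop("scores missing for: ",
         paste(utils::head(setdiff(all_ids, names(scores)), 5),
               collapse = ", "), call. = FALSE)
  }
  s <- scores[all_ids]
  r <- rank(s)
  n_pos <- length(positives); n_neg <- length(negatives)
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Discovery rate of ranked candidates
#'
#' For each cutoff `k`, the fraction of the top-`k` ranked candidates
#' found in an independent validation gene set, the discovery rate
#' expected by random chance (`|validation| / universe_size`), and the
#' fold enrichment of the former over the latter.
#'
#' @param ranked ordered character vector of candidate gene ids (best
#'   first).
#' @param validation character vector of validated gene ids.
#' @param ks integer cutoffs (each `>= 1` and `<= length(ranked)`).
#' @param universe_size size of the gene universe the candidates were
#'   drawn from (`>= length(validation)`).
#' @return Data frame (`k`, `n_hits`, `rate`, `expected`, `fold`).
#' @export
discovery_rate <- function(ranked, validation, ks = c(50, 100, 200),
                           universe_size) {
  ranked <- as.character(ranked)
  validation <- unique(as.character(validation))
  ks <- as.integer(ks)
  if (any(ks <= 0)) stop("cutoffs k must be positive", call. = FALSE)
  if (any(ks > length(ranked))) {
    stop("cutoff exceeds the number of ranked candidates", call. = FALSE)
  }
  if (universe_size < length(validation)) {
    stop("universe_size smaller than the validation set", call. = FALSE)
  }
  expected <- length(validation) / universe_size
  hits <- vapply(ks, function(k) sum(ranked[seq_len(k)] %in% validation),
                 numeric(1))
  rate <- hits / ks
  data.frame(k = ks, n_hits = as.integer(hits), rate = rate,
             expected = expected,
             fold = ifelse(expected > 0, rate / expected, NA_real_),
             row.names = NULL)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests every annotation term for over-representation in a query gene
#' set with the hypergeometric upper tail (probability of an overlap at
#' least as large as observed), followed by Benjamini-Hochberg
#' adjustment across the tested terms.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param ann an [annotation_set()].
#' @param universe character vector: the gene universe.
#' @return Data frame (`term`, `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `p`, `q`) sorted by ascending p-value.
#' @export
hypergeom_enrichment <- function(query, ann, universe) {
  stopifnot(inherits(ann, "annotation_set"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe); n <- length(query)
  terms <- names(ann$genes)
  K <- vapply(terms, function(t) length(intersect(ann$genes[[t]], universe)),
              numeric(1))
  k <- vapply(terms, function(t) length(intersect(ann$genes[[t]], query)),
              numeric(1))
  keep <- K > 0
  terms <- terms[keep]; K <- K[keep]; k <- k[keep]
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = terms, overlap = as.integer(k),
                    term_size = as.integer(K), query_size = n,
                    universe_size = N, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Degree-preserving random network
#'
#' Null model for network prioritization: rewires the network by
#' repeated double-edge swaps (rejecting self-loops and multi-edges), so
#' the degree sequence is preserved exactly, then redistributes the
#' original edge weights uniformly at random over the rewired edges.
#' Reproducible for a given seed.
#'
#' @param net a [gene_network()].
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer RNG seed.
#' @return A rewired [gene_network()] with the same degree sequence and
#'   the same multiset of weights.
#' @export
degree_preserving_null <- function(net, n_swaps_per_edge = 10, seed) {
  stopifnot(inherits(net, "gene_network"), n_swaps_per_edge >= 1)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (nrow(net$edges) < 2) {
    warning("fewer than 2 edges; network returned unchanged", call. = FALSE)
    return(net)
  }
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = net$genes)
  .with_seed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(
      niter = n_swaps_per_edge * igraph::ecount(g)))
    ed <- igraph::as_data_frame(g2, what = "edges")
    w <- sample(net$edges$weight)
  })
  gene_network(data.frame(gene_a = ed$from, gene_b = ed$to, weight = w,
                          stringsAsFactors = FALSE))
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided paired comparison (e.g. per-trait AUC on the real network
#' versus on degree-preserving null networks).  Zero differences are
#' dropped; the exact signed-rank distribution is used for n <= 25
#' without ties in the absolute differences, otherwise the normal
#' approximation with continuity correction.
#'
#' @param paired_a,paired_b equal-length numeric vectors (length
#'   `>= 5`).
#' @return List with `statistic` (W, the sum of positive-difference
#'   ranks), `p.value` (two-sided), `n` (non-zero differences) and
#'   `exact` (whether the exact distribution was used).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stopifnot(is.numeric(paired_a), is.numeric(paired_b))
  if (length(paired_a) != length(paired_b) || length(paired_a) < 5) {
    stop("need two equal-length vectors of length >= 5", call. = FALSE)
  }
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0) {
    stop("all paired differences are zero", call. = FALSE)
  }
  n <- length(d)
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !ties
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, n = n,
       exact = exact)
}
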