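#' Construct a gold standard of functional gene pairs
#'
#' Disjoint positive and negative unordered gene-pair sets used to
#' calibrate raw evidence scores into log-likelihood scores and to
#' benchmark networks.
#'
#' @param positives,negatives data frames with character columns
#'   `gene_a`, `gene_b` (self-pairs forbidden; the two sets must be
#'   disjoint).
#' @return An object of class `gold_standard` with canonical, deduplicated
#'   pair tables.
#' @seealso [derive_gold_standard()]
#' @export
gold_standard <- function(positives, negatives) {
  canon <- function(df) {
    if (nrow(df) == 0) {
      return(data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE))
    }
    a <- .assert_gene_ids(df$gene_a); b <- .assert_gene_ids(df$gene_b)
    if (any(a == b)) stop("self-pairs are not allowed", call. = FALSE)
    cp <- .canonical_pairs(a, b)
    key <- .pair_key(cp$gene_a, cp$gene_b)
    keep <- !duplicated(key)
    ord <- order(cp$gene_a[keep], cp$gene_b[keep])
    data.frame(gene_a = cp$gene_a[keep][ord], gene_b = cp$gene_b[keep][ord],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  pos <- canon(positives); neg <- canon(negatives)
  if (length(intersect(.pair_key(pos$gene_a, pos$gene_b),
                       .pair_key(neg$gene_a, neg$gene_b))) > 0) {
    stop("positive and negative pair sets overlap", call. = FALSE)
  }
  structure(list(positives = pos, negatives = neg), class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d positive, %d negative gene pairs\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

#' Derive a gold standard from functional annotations
#'
#' Positive pairs are all gene pairs co-annotated to at least one term
#' whose size (within the universe) lies in `[min_term, max_term]`;
#' negative pairs are all pairs of annotated genes sharing no
#' size-eligible term.  Terms outside the size bounds neither create
#' positives nor block negativity (very large terms are too unspecific
#' to certify co-functionality).  Pairs involving unannotated genes are
#' in neither set.
#'
#' @param ann an [annotation_set()].
#' @param min_term,max_term term-size bounds for eligible terms
#'   (defaults 3 and 500).
#' @param universe optional gene universe restricting the annotations
#'   (default: all annotated genes).
#' @return A [gold_standard()].
#' @export
derive_gold_standard <- function(ann, min_term = 3, max_term = 500,
                                 universe = NULL) {
  stopifnot(inherits(ann, "annotation_set"),
            min_term >= 1, min_term <= max_term)
  if (length(ann$genes) == 0) stop("empty annotation set", call. = FALSE)
  sets <- ann$genes
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, y = universe)
  }
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) {
    stop("no annotated genes within the universe", call. = FALSE)
  }
  annotated <- sort(unique(unlist(sets)))
  eligible <- sets[lengths(sets) >= min_term & lengths(sets) <= max_term]
  pos_a <- pos_b <- character(0)
  for (g in eligible) {
    if (length(g) < 2) next
    pr <- utils::combn(sort(g), 2)
    pos_a <- c(pos_a, pr[1, ]); pos_b <- c(pos_b, pr[2, ])
  }
  pos_key <- unique(.pair_key(pos_a, pos_b))
  # negatives: annotated pairs sharing no eligible term
  neg_a <- neg_b <- character(0)
  if (length(annotated) >= 2) {
    allp <- utils::combn(annotated, 2)
    key <- .pair_key(allp[1, ], allp[2, ])
    keep <- !(key %in% pos_key)
    neg_a <- allp[1, keep]; neg_b <- allp[2, keep]
  }
  first <- !duplicated(.pair_key(pos_a, pos_b))
  gold_standard(data.frame(gene_a = pos_a[first], gene_b = pos_b[first],
                           stringsAsFactors = FALSE),
                data.frame(gene_a = neg_a, gene_b = neg_b,
                           stringsAsFactors = FALSE))
}

# Label scored pairs against a gold standard: +1 positive, -1 negative,
# 0 unlabeled.  Works for scored_pairs and gene_network edge frames.
.gold_labels <- function(gene_a, gene_b, gold) {
  key <- .pair_key(gene_a, gene_b)
  lab <- integer(length(key))
  lab[key %in% .pair_key(gold$positives$gene_a, gold$positives$gene_b)] <- 1L
  lab[key %in% .pair_key(gold$negatives$gene_a, gold$negatives$gene_b)] <- -1L
  lab
}

#' Construct a calibration curve
#'
#' Raw-score bins with per-bin log-likelihood scores.  Usually produced
#' by [calibrate_lls()]; the constructor validates an existing curve.
#'
#' @param evidence_code evidence code the curve was fitted for.
#' @param bins data frame with columns `lower`, `upper`, `n_pos`,
#'   `n_neg`, `lls`, ordered by ascending raw score and non-overlapping.
#' @param prior_pos,prior_neg gold-standard totals among the scorable
#'   pairs the curve was fitted on.
#' @return An object of class `calibration_curve`.  Element `breaks`
#'   holds the internal bin boundaries used for score lookup.
#' @export
calibration_curve <- function(evidence_code, bins, prior_pos, prior_neg) {
  stopifnot(is.data.frame(bins),
            all(c("lower", "upper", "n_pos", "n_neg", "lls") %in% names(bins)),
            nrow(bins) >= 1, prior_pos >= 1, prior_neg >= 1)
  if (is.unsorted(bins$lower) || any(bins$upper < bins$lower)) {
    stop("bins must be ordered by ascending raw score", call. = FALSE)
  }
  if (nrow(bins) > 1 && any(bins$lower[-1] < bins$upper[-nrow(bins)])) {
    stop("bins must not overlap", call. = FALSE)
  }
  if (any(!is.finite(bins$lls))) stop("lls must be finite", call. = FALSE)
  breaks <- if (nrow(bins) > 1) {
    (bins$upper[-nrow(bins)] + bins$lower[-1]) / 2
  } else numeric(0)
  structure(list(evidence_code = evidence_code, bins = bins,
                 prior_pos = prior_pos, prior_neg = prior_neg,
                 breaks = breaks),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve[%s]: %d bins, priors %d pos / %d neg\n",
              x$evidence_code, nrow(x$bins), x$prior_pos, x$prior_neg))
  print(x$bins, digits = 4)
  invisible(x)
}

#' @export
plot.calibration_curve <- function(x, ...) {
  mid <- (x$bins$lower + x$bins$upper) / 2
  graphics::plot(mid, x$bins$lls, type = "b", pch = 16,
                 xlab = sprintf("raw %s score (bin midpoint)",
                                x$evidence_code),
                 ylab = "log-likelihood score (nats)", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Calibrate raw evidence scores into log-likelihood scores
#'
#' Benchmarks a raw scored pair set against a gold standard.  The
#' gold-labeled scorable pairs are sorted by raw score and cut into at
#' most `n_bins` equal-frequency bins (ties never split across bins),
#' merging bins from the top of the score range downwards until every
#' bin holds at least `min_bin_count` gold pairs.  Each bin receives
#'
#' \deqn{LLS = \ln\frac{P(L|E)/\neg P(L|E)}{P(L)/\neg P(L)}
#'           = \ln\frac{n_{pos}/n_{neg}}{prior_{pos}/prior_{neg}}}
#'
#' the log ratio of the bin's positive:negative odds to the prior odds
#' among all scorable gold pairs (in nats).  Add-one smoothing of the
#' bin counts is applied only when a bin has zero positives or zero
#' negatives.
#'
#' @param pairs a [scored_pairs()] set.
#' @param gold a [gold_standard()].
#' @param n_bins maximum number of bins (default 10).
#' @param min_bin_count minimum gold pairs per bin (default 10).
#' @return A [calibration_curve()].
#' @export
calibrate_lls <- function(pairs, gold, n_bins = 10, min_bin_count = 10) {
  stopifnot(inherits(pairs, "scored_pairs"), inherits(gold, "gold_standard"),
            n_bins >= 1, min_bin_count >= 1)
  lab <- .gold_labels(pairs$gene_a, pairs$gene_b, gold)
  sc <- pairs$score[lab != 0]
  lab <- lab[lab != 0]
  m <- length(sc)
  if (m < min_bin_count) {
    stop("insufficient gold-standard coverage: ", m,
         " scorable gold pairs (need >= ", min_bin_count, ")", call. = FALSE)
  }
  ord <- order(-sc)
  sc <- sc[ord]; lab <- lab[ord]
  # cut into <= n_bins equal-frequency chunks, keeping tied scores together
  target <- ceiling(m / n_bins)
  bin_id <- integer(m)
  bin <- 1L; count <- 0L
  for (i in seq_len(m)) {
    bin_id[i] <- bin
    count <- count + 1L
    if (count >= target && i < m && sc[i + 1] < sc[i] && bin < n_bins) {
      bin <- bin + 1L; count <- 0L
    }
  }
  # merge from the top until every bin holds >= min_bin_count gold pairs
  repeat {
    sizes <- table(bin_id)
    small <- as.integer(names(sizes))[sizes < min_bin_count]
    if (length(small) == 0) break
    b <- small[1]
    ids <- sort(unique(bin_id))
    nb <- if (b < max(ids)) min(ids[ids > b]) else max(ids[ids < b])
    bin_id[bin_id == b] <- nb
  }
  ids <- sort(unique(bin_id))           # descending-score order
  prior_pos <- sum(lab == 1); prior_neg <- sum(lab == -1)
  if (prior_pos == 0 || prior_neg == 0) {
    stop("gold-standard coverage lacks one class entirely", call. = FALSE)
  }
  rows <- lapply(ids, function(b) {
    in_bin <- bin_id == b
    n_pos <- sum(lab[in_bin] == 1); n_neg <- sum(lab[in_bin] == -1)
    if (n_pos == 0 || n_neg == 0) {    # Laplace add-one smoothing
      odds <- (n_pos + 1) / (n_neg + 1)
    } else {
      odds <- n_pos / n_neg
    }
    data.frame(lower = min(sc[in_bin]), upper = max(sc[in_bin]),
               n_pos = n_pos, n_neg = n_neg,
               lls = log(odds / (prior_pos / prior_neg)))
  })
  bins <- do.call(rbind, rev(rows))    # ascending raw-score order
  calibration_curve(evidence_code(pairs), bins, prior_pos, prior_neg)
}

#' Apply a calibration curve to raw scores
#'
#' Every pair (gold-labeled or not) receives the log-likelihood score of
#' the bin containing its raw score; scores below the lowest bin take
#' the lowest bin's LLS and scores above the highest take the highest.
#' Edges with `LLS <= 0` carry no positive evidence of co-functionality
#' and are dropped.
#'
#' @param pairs a [scored_pairs()] set with the curve's evidence code.
#' @param curve a [calibration_curve()].
#' @return A [gene_network()] whose edge weights are LLS values (nats).
#' @export
apply_calibration <- function(pairs, curve) {
  stopifnot(inherits(pairs, "scored_pairs"),
            inherits(curve, "calibration_curve"))
  if (nrow(curve$bins) == 0) stop("empty calibration curve", call. = FALSE)
  if (!identical(evidence_code(pairs), curve$evidence_code)) {
    stop(sprintf("curve was fitted for %s but pairs carry %s evidence",
                 curve$evidence_code, evidence_code(pairs)), call. = FALSE)
  }
  idx <- findInterval(pairs$score, curve$breaks) + 1L
  lls <- curve$bins$lls[idx]
  keep <- lls > 0
  gene_network(data.frame(gene_a = pairs$gene_a[keep],
                          gene_b = pairs$gene_b[keep],
                          weight = lls[keep], stringsAsFactors = FALSE))
}

#' Write a calibration curve as TSV
#' @param curve a [calibration_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  b <- curve$bins
  lines <- c(sprintf("# evidence_code: %s", curve$evidence_code),
             sprintf("# prior_pos: %d", curve$prior_pos),
             sprintf("# prior_neg: %d", curve$prior_neg),
             "lower\tupper\tn_pos\tn_neg\tlls",
             paste(.fmt_num(b$lower), .fmt_num(b$upper), b$n_pos, b$n_neg,
                   .fmt_num(b$lls), sep = "\t"))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a calibration curve from TSV
#' @param path path written by [write_calibration_curve()].
#' @return A [calibration_curve()].
#' @export
read_calibration_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- function(k) sub(sprintf("^#\\s*%s:\\s*", k), "",
                          grep(sprintf("^#\\s*%s:", k), lines, value = TRUE)[1])
  tf <- .read_tsv_fields(path)
  body <- tf$fields[-1]  # drop column header
  bins <- do.call(rbind, lapply(body, function(f) {
    data.frame(lower = as.numeric(f[1]), upper = as.numeric(f[2]),
               n_pos = as.integer(f[3]), n_neg = as.integer(f[4]),
               lls = as.numeric(f[5]))
  }))
  calibration_curve(meta("evidence_code"), bins,
                    as.integer(meta("prior_pos")),
                    as.integer(meta("prior_neg")))
}

#' Integration parameters for the weighted sum
#'
#' @param D degradation divisor (`>= 1`): how fast lower-ranked
#'   component scores are discounted.
#' @param T minimum component LLS admitted into the sum (nats).
#' @return An object of class `integration_params`.
#' @export
integration_params <- function(D = 1, T = 0) {
  stopifnot(is.numeric(D), length(D) == 1, is.finite(D), D >= 1,
            is.numeric(T), length(T) == 1, is.finite(T))
  structure(list(D = D, T = T), class = "integration_params")
}

#' @export
print.integration_params <- function(x, ...) {
  cat(sprintf("integration_params: D = %g, T = %g\n", x$D, x$T))
  invisible(x)
}

#' Integrate component networks by rank-discounted weighted sum
#'
#' For each gene pair, the component LLS values `>= T` are sorted in
#' descending order \eqn{L_0 \ge L_1 \ge \dots} and combined as
#' \deqn{WS = L_0 + \sum_{i \ge 1} \frac{L_i}{D \cdot i}}
#' a modified naive-Bayes sum in which agreement between evidence types
#' always helps but is discounted by rank to absorb their correlation.
#' Pairs with no component passing `T` are absent from the result.
#' Component exclusion (e.g. dropping a potentially circular evidence
#' type) is done by passing a subset of `nets`.
#'
#' @param nets list of component [gene_network()]s (LLS-weighted).
#' @param params an [integration_params()].
#' @return The integrated [gene_network()].
#' @export
integrate_weighted_sum <- function(nets, params = integration_params()) {
  if (inherits(nets, "gene_network")) nets <- list(nets)
  stopifnot(length(nets) >= 1, all(vapply(nets, inherits, logical(1),
                                          "gene_network")),
            inherits(params, "integration_params"))
  ed <- do.call(rbind, lapply(nets, function(n) n$edges))
  ed <- ed[ed$weight >= params$T, , drop = FALSE]
  if (nrow(ed) == 0) return(gene_network())
  key <- .pair_key(ed$gene_a, ed$gene_b)
  ord <- order(key, -ed$weight)
  ed <- ed[ord, , drop = FALSE]; key <- key[ord]
  rank_in_pair <- stats::ave(ed$weight, key, FUN = seq_along)
  contrib <- ifelse(rank_in_pair == 1, ed$weight,
                    ed$weight / (params$D * (rank_in_pair - 1)))
  ws <- rowsum(contrib, key, reorder = FALSE)
  first <- !duplicated(key)
  gene_network(data.frame(gene_a = ed$gene_a[first],
                          gene_b = ed$gene_b[first],
                          weight = as.numeric(ws[, 1]),
                          stringsAsFactors = FALSE))
}

#' Choose integration parameters by grid search
#'
#' Evaluates every `(D, T)` combination by the precision-recall AUC
#' (average precision, see [pr_auc()]) of the integrated network against
#' a gold standard, and returns the maximizer.  Ties break toward larger
#' `D`, then larger `T`, so the least aggressive integration compatible
#' with the best benchmark wins; the search is deterministic.
#'
#' @param nets list of component [gene_network()]s.
#' @param gold a [gold_standard()].
#' @param D_grid,T_grid numeric grids of candidate values.
#' @return The selected [integration_params()], with the grid of scores
#'   attached as attribute `"grid"`.
#' @export
optimize_integration_params <- function(nets, gold,
                                        D_grid = c(1, 1.5, 2, 4),
                                        T_grid = c(0, 0.5, 1, 1.5)) {
  stopifnot(length(D_grid) >= 1, length(T_grid) >= 1)
  grid <- expand.grid(D = sort(D_grid), T = sort(T_grid))
  grid$pr_auc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    net <- integrate_weighted_sum(nets, integration_params(grid$D[i],
                                                           grid$T[i]))
    if (nrow(net$edges) == 0) next
    lab <- .gold_labels(net$edges$gene_a, net$edges$gene_b, gold)
    if (!any(lab == 1)) next
    grid$pr_auc[i] <- pr_auc(net, gold)
  }
  if (all(is.na(grid$pr_auc))) {
    stop("gold standard not scorable by any component network",
         call. = FALSE)
  }
  best <- max(grid$pr_auc, na.rm = TRUE)
  cand <- grid[!is.na(grid$pr_auc) & grid$pr_auc >= best - 1e-12, ]
  cand <- cand[order(-cand$D, -cand$T), ]
  out <- integration_params(cand$D[1], cand$T[1])
  attr(out, "grid") <- grid
  out
}
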