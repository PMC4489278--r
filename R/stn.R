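# Spatiotemporal-specific networks (STNs): context-restricted
# subnetworks of the integrated network, one per developmental stage or
# tissue type, built from expression evidence.

#' Build spatiotemporal-specific networks
#'
#' For every context (stage or tissue) in the expression bundle, a gene
#' is considered expressed iff its mean value over the context's samples
#' exceeds `threshold` (BPKM > 1 by default); an edge of the parent
#' network is retained iff both endpoints are expressed.  Genes absent
#' from the expression matrix are treated as not expressed (reported in
#' a message).
#'
#' @param net the parent [gene_network()].
#' @param bundle an [expression_bundle()] whose contexts define the
#'   STNs.
#' @param threshold expression cutoff (default 1).
#' @return An object of class `stn_set`: `contexts` (data frame `label`,
#'   `kind`, `n_samples`, `n_genes`, `n_links`), `networks` (named list
#'   of [gene_network()]s), `threshold`.
#' @export
build_stns <- function(net, bundle, threshold = 1) {
  stopifnot(inherits(net, "gene_network"),
            inherits(bundle, "expression_bundle"),
            is.numeric(threshold), length(threshold) == 1)
  cx <- unique(bundle$contexts[, c("label", "kind")])
  if (nrow(cx) == 0) stop("no contexts in the expression bundle", call. = FALSE)
  cx <- cx[order(match(cx$kind, c("stage", "tissue")), cx$label), ,
           drop = FALSE]
  unmeasured <- setdiff(net$genes, rownames(bundle$matrix))
  if (length(unmeasured) > 0) {
    message(length(unmeasured),
            " networked gene(s) absent from the expression matrix are ",
            "treated as not expressed")
  }
  networks <- vector("list", nrow(cx))
  names(networks) <- cx$label
  n_samples <- integer(nrow(cx))
  for (i in seq_len(nrow(cx))) {
    samples <- bundle$contexts$sample[bundle$contexts$label == cx$label[i]]
    if (length(samples) == 0) {
      stop("context '", cx$label[i], "' has no samples", call. = FALSE)
    }
    n_samples[i] <- length(samples)
    mean_expr <- rowMeans(bundle$matrix[, samples, drop = FALSE])
    expressed <- rownames(bundle$matrix)[mean_expr > threshold]
    ed <- net$edges
    keep <- ed$gene_a %in% expressed & ed$gene_b %in% expressed
    networks[[i]] <- gene_network(ed[keep, , drop = FALSE])
  }
  contexts <- data.frame(label = cx$label, kind = cx$kind,
                         n_samples = n_samples,
                         n_genes = vapply(networks, function(n)
                           length(n$genes), integer(1)),
                         n_links = vapply(networks, function(n)
                           nrow(n$edges), integer(1)),
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(contexts = contexts, networks = networks,
                 threshold = threshold),
            class = "stn_set")
}

#' @export
print.stn_set <- function(x, ...) {
  cat(sprintf("stn_set: %d spatiotemporal networks (threshold > %g)\n",
              nrow(x$contexts), x$threshold))
  print(x$contexts)
  invisible(x)
}

#' STN neighbor-count profiles
#'
#' Counts, for each input gene, its number of network neighbors in
#' every STN, plus an aggregate row with the number of *unique*
#' neighbors of any input gene per context.  The log view is
#' `log10(count + 1)`.  The context with the largest aggregate count is
#' reported per context kind (e.g. the most enriched tissue type),
#' pointing to the spatiotemporal context in which the gene set is most
#' active.
#'
#' @param stns a [build_stns()] result.
#' @param genes character vector of gene ids (e.g. guides and top
#'   candidates).
#' @return An object of class `stn_counts`: `counts` and `log_counts`
#'   (gene x context matrices with an `"[set]"` aggregate row) and
#'   `top_context` (named character vector, one context label per kind).
#' @export
stn_neighbor_counts <- function(stns, genes) {
  stopifnot(inherits(stns, "stn_set"))
  genes <- unique(as.character(genes))
  labels <- stns$contexts$label
  counts <- matrix(0L, nrow = length(genes) + 1L, ncol = length(labels),
                   dimnames = list(c(genes, "[set]"), labels))
  for (j in seq_along(labels)) {
    ed <- stns$networks[[labels[j]]]$edges
    uniq <- character(0)
    for (i in seq_along(genes)) {
      nb <- c(ed$gene_b[ed$gene_a == genes[i]],
              ed$gene_a[ed$gene_b == genes[i]])
      counts[i, j] <- length(nb)
      uniq <- c(uniq, nb)
    }
    counts[length(genes) + 1L, j] <- length(unique(uniq))
  }
  agg <- counts["[set]", ]
  top_context <- vapply(unique(stns$contexts$kind), function(k) {
    lab <- stns$contexts$label[stns$contexts$kind == k]
    lab[which.max(agg[lab])]
  }, character(1))
  structure(list(counts = counts, log_counts = log10(counts + 1),
                 top_context = top_context),
            class = "stn_counts")
}

#' @export
print.stn_counts <- function(x, n = 10, ...) {
  cat("stn_counts: neighbor counts across",
      ncol(x$counts), "spatiotemporal networks\n")
  print(utils::head(x$counts, n))
  if (nrow(x$counts) > n) cat("  ...\n")
  cat("most enriched context per kind:",
      paste(names(x$top_context), x$top_context, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Context-specific network links
#'
#' Reports the edges present in exactly one context of their kind
#' (e.g. links found in a single tissue's STN and no other tissue),
#' an optional view of spatiotemporal specificity at the link level.
#'
#' @param stns a [build_stns()] result.
#' @return Data frame (`gene_a`, `gene_b`, `weight`, `label`, `kind`)
#'   of edges specific to a single context of their kind.
#' @export
stn_specific_links <- function(stns) {
  stopifnot(inherits(stns, "stn_set"))
  out <- list()
  for (k in unique(stns$contexts$kind)) {
    labels <- stns$contexts$label[stns$contexts$kind == k]
    keys <- lapply(labels, function(l) {
      ed <- stns$networks[[l]]$edges
      .pair_key(ed$gene_a, ed$gene_b)
    })
    tab <- table(unlist(keys))
    once <- names(tab)[tab == 1]
    for (i in seq_along(labels)) {
      ed <- stns$networks[[labels[i]]]$edges
      keep <- .pair_key(ed$gene_a, ed$gene_b) %in% once
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          ed[keep, , drop = FALSE], label = labels[i], kind = k,
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), label = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
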