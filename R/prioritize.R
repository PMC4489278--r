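# Gene, function and disease prioritization on a functional gene
# network, guided by user-supplied guide genes.

#' Direct-neighborhood scores
#'
#' Scores every networked gene by the sum of its edge weights (LLS) to
#' the guide genes.  A guide's own score sums its edges to the *other*
#' guides (self excluded); genes with no edge to a guide score 0.
#'
#' @param net a [gene_network()].
#' @param guides character vector of guide gene ids; guides absent from
#'   the network are reported in a message and ignored.
#' @return Named numeric vector of scores over all networked genes.
#' @export
score_direct_neighborhood <- function(net, guides) {
  stopifnot(inherits(net, "gene_network"))
  guides <- unique(as.character(guides))
  present <- intersect(guides, net$genes)
  if (length(present) == 0) {
    stop("no guide gene present in the network; missing: ",
         paste(guides, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(guides, present)
  if (length(absent) > 0) {
    message("ignoring ", length(absent), " guide(s) absent from the network: ",
            paste(absent, collapse = ", "))
  }
  ed <- net$edges
  score <- stats::setNames(numeric(length(net$genes)), net$genes)
  a_is_guide <- ed$gene_a %in% present
  b_is_guide <- ed$gene_b %in% present
  # each edge contributes to the non-guide (or other-guide) endpoint
  inc_b <- rowsum(ed$weight[a_is_guide], ed$gene_b[a_is_guide])
  inc_a <- rowsum(ed$weight[b_is_guide], ed$gene_a[b_is_guide])
  if (length(inc_b) > 0) score[rownames(inc_b)] <-
    score[rownames(inc_b)] + inc_b[, 1]
  if (length(inc_a) > 0) score[rownames(inc_a)] <-
    score[rownames(inc_a)] + inc_a[, 1]
  score
}

#' Network-diffusion (label propagation) scores
#'
#' Propagates guide-gene labels over the whole network by Gaussian-field
#' label propagation on the symmetrically normalized weight matrix: with
#' `W` the edge-weight matrix, `S = Dg^{-1/2} W Dg^{-1/2}` (`Dg` the
#' diagonal of weighted degrees) and `y` the 0/1 guide indicator, the
#' score vector solves `(I - alpha S) f = y`.  Solved exactly (sparse
#' LU) or by the fixed-point iteration `f <- alpha S f + y` to a maximum
#' residual below `tol`.
#'
#' @param net a [gene_network()].
#' @param guides character vector of guide gene ids (absent guides are
#'   ignored with a message; an empty effective guide set is an error).
#' @param alpha propagation strength in (0, 1); default 0.9.
#' @param tol iteration residual tolerance (default 1e-8).
#' @param method `"exact"`, `"iterative"`, or `"auto"` (exact up to
#'   2000 nodes).
#' @return Named numeric vector of diffusion scores over all networked
#'   genes.
#' @export
score_network_diffusion <- function(net, guides, alpha = 0.9, tol = 1e-8,
                                    method = c("auto", "exact", "iterative")) {
  stopifnot(inherits(net, "gene_network"), alpha > 0, alpha < 1, tol > 0)
  method <- match.arg(method)
  guides <- unique(as.character(guides))
  present <- intersect(guides, net$genes)
  if (length(present) == 0 && length(guides) > 0) {
    stop("no guide gene present in the network; missing: ",
         paste(guides, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(guides, present)
  if (length(absent) > 0) {
    message("ignoring ", length(absent), " guide(s) absent from the network: ",
            paste(absent, collapse = ", "))
  }
  genes <- net$genes
  n <- length(genes)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  ed <- net$edges
  i <- match(ed$gene_a, genes); j <- match(ed$gene_b, genes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = c(ed$weight, ed$weight), dims = c(n, n))
  deg <- Matrix::rowSums(W)
  if (any(deg[match(present, genes)] == 0)) {
    warning("isolated guide(s) with zero weighted degree retain only ",
            "their own label", call. = FALSE)
  }
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- Matrix::Diagonal(n, dinv) %*% W %*% Matrix::Diagonal(n, dinv)
  y <- as.numeric(genes %in% present)
  if (method == "auto") method <- if (n <= 2000) "exact" else "iterative"
  if (method == "exact") {
    f <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - alpha * S, y))
  } else {
    f <- y
    repeat {
      f_new <- as.numeric(alpha * (S %*% f)) + y
      if (max(abs(f_new - f)) < tol) { f <- f_new; break }
      f <- f_new
    }
  }
  stats::setNames(f, genes)
}

#' Prioritize genes against a guide set
#'
#' Ranks every networked gene by its association with the guide genes
#' under the chosen algorithm (descending score, ties broken by gene
#' id), and measures the retrieval power for the guide genes themselves
#' as a ROC AUC (guides as positives, all other networked genes as
#' negatives) to gauge how predictable the trait is.
#'
#' @param net a [gene_network()].
#' @param guides character vector of guide gene ids.
#' @param algorithm `"direct"` (sum of edge weights to guides) or
#'   `"diffusion"` (Gaussian-field label propagation).
#' @param stns optional [build_stns()] result; when supplied, the STN
#'   neighbor-count matrix for the guides and the top candidates is
#'   attached (element `stn_counts`).
#' @param alpha,tol diffusion parameters (see
#'   [score_network_diffusion()]).
#' @param stn_top number of top candidates included in the STN count
#'   matrix (default 50).
#' @return An object of class `prioritization_result`: `records` (data
#'   frame `gene`, `score`, `rank`, `is_guide`), `candidates` (non-guide
#'   genes in rank order), `auc`, `algorithm`, and optionally
#'   `stn_counts`.
#' @export
prioritize_genes <- function(net, guides, algorithm = c("direct", "diffusion"),
                             stns = NULL, alpha = 0.9, tol = 1e-8,
                             stn_top = 50) {
  algorithm <- match.arg(algorithm)
  guides <- unique(as.character(guides))
  score <- switch(algorithm,
    direct = score_direct_neighborhood(net, guides),
    diffusion = score_network_diffusion(net, guides, alpha = alpha, tol = tol))
  genes <- names(score)
  ord <- order(-score, genes)
  records <- data.frame(gene = genes[ord], score = as.numeric(score[ord]),
                        rank = seq_along(ord),
                        is_guide = genes[ord] %in% guides,
                        stringsAsFactors = FALSE, row.names = NULL)
  pos <- genes[genes %in% guides]
  neg <- setdiff(genes, guides)
  auc <- if (length(pos) > 0 && length(neg) > 0) {
    roc_auc(score, pos, neg)
  } else NA_real_
  res <- structure(list(algorithm = algorithm, records = records,
                        candidates = records$gene[!records$is_guide],
                        guides = intersect(guides, genes), auc = auc),
                   class = "prioritization_result")
  if (!is.null(stns)) {
    stopifnot(inherits(stns, "stn_set"))
    show <- c(res$guides, utils::head(res$candidates, stn_top))
    res$stn_counts <- stn_neighbor_counts(stns, show)
  }
  res
}

#' @export
print.prioritization_result <- function(x, n = 10, ...) {
  cat(sprintf("prioritization_result (%s): %d genes, %d guides, AUC = %s\n",
              x$algorithm, nrow(x$records), length(x$guides),
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  print(utils::head(x$records, n))
  if (nrow(x$records) > n) cat("  ...\n")
  invisible(x)
}

#' Prioritize functional terms for a query gene
#'
#' Ranks annotation terms by the sum of the network edge weights (LLS)
#' from the query gene to its neighbors annotated with each term.
#' Annotations of the query itself do not contribute; terms with score 0
#' are omitted; output is ordered by descending score, ties by term id.
#'
#' @param net a [gene_network()].
#' @param query a single gene id present in the network.
#' @param ann an [annotation_set()].
#' @return Data frame (`term`, `description`, `source`, `score`,
#'   `n_neighbors`) in rank order.
#' @export
prioritize_functions <- function(net, query, ann) {
  stopifnot(inherits(net, "gene_network"), inherits(ann, "annotation_set"),
            length(query) == 1)
  query <- as.character(query)
  if (!query %in% net$genes) {
    stop("query gene '", query, "' absent from the network", call. = FALSE)
  }
  ed <- net$edges
  nb <- rbind(
    data.frame(gene = ed$gene_b[ed$gene_a == query],
               w = ed$weight[ed$gene_a == query], stringsAsFactors = FALSE),
    data.frame(gene = ed$gene_a[ed$gene_b == query],
               w = ed$weight[ed$gene_b == query], stringsAsFactors = FALSE))
  terms <- names(ann$genes)
  score <- vapply(terms, function(t) {
    sum(nb$w[nb$gene %in% ann$genes[[t]]])
  }, numeric(1))
  n_nb <- vapply(terms, function(t) sum(nb$gene %in% ann$genes[[t]]),
                 numeric(1))
  keep <- score > 0
  out <- data.frame(term = terms[keep],
                    description = as.character(ann$description[terms[keep]]),
                    source = as.character(ann$source[terms[keep]]),
                    score = score[keep], n_neighbors = as.integer(n_nb[keep]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$score, out$term), , drop = FALSE]
}

#' Prioritize disease genes across species by orthology
#'
#' Runs the network prioritizer in the network's (model-organism)
#' namespace for guide genes supplied in either namespace.  Guides given
#' in the disease (e.g. human) namespace are mapped to the union of
#' their model-organism orthologs; ranked candidate genes are mapped
#' back for reporting.  When support genes (e.g. GWAS or de novo
#' mutation hits) are supplied, candidates are split into a first tier
#' (candidates intersecting the support set: backed by both network and
#' genetic evidence) and a second tier (all ranked candidates).
#'
#' @param net a model-organism [gene_network()].
#' @param omap an [ortholog_map()] with `source` = disease-namespace
#'   ids and `target` = network-namespace ids.
#' @param guides character vector of guide gene ids.
#' @param namespace namespace of `guides`: `"network"` (already in the
#'   network's namespace) or `"disease"` (mapped through `omap`).
#' @param support optional character vector of support genes in the
#'   disease namespace.
#' @param algorithm,alpha,tol passed to [prioritize_genes()].
#' @return An object of class `tiered_candidates`: `first_tier` and
#'   `second_tier` (ordered disease-namespace gene lists, first tier a
#'   subset of the second), `support_genes_used`, `mapping` (candidate
#'   mapping table), and `result` (the underlying
#'   [prioritize_genes()] output in the network namespace).
#' @export
prioritize_disease <- function(net, omap, guides,
                               namespace = c("disease", "network"),
                               support = NULL,
                               algorithm = c("direct", "diffusion"),
                               alpha = 0.9, tol = 1e-8) {
  stopifnot(inherits(net, "gene_network"), inherits(omap, "ortholog_map"))
  namespace <- match.arg(namespace)
  algorithm <- match.arg(algorithm)
  guides <- unique(as.character(guides))
  if (namespace == "disease") {
    mapped <- omap$pairs$target[omap$pairs$source %in% guides]
    unmapped <- setdiff(guides, omap$pairs$source)
    if (length(unmapped) > 0) {
      message("ignoring ", length(unmapped),
              " guide(s) with no ortholog: ",
              paste(unmapped, collapse = ", "))
    }
    net_guides <- unique(mapped)
    if (length(net_guides) == 0) {
      stop("no guide gene maps to the network namespace", call. = FALSE)
    }
  } else {
    net_guides <- guides
  }
  res <- prioritize_genes(net, net_guides, algorithm = algorithm,
                          alpha = alpha, tol = tol)
  # map candidates back to the disease namespace, keeping rank order;
  # a disease gene inherits the rank of its best network candidate
  back <- split(omap$pairs$source, omap$pairs$target)
  rows <- lapply(seq_along(res$candidates), function(i) {
    d <- back[[res$candidates[i]]]
    if (is.null(d)) return(NULL)
    data.frame(disease_gene = d, network_gene = res$candidates[i],
               network_rank = i, stringsAsFactors = FALSE)
  })
  mapping <- do.call(rbind, rows)
  if (is.null(mapping)) {
    mapping <- data.frame(disease_gene = character(),
                          network_gene = character(),
                          network_rank = integer(), stringsAsFactors = FALSE)
  }
  mapping <- mapping[!duplicated(mapping$disease_gene), , drop = FALSE]
  second_tier <- mapping$disease_gene
  support <- unique(as.character(support))
  first_tier <- second_tier[second_tier %in% support]
  structure(list(first_tier = first_tier, second_tier = second_tier,
                 support_genes_used = support, mapping = mapping,
                 result = res),
            class = "tiered_candidates")
}

#' @export
print.tiered_candidates <- function(x, n = 10, ...) {
  cat(sprintf(
    "tiered_candidates: %d first-tier / %d second-tier (support: %d genes)\n",
    length(x$first_tier), length(x$second_tier),
    length(x$support_genes_used)))
  cat("top second-tier:", paste(utils::head(x$second_tier, n),
                                collapse = ", "), "\n")
  if (length(x$first_tier) > 0) {
    cat("top first-tier: ", paste(utils::head(x$first_tier, n),
                                  collapse = ", "), "\n")
  }
  invisible(x)
}
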