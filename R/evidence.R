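#' Construct a scored pair set
#'
#' Raw (uncalibrated) co-functionality scores for unordered gene pairs
#' from one evidence type.  Scores are evidence-specific (higher =
#' stronger evidence) and are re-mapped to log-likelihood scores by
#' [calibrate_lls()]/[apply_calibration()]; they only need to be
#' monotone in evidence strength.
#'
#' @param gene_a,gene_b character vectors of gene ids (no self-pairs).
#' @param score finite numeric raw scores.
#' @param code evidence code, one of `"CC"` (co-citation), `"CX"`
#'   (co-expression), `"DC"` (domain co-occurrence), `"GN"` (gene
#'   neighborhood), `"PG"` (phylogenetic profile), `"HT"`
#'   (high-throughput PPI), `"LC"` (literature-curated PPI), `"XFER"`
#'   (orthology transfer).
#' @return An object of class `scored_pairs`: a data frame
#'   (`gene_a`, `gene_b`, `score`) in canonical pair order with
#'   attribute `evidence_code`; duplicates collapse keeping the maximum
#'   score.
#' @export
scored_pairs <- function(gene_a = character(), gene_b = character(),
                         score = numeric(), code = "CX") {
  code <- match.arg(code, c("CC", "CX", "DC", "GN", "PG", "HT", "LC", "XFER"))
  gene_a <- .assert_gene_ids(gene_a)
  gene_b <- .assert_gene_ids(gene_b)
  score <- as.numeric(score)
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(score))
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  if (any(gene_a == gene_b)) stop("self-pairs are not allowed", call. = FALSE)
  cp <- .canonical_pairs(gene_a, gene_b)
  key <- .pair_key(cp$gene_a, cp$gene_b)
  if (anyDuplicated(key)) {
    s <- tapply(score, key, max)
    first <- !duplicated(key)
    cp$gene_a <- cp$gene_a[first]; cp$gene_b <- cp$gene_b[first]
    score <- as.numeric(s[.pair_key(cp$gene_a, cp$gene_b)])
  }
  ord <- order(-score, cp$gene_a, cp$gene_b)
  structure(data.frame(gene_a = cp$gene_a[ord], gene_b = cp$gene_b[ord],
                       score = score[ord], stringsAsFactors = FALSE,
                       row.names = NULL),
            evidence_code = code, class = c("scored_pairs", "data.frame"))
}

#' @export
print.scored_pairs <- function(x, ...) {
  cat(sprintf("scored_pairs[%s]: %d pairs\n", evidence_code(x), nrow(x)))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Evidence code of a scored pair set
#' @param pairs a [scored_pairs()] object.
#' @return The evidence code string.
#' @export
evidence_code <- function(pairs) attr(pairs, "evidence_code")

#' Co-expression evidence (Pearson correlation)
#'
#' Scores every gene pair within one expression data set by the Pearson
#' correlation coefficient of their expression profiles.  Zero-variance
#' genes are excluded; pairs with undefined correlation are omitted.
#' When several independent expression series are available, call this
#' once per series and calibrate each resulting set separately.
#'
#' @param bundle an [expression_bundle()] (one data set).
#' @param min_samples minimum number of samples required (default 4).
#' @return [scored_pairs()] with code `"CX"`; scores in `[-1, 1]`
#'   (negative correlations are retained and left for calibration to
#'   down-weight).
#' @export
infer_coexpression <- function(bundle, min_samples = 4) {
  stopifnot(inherits(bundle, "expression_bundle"))
  m <- bundle$matrix
  if (ncol(m) < min_samples) {
    stop(sprintf("need >= %d samples, got %d", min_samples, ncol(m)),
         call. = FALSE)
  }
  v <- apply(m, 1, stats::var)
  m <- m[v > 0, , drop = FALSE]
  if (nrow(m) < 2) {
    warning("fewer than 2 variable genes; empty co-expression set",
            call. = FALSE)
    return(scored_pairs(code = "CX"))
  }
  cc <- stats::cor(t(m))
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  r <- cc[ut]
  ok <- is.finite(r)
  scored_pairs(rownames(m)[ut[ok, 1]], rownames(m)[ut[ok, 2]], r[ok],
               code = "CX")
}

#' Construct a gene-to-document incidence table
#'
#' @param gene_docs named list: gene id -> character vector of document
#'   ids (e.g. PubMed ids) mentioning the gene.
#' @param corpus_size total number of documents in the corpus; must be
#'   at least the number of distinct listed documents.
#' @return An object of class `doc_incidence`.
#' @export
doc_incidence <- function(gene_docs, corpus_size) {
  stopifnot(is.list(gene_docs), length(names(gene_docs)) == length(gene_docs))
  gene_docs <- lapply(gene_docs, function(d) unique(as.character(d)))
  n_distinct <- length(unique(unlist(gene_docs)))
  corpus_size <- as.integer(corpus_size)
  if (corpus_size < n_distinct) {
    stop("corpus_size smaller than the number of distinct documents",
         call. = FALSE)
  }
  structure(list(gene_docs = gene_docs, corpus_size = corpus_size),
            class = "doc_incidence")
}

# Shared hypergeometric overlap scoring for co-citation and domain
# co-occurrence: -log10 upper-tail P(overlap >= observed) given the two
# set sizes and the universe size.  Computed on the log scale so large
# overlaps never overflow to Inf.
.hypergeom_overlap_scores <- function(sets, universe_size, min_count,
                                      code, what) {
  sizes <- lengths(sets)
  if (universe_size < max(sizes, 0)) {
    stop(sprintf("universe (%d) smaller than a gene's %s count (%d)",
                 universe_size, what, max(sizes)), call. = FALSE)
  }
  sets <- sets[sizes >= min_count]
  if (length(sets) < 2) return(scored_pairs(code = code))
  items <- sort(unique(unlist(sets)))
  inc <- vapply(sets, function(s) as.numeric(items %in% s),
                numeric(length(items)))
  inc <- matrix(inc, nrow = length(items),
                dimnames = list(items, names(sets)))
  ov <- crossprod(inc)                      # pairwise overlap counts
  sz <- lengths(sets)
  ut <- which(upper.tri(ov), arr.ind = TRUE)
  k <- ov[ut]
  keep <- k > 0
  ut <- ut[keep, , drop = FALSE]; k <- k[keep]
  if (length(k) == 0) return(scored_pairs(code = code))
  K1 <- sz[ut[, 1]]; K2 <- sz[ut[, 2]]
  logp <- stats::phyper(k - 1, K1, universe_size - K1, K2,
                        lower.tail = FALSE, log.p = TRUE)
  scored_pairs(names(sets)[ut[, 1]], names(sets)[ut[, 2]],
               -logp / log(10), code = code)
}

#' Co-citation evidence (hypergeometric document overlap)
#'
#' Scores a gene pair by `-log10` of the hypergeometric upper-tail
#' probability of observing at least the actual overlap between the two
#' genes' document sets, given each gene's document count and the corpus
#' size.  Pairs with zero overlap are omitted.
#'
#' @param docs a [doc_incidence()].
#' @param min_docs minimum documents per scored gene (default 2).
#' @return [scored_pairs()] with code `"CC"`; scores `>= 0`.
#' @export
infer_cocitation <- function(docs, min_docs = 2) {
  stopifnot(inherits(docs, "doc_incidence"))
  .hypergeom_overlap_scores(docs$gene_docs, docs$corpus_size, min_docs,
                            "CC", "document")
}

#' Construct a phylogenetic profile matrix
#'
#' @param matrix binary (0/1) gene x reference-genome matrix with row and
#'   column names; at least 2 genomes.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- sprintf("G%02d", seq_len(ncol(matrix)))
  }
  if (ncol(matrix) < 2) stop("need >= 2 reference genomes", call. = FALSE)
  if (!all(matrix %in% c(0, 1))) {
    stop("profile entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(matrix) <- "double"
  structure(list(matrix = matrix), class = "profile_matrix")
}

#' Phylogenetic profile evidence (mutual information)
#'
#' Scores a gene pair by the mutual information (in bits) between their
#' binary presence/absence profiles across reference genomes.  Genes
#' with a degenerate (all-present or all-absent) profile are excluded.
#'
#' @param profiles a [profile_matrix()].
#' @return [scored_pairs()] with code `"PG"`; scores `>= 0` (pairs with
#'   exactly factorizing joint distribution score 0 and are retained).
#' @export
infer_phylo_profile <- function(profiles) {
  stopifnot(inherits(profiles, "profile_matrix"))
  m <- profiles$matrix
  G <- ncol(m)
  rs <- rowSums(m)
  m <- m[rs > 0 & rs < G, , drop = FALSE]
  if (nrow(m) < 2) return(scored_pairs(code = "PG"))
  K <- rowSums(m)
  n11 <- tcrossprod(m)
  ut <- which(upper.tri(n11), arr.ind = TRUE)
  a <- n11[ut]                     # both present
  b <- K[ut[, 1]] - a              # i present, j absent
  cc <- K[ut[, 2]] - a             # j present, i absent
  d <- G - a - b - cc              # both absent
  plogp <- function(n, r, c) {
    out <- numeric(length(n))
    pos <- n > 0
    out[pos] <- (n[pos] / G) * log2(n[pos] * G / (r[pos] * c[pos]))
    out
  }
  ri <- K[ut[, 1]]; rj <- K[ut[, 2]]
  mi <- plogp(a, ri, rj) + plogp(b, ri, G - rj) +
    plogp(cc, G - ri, rj) + plogp(d, G - ri, G - rj)
  mi <- pmax(mi, 0)  # clip tiny negative rounding residue
  scored_pairs(rownames(m)[ut[, 1]], rownames(m)[ut[, 2]], mi, code = "PG")
}

#' Construct a protein domain table
#'
#' @param gene_domains named list: gene id -> character vector of domain
#'   ids (non-empty sets only).
#' @param universe_size total number of distinct domains in the domain
#'   universe.
#' @return An object of class `domain_table`.
#' @export
domain_table <- function(gene_domains, universe_size) {
  stopifnot(is.list(gene_domains),
            length(names(gene_domains)) == length(gene_domains))
  gene_domains <- lapply(gene_domains, function(d) unique(as.character(d)))
  if (any(lengths(gene_domains) == 0)) {
    stop("every gene must have at least one domain", call. = FALSE)
  }
  universe_size <- as.integer(universe_size)
  if (universe_size < length(unique(unlist(gene_domains)))) {
    stop("universe_size smaller than the number of distinct domains",
         call. = FALSE)
  }
  structure(list(gene_domains = gene_domains,
                 universe_size = universe_size),
            class = "domain_table")
}

#' Domain co-occurrence evidence (hypergeometric domain overlap)
#'
#' Scores a gene pair by `-log10` of the hypergeometric upper-tail
#' probability of sharing at least the observed number of protein
#' domains, given each gene's domain count and the domain universe size.
#' Pairs sharing no domain are omitted.
#'
#' @param domains a [domain_table()].
#' @return [scored_pairs()] with code `"DC"`; scores `>= 0`.
#' @export
infer_domain_cooccurrence <- function(domains) {
  stopifnot(inherits(domains, "domain_table"))
  .hypergeom_overlap_scores(domains$gene_domains, domains$universe_size, 1,
                            "DC", "domain")
}

#' Construct a gene neighborhood table
#'
#' Ortholog gene order in reference genomes for the query species'
#' genes, used for genomic-context evidence.
#'
#' @param table data frame with columns `genome`, `gene`, `position`
#'   (integer gene-order index, unique within a genome).
#' @return An object of class `neighborhood_table`.
#' @export
neighborhood_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("genome", "gene", "position") %in% names(table)))
  tab <- data.frame(genome = as.character(table$genome),
                    gene = .assert_gene_ids(table$gene),
                    position = as.numeric(table$position),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(tab$position))) {
    stop("positions must be finite numbers", call. = FALSE)
  }
  for (g in unique(tab$genome)) {
    sub <- tab[tab$genome == g, ]
    if (anyDuplicated(sub$position) || anyDuplicated(sub$gene)) {
      stop("positions and genes must be unique within genome '", g, "'",
           call. = FALSE)
    }
  }
  structure(list(table = tab), class = "neighborhood_table")
}

#' Gene neighborhood evidence (chromosomal co-proximity of orthologs)
#'
#' Scores a gene pair by the fraction of reference genomes in which both
#' genes have orthologs *and* those orthologs lie within `window` gene
#' positions of each other, among the genomes where both are present.
#' Pairs co-present in fewer than 2 genomes, or never within the window,
#' are omitted.
#'
#' @param nbr a [neighborhood_table()].
#' @param window maximum gene-order distance counted as proximal
#'   (default 1 = adjacency).
#' @return [scored_pairs()] with code `"GN"`; scores in `(0, 1]`.
#' @export
infer_gene_neighborhood <- function(nbr, window = 1) {
  stopifnot(inherits(nbr, "neighborhood_table"), window >= 1)
  tab <- nbr$table
  genes <- sort(unique(tab$gene))
  n <- length(genes)
  if (n < 2) return(scored_pairs(code = "GN"))
  co <- matrix(0, n, n, dimnames = list(genes, genes))
  near <- matrix(0, n, n, dimnames = list(genes, genes))
  for (g in unique(tab$genome)) {
    sub <- tab[tab$genome == g, ]
    idx <- match(sub$gene, genes)
    co[idx, idx] <- co[idx, idx] + 1
    d <- abs(outer(sub$position, sub$position, "-")) <= window
    near[idx, idx] <- near[idx, idx] + d
  }
  ut <- which(upper.tri(co), arr.ind = TRUE)
  copresent <- co[ut]
  prox <- near[ut]
  keep <- copresent >= 2 & prox > 0
  scored_pairs(genes[ut[keep, 1]], genes[ut[keep, 2]],
               prox[keep] / copresent[keep], code = "GN")
}

#' Transfer a network across species by orthology
#'
#' Each source-species edge `(a, b, w)` emits every target-species pair
#' `(a', b')` with `a'` an ortholog of `a` and `b'` an ortholog of `b`,
#' carrying the raw score `w`.  Self-pairs (when `a` and `b` share an
#' ortholog) are never emitted; duplicate target pairs collapse keeping
#' the maximum score; edges with an unmapped endpoint are dropped.
#'
#' @param net source-species [gene_network()].
#' @param omap an [ortholog_map()] from source to target gene ids.
#' @return [scored_pairs()] with code `"XFER"` in the target namespace.
#' @export
transfer_orthology <- function(net, omap) {
  stopifnot(inherits(net, "gene_network"), inherits(omap, "ortholog_map"))
  ed <- net$edges
  if (nrow(ed) == 0) return(scored_pairs(code = "XFER"))
  orth <- split(omap$pairs$target, omap$pairs$source)
  ta <- orth[ed$gene_a]
  tb <- orth[ed$gene_b]
  na <- lengths(ta); nb <- lengths(tb)
  keep <- na > 0 & nb > 0
  if (!any(keep)) return(scored_pairs(code = "XFER"))
  ga <- gb <- character(0); w <- numeric(0)
  for (i in which(keep)) {
    grid <- expand.grid(a = ta[[i]], b = tb[[i]],
                        stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (nrow(grid) == 0) next
    ga <- c(ga, grid$a); gb <- c(gb, grid$b)
    w <- c(w, rep(ed$weight[i], nrow(grid)))
  }
  if (length(ga) == 0) return(scored_pairs(code = "XFER"))
  scored_pairs(ga, gb, w, code = "XFER")
}
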