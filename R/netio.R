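#' Construct a functional gene network
#'
#' A `gene_network` is an undirected, weighted gene graph: the central
#' container of the package.  Edge weights are log-likelihood scores (LLS,
#' in nats) for integrated or calibrated networks, or arbitrary finite
#' confidences for imported networks.  Gene identifiers are opaque
#' non-empty strings; no organism-specific validation is applied.
#'
#' Edges are normalized on construction: pairs are put in canonical order
#' (`gene_a < gene_b`), self-loops are dropped with a warning, duplicate
#' unordered pairs collapse keeping the maximum weight, and rows are
#' sorted by descending weight then pair, so that a network has a single
#' canonical representation.
#'
#' @param edges data frame with character columns `gene_a`, `gene_b` and a
#'   finite numeric `weight` column.
#' @return An object of class `gene_network` with elements `edges` (the
#'   normalized edge data frame) and `genes` (sorted node set).
#' @seealso [read_network()], [write_network()], [network_stats()]
#' @export
#' @examples
#' net <- gene_network(data.frame(gene_a = c("b", "a"),
#'                                gene_b = c("a", "c"),
#'                                weight = c(1.5, 2)))
#' network_stats(net)
gene_network <- function(edges = data.frame(gene_a = character(),
                                            gene_b = character(),
                                            weight = numeric())) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  gene_a <- .assert_gene_ids(edges$gene_a)
  gene_b <- .assert_gene_ids(edges$gene_b)
  weight <- as.numeric(edges$weight)
  if (any(!is.finite(weight))) {
    stop("edge weights must be finite", call. = FALSE)
  }
  self <- gene_a == gene_b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped", call. = FALSE)
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]; weight <- weight[!self]
  }
  cp <- .canonical_pairs(gene_a, gene_b)
  key <- .pair_key(cp$gene_a, cp$gene_b)
  if (anyDuplicated(key)) {
    w <- tapply(weight, key, max)
    first <- !duplicated(key)
    cp$gene_a <- cp$gene_a[first]
    cp$gene_b <- cp$gene_b[first]
    weight <- as.numeric(w[.pair_key(cp$gene_a, cp$gene_b)])
  }
  ord <- order(-weight, cp$gene_a, cp$gene_b)
  ed <- data.frame(gene_a = cp$gene_a[ord], gene_b = cp$gene_b[ord],
                   weight = weight[ord], stringsAsFactors = FALSE,
                   row.names = NULL)
  structure(list(edges = ed,
                 genes = sort(unique(c(ed$gene_a, ed$gene_b)))),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d links\n",
              length(x$genes), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    q <- stats::quantile(x$edges$weight, c(0, .25, .5, .75, 1))
    cat("  weights: ", paste(sprintf("%s=%.3g", names(q), q),
                             collapse = " "), "\n", sep = "")
    print(utils::head(x$edges, 5L))
    if (nrow(x$edges) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Network summary statistics
#'
#' Gene count, link count and weight quantiles of a network.
#'
#' @param net a [gene_network()].
#' @param probs quantile probabilities for the weight distribution.
#' @return list with `n_genes`, `n_links`, `weight_quantiles`.
#' @export
network_stats <- function(net, probs = c(0, .25, .5, .75, 1)) {
  stopifnot(inherits(net, "gene_network"))
  list(n_genes = length(net$genes),
       n_links = nrow(net$edges),
       weight_quantiles = if (nrow(net$edges) > 0)
         stats::quantile(net$edges$weight, probs) else
           stats::setNames(rep(NA_real_, length(probs)),
                           paste0(100 * probs, "%")))
}

#' @export
summary.gene_network <- function(object, ...) network_stats(object)

#' Read a weighted gene-network edge list
#'
#' Parses a tab-delimited edge list with at least three columns
#' (`gene_a`, `gene_b`, `weight`).  A header line is detected by a
#' non-numeric third field and skipped; `#` comment lines are ignored.
#' Duplicate unordered pairs collapse keeping the maximum weight and
#' self-loops are dropped with a warning (see [gene_network()]).
#'
#' @param path path to a TSV file.
#' @return A [gene_network()].
#' @export
read_network <- function(path) {
  tf <- .read_tsv_fields(path)
  n <- length(tf$fields)
  if (n == 0) return(gene_network())
  start <- 1L
  f1 <- tf$fields[[1]]
  if (length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3])))) {
    start <- 2L  # header line
  }
  if (start > n) return(gene_network())
  idx <- start:n
  ga <- gb <- character(length(idx)); w <- numeric(length(idx))
  for (j in seq_along(idx)) {
    f <- tf$fields[[idx[j]]]
    if (length(f) < 3) {
      .stop_parse(path, tf$lineno[idx[j]], "expected >= 3 tab-separated columns")
    }
    wt <- suppressWarnings(as.numeric(f[3]))
    if (is.na(wt)) {
      .stop_parse(path, tf$lineno[idx[j]],
                  sprintf("non-numeric weight '%s'", f[3]))
    }
    ga[j] <- f[1]; gb[j] <- f[2]; w[j] <- wt
  }
  gene_network(data.frame(gene_a = ga, gene_b = gb, weight = w,
                          stringsAsFactors = FALSE))
}

#' Write a gene network as a canonical TSV edge list
#'
#' Writes a header (`gene_a`, `gene_b`, `weight`) and one row per edge,
#' pairs in lexicographic order within a row, rows sorted by descending
#' weight then pair, weights printed with 6 significant digits.  Output
#' bytes are deterministic for a given network, and
#' `write_network()` then [read_network()] is the identity to printed
#' precision.
#'
#' @param net a [gene_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  ed <- net$edges
  lines <- c("gene_a\tgene_b\tweight",
             if (nrow(ed) > 0)
               paste(ed$gene_a, ed$gene_b, .fmt_num(ed$weight), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct an annotation set
#'
#' Maps functional terms (GO-BP, KEGG, pathway, phenotype, ...) to gene
#' sets in the same identifier namespace as the networks.
#'
#' @param genes named list: term id -> character vector of gene ids
#'   (non-empty, deduplicated).
#' @param description character vector of term descriptions (recycled).
#' @param source character vector of source tags, e.g. `"GO-BP"`,
#'   `"KEGG"`, `"other"` (recycled).
#' @return An object of class `annotation_set` with elements `genes`,
#'   `description`, `source` (all named by term id).
#' @export
annotation_set <- function(genes, description = "", source = "other") {
  stopifnot(is.list(genes), length(names(genes)) == length(genes),
            all(nzchar(names(genes))))
  genes <- lapply(genes, function(g) sort(unique(.assert_gene_ids(g))))
  if (any(lengths(genes) == 0)) {
    stop("every term must annotate at least one gene", call. = FALSE)
  }
  terms <- names(genes)
  structure(list(
    genes = genes,
    description = stats::setNames(rep_len(as.character(description),
                                          length(terms)), terms),
    source = stats::setNames(rep_len(as.character(source),
                                     length(terms)), terms)
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d terms, %d genes (sources: %s)\n",
              length(x$genes), length(unique(unlist(x$genes))),
              paste(unique(x$source), collapse = ", ")))
  invisible(x)
}

#' Subset an annotation set
#'
#' @param ann an [annotation_set()].
#' @param terms term ids to keep (default all).
#' @param source keep only terms with these source tags (default all).
#' @return An [annotation_set()].
#' @export
subset_annotations <- function(ann, terms = NULL, source = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  keep <- names(ann$genes)
  if (!is.null(terms)) keep <- intersect(keep, terms)
  if (!is.null(source)) keep <- keep[ann$source[keep] %in% source]
  annotation_set(ann$genes[keep], ann$description[keep], ann$source[keep])
}

#' Read a GMT annotation file
#'
#' Standard GMT dialect: per line, term id, description, then gene ids,
#' tab-separated.  Duplicate genes within a line are deduplicated; lines
#' with no genes are dropped with a warning; lines with fewer than two
#' columns are a parse error.
#'
#' @param path path to a GMT file.
#' @param source source tag recorded for every term (default `"other"`).
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, source = "other") {
  tf <- .read_tsv_fields(path)
  genes <- list(); desc <- character()
  for (j in seq_along(tf$fields)) {
    f <- tf$fields[[j]]
    if (length(f) < 2) {
      .stop_parse(path, tf$lineno[j], "expected >= 2 tab-separated columns")
    }
    g <- unique(f[-(1:2)])
    g <- g[nzchar(g)]
    if (length(g) == 0) {
      warning(sprintf("term '%s' has no genes; dropped (line %d)",
                      f[1], tf$lineno[j]), call. = FALSE)
      next
    }
    genes[[f[1]]] <- g
    desc[f[1]] <- f[2]
  }
  if (length(genes) == 0) {
    return(structure(list(genes = list(),
                          description = character(),
                          source = character()),
                     class = "annotation_set"))
  }
  annotation_set(genes, desc[names(genes)], source)
}

#' Write an annotation set as GMT
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  terms <- sort(names(ann$genes))
  lines <- vapply(terms, function(t) {
    paste(c(t, ann$description[[t]], ann$genes[[t]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct an expression bundle
#'
#' A gene-by-sample matrix of non-negative expression values (BPKM or
#' array intensities) together with a sample-to-context map assigning
#' each sample a spatiotemporal context (a developmental stage or a
#' tissue type).
#'
#' @param matrix numeric gene x sample matrix, non-negative, with row
#'   (gene) and column (sample) names.
#' @param contexts data frame with columns `sample`, `label`, `kind`
#'   (`kind` in `"stage"`/`"tissue"`); every matrix sample must appear.
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(matrix, contexts) {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            !is.null(rownames(matrix)), !is.null(colnames(matrix)),
            is.data.frame(contexts),
            all(c("sample", "label", "kind") %in% names(contexts)))
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  contexts <- data.frame(sample = as.character(contexts$sample),
                         label = as.character(contexts$label),
                         kind = as.character(contexts$kind),
                         stringsAsFactors = FALSE)
  if (!all(contexts$kind %in% c("stage", "tissue"))) {
    stop("context kind must be 'stage' or 'tissue'", call. = FALSE)
  }
  contexts <- contexts[!duplicated(contexts$sample), , drop = FALSE]
  missing <- setdiff(colnames(matrix), contexts$sample)
  if (length(missing) > 0) {
    stop("samples lack a context: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(contexts$sample, colnames(matrix))
  if (length(extra) > 0) {
    warning("context map lists unknown samples: ",
            paste(extra, collapse = ", "), call. = FALSE)
    contexts <- contexts[contexts$sample %in% colnames(matrix), , drop = FALSE]
  }
  rownames(contexts) <- NULL
  structure(list(matrix = matrix, contexts = contexts),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("expression_bundle: %d genes x %d samples, %d contexts\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$contexts$label))))
  invisible(x)
}

#' Read an expression matrix and its sample context map
#'
#' The matrix file is a TSV whose header row names the samples (an
#' optional leading field naming the gene column is tolerated) and whose
#' first column holds gene ids.  The context file is a 3-column TSV:
#' sample, context label, context kind (`stage` or `tissue`).
#'
#' @param matrix_path path to the expression TSV.
#' @param context_path path to the context TSV.
#' @return An [expression_bundle()].
#' @export
read_expression <- function(matrix_path, context_path) {
  tf <- .read_tsv_fields(matrix_path)
  if (length(tf$fields) < 2) {
    .stop_parse(matrix_path, 1L, "need a header line and at least one gene row")
  }
  header <- tf$fields[[1]]
  body <- tf$fields[-1]
  ncol_body <- length(body[[1]])
  samples <- if (length(header) == ncol_body) header[-1] else header
  if (length(samples) != ncol_body - 1) {
    .stop_parse(matrix_path, tf$lineno[1], "header/sample count mismatch")
  }
  genes <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (j in seq_along(body)) {
    f <- body[[j]]
    if (length(f) != ncol_body) {
      .stop_parse(matrix_path, tf$lineno[j + 1L], "ragged row")
    }
    v <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(v))) {
      .stop_parse(matrix_path, tf$lineno[j + 1L], "non-numeric value")
    }
    genes[j] <- f[1]
    vals[j, ] <- v
  }
  dimnames(vals) <- list(genes, samples)
  ctf <- .read_tsv_fields(context_path)
  bad <- which(lengths(ctf$fields) < 3)
  if (length(bad) > 0) {
    .stop_parse(context_path, ctf$lineno[bad[1]], "expected 3 columns")
  }
  cx <- do.call(rbind, lapply(ctf$fields, function(f)
    data.frame(sample = f[1], label = f[2], kind = f[3],
               stringsAsFactors = FALSE)))
  expression_bundle(vals, cx)
}

#' Write an expression bundle to TSV files
#'
#' @param bundle an [expression_bundle()].
#' @param matrix_path,context_path output file paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(bundle, matrix_path, context_path) {
  stopifnot(inherits(bundle, "expression_bundle"))
  m <- bundle$matrix
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], .fmt_num(m[i, ])), collapse = "\t"),
               character(1)))
  con <- file(matrix_path, open = "wb"); writeLines(lines, con, useBytes = TRUE)
  close(con)
  cx <- bundle$contexts
  con <- file(context_path, open = "wb")
  writeLines(paste(cx$sample, cx$label, cx$kind, sep = "\t"), con,
             useBytes = TRUE)
  close(con)
  invisible(matrix_path)
}

#' Construct an ortholog map
#'
#' Many-to-many pairs of (source-species gene, target-species gene).
#'
#' @param pairs data frame with character columns `source`, `target`.
#' @return An object of class `ortholog_map` (deduplicated pair table).
#' @export
ortholog_map <- function(pairs = data.frame(source = character(),
                                            target = character())) {
  stopifnot(is.data.frame(pairs),
            all(c("source", "target") %in% names(pairs)))
  src <- .assert_gene_ids(pairs$source, "source gene id")
  tgt <- .assert_gene_ids(pairs$target, "target gene id")
  key <- .pair_key(src, tgt)
  keep <- !duplicated(key)
  ord <- order(src[keep], tgt[keep])
  structure(list(pairs = data.frame(source = src[keep][ord],
                                    target = tgt[keep][ord],
                                    stringsAsFactors = FALSE,
                                    row.names = NULL)),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map: %d pairs (%d source, %d target genes)\n",
              nrow(x$pairs), length(unique(x$pairs$source)),
              length(unique(x$pairs$target))))
  invisible(x)
}

#' Read a two-column ortholog pair table
#'
#' @param path path to a 2-column TSV (source gene, target gene); a
#'   header line whose first field is `source` is skipped.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  tf <- .read_tsv_fields(path)
  if (length(tf$fields) == 0) return(ortholog_map())
  start <- if (identical(tf$fields[[1]][1], "source")) 2L else 1L
  if (start > length(tf$fields)) return(ortholog_map())
  src <- tgt <- character()
  for (j in start:length(tf$fields)) {
    f <- tf$fields[[j]]
    if (length(f) != 2) {
      .stop_parse(path, tf$lineno[j], "expected exactly 2 columns")
    }
    src <- c(src, f[1]); tgt <- c(tgt, f[2])
  }
  ortholog_map(data.frame(source = src, target = tgt,
                          stringsAsFactors = FALSE))
}

#' Write an ortholog map
#'
#' @param omap an [ortholog_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(omap, path) {
  stopifnot(inherits(omap, "ortholog_map"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("source\ttarget",
               paste(omap$pairs$source, omap$pairs$target, sep = "\t")),
             con, useBytes = TRUE)
  invisible(path)
}
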