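# Readers and writers for the evidence input tables (gene-document
# incidence, phylogenetic profiles, protein domains, gene neighborhood)
# and for raw scored pair sets.  All formats are tab-delimited UTF-8
# with '#' comment lines ignored.

#' Read a gene-to-document incidence table
#'
#' Two-column TSV: gene id, document id (one row per citation).  The
#' corpus size may be given explicitly or as a `# corpus_size: N` header
#' comment; otherwise it defaults to the number of distinct documents.
#'
#' @param path path to the TSV file.
#' @param corpus_size optional total document count.
#' @return A [doc_incidence()].
#' @export
read_doc_incidence <- function(path, corpus_size = NULL) {
  if (is.null(corpus_size)) {
    hdr <- grep("^#\\s*corpus_size:", readLines(path, warn = FALSE),
                value = TRUE)
    if (length(hdr) > 0) {
      corpus_size <- as.integer(sub("^#\\s*corpus_size:\\s*", "", hdr[1]))
    }
  }
  tf <- .read_tsv_fields(path)
  bad <- which(lengths(tf$fields) < 2)
  if (length(bad) > 0) {
    .stop_parse(path, tf$lineno[bad[1]], "expected 2 columns (gene, doc)")
  }
  gene <- vapply(tf$fields, `[`, character(1), 1)
  doc <- vapply(tf$fields, `[`, character(1), 2)
  if (is.null(corpus_size)) corpus_size <- length(unique(doc))
  doc_incidence(split(doc, gene), corpus_size)
}

#' Write a gene-to-document incidence table
#' @param docs a [doc_incidence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_doc_incidence <- function(docs, path) {
  stopifnot(inherits(docs, "doc_incidence"))
  genes <- sort(names(docs$gene_docs))
  lines <- c(sprintf("# corpus_size: %d", docs$corpus_size),
             unlist(lapply(genes, function(g)
               paste(g, sort(docs$gene_docs[[g]]), sep = "\t"))))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a phylogenetic profile matrix
#'
#' TSV with a header of genome ids (optional leading gene-column name)
#' and one 0/1 row per gene.
#'
#' @param path path to the TSV file.
#' @return A [profile_matrix()].
#' @export
read_profile_matrix <- function(path) {
  tf <- .read_tsv_fields(path)
  if (length(tf$fields) < 2) {
    .stop_parse(path, 1L, "need a header line and at least one gene row")
  }
  header <- tf$fields[[1]]
  body <- tf$fields[-1]
  ncol_body <- length(body[[1]])
  genomes <- if (length(header) == ncol_body) header[-1] else header
  vals <- matrix(NA_real_, length(body), length(genomes))
  genes <- character(length(body))
  for (j in seq_along(body)) {
    f <- body[[j]]
    if (length(f) != ncol_body) .stop_parse(path, tf$lineno[j + 1L], "ragged row")
    v <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(v))) .stop_parse(path, tf$lineno[j + 1L], "non-numeric entry")
    genes[j] <- f[1]; vals[j, ] <- v
  }
  dimnames(vals) <- list(genes, genomes)
  profile_matrix(vals)
}

#' Write a phylogenetic profile matrix
#' @param profiles a [profile_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(profiles, path) {
  stopifnot(inherits(profiles, "profile_matrix"))
  m <- profiles$matrix
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)),
                     collapse = "\t"), character(1)))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a gene-to-domain table
#'
#' Two-column TSV: gene id, domain id.  The domain universe size may be
#' given explicitly or as a `# universe_size: N` header comment;
#' otherwise it defaults to the number of distinct domains.
#'
#' @param path path to the TSV file.
#' @param universe_size optional domain universe size.
#' @return A [domain_table()].
#' @export
read_domain_table <- function(path, universe_size = NULL) {
  if (is.null(universe_size)) {
    hdr <- grep("^#\\s*universe_size:", readLines(path, warn = FALSE),
                value = TRUE)
    if (length(hdr) > 0) {
      universe_size <- as.integer(sub("^#\\s*universe_size:\\s*", "", hdr[1]))
    }
  }
  tf <- .read_tsv_fields(path)
  bad <- which(lengths(tf$fields) < 2)
  if (length(bad) > 0) {
    .stop_parse(path, tf$lineno[bad[1]], "expected 2 columns (gene, domain)")
  }
  gene <- vapply(tf$fields, `[`, character(1), 1)
  dom <- vapply(tf$fields, `[`, character(1), 2)
  if (is.null(universe_size)) universe_size <- length(unique(dom))
  domain_table(split(dom, gene), universe_size)
}

#' Write a gene-to-domain table
#' @param domains a [domain_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  stopifnot(inherits(domains, "domain_table"))
  genes <- sort(names(domains$gene_domains))
  lines <- c(sprintf("# universe_size: %d", domains$universe_size),
             unlist(lapply(genes, function(g)
               paste(g, sort(domains$gene_domains[[g]]), sep = "\t"))))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a gene neighborhood table
#'
#' Three-column TSV: reference genome id, gene id, gene-order position.
#' A header line starting with `genome` is skipped.
#'
#' @param path path to the TSV file.
#' @return A [neighborhood_table()].
#' @export
read_neighborhood_table <- function(path) {
  tf <- .read_tsv_fields(path)
  if (length(tf$fields) == 0) {
    return(neighborhood_table(data.frame(genome = character(),
                                         gene = character(),
                                         position = numeric())))
  }
  start <- if (identical(tf$fields[[1]][1], "genome")) 2L else 1L
  rows <- lapply(seq(start, length.out = length(tf$fields) - start + 1L),
                 function(j) {
    f <- tf$fields[[j]]
    if (length(f) != 3) {
      .stop_parse(path, tf$lineno[j], "expected 3 columns (genome, gene, position)")
    }
    pos <- suppressWarnings(as.numeric(f[3]))
    if (is.na(pos)) .stop_parse(path, tf$lineno[j], "non-numeric position")
    data.frame(genome = f[1], gene = f[2], position = pos,
               stringsAsFactors = FALSE)
  })
  neighborhood_table(do.call(rbind, rows))
}

#' Write a gene neighborhood table
#' @param nbr a [neighborhood_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_neighborhood_table <- function(nbr, path) {
  stopifnot(inherits(nbr, "neighborhood_table"))
  tab <- nbr$table
  tab <- tab[order(tab$genome, tab$position), , drop = FALSE]
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(c("genome\tgene\tposition",
               paste(tab$genome, tab$gene, format(tab$position, trim = TRUE),
                     sep = "\t")), con, useBytes = TRUE)
  invisible(path)
}

#' Read a raw scored pair set
#'
#' Three-column TSV (gene_a, gene_b, score) with the evidence code in a
#' `# evidence_code: X` header comment or supplied explicitly.
#'
#' @param path path to the TSV file.
#' @param code optional evidence code overriding the header.
#' @return A [scored_pairs()] object.
#' @export
read_scored_pairs <- function(path, code = NULL) {
  if (is.null(code)) {
    hdr <- grep("^#\\s*evidence_code:", readLines(path, warn = FALSE),
                value = TRUE)
    code <- if (length(hdr) > 0) {
      sub("^#\\s*evidence_code:\\s*", "", hdr[1])
    } else "CX"
  }
  net <- read_network(path)
  scored_pairs(net$edges$gene_a, net$edges$gene_b, net$edges$weight,
               code = code)
}

#' Write a raw scored pair set
#' @param pairs a [scored_pairs()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "scored_pairs"))
  lines <- c(sprintf("# evidence_code: %s", evidence_code(pairs)),
             "gene_a\tgene_b\tscore",
             if (nrow(pairs) > 0)
               paste(pairs$gene_a, pairs$gene_b, .fmt_num(pairs$score),
                     sep = "\t"))
  con <- file(path, open = "wb"); on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
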