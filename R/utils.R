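# Internal helpers shared across modules.

# Put every gene pair in canonical order (gene_a < gene_b, lexicographic).
.canonical_pairs <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  swap <- gene_a > gene_b
  if (any(swap)) {
    tmp <- gene_a[swap]
    gene_a[swap] <- gene_b[swap]
    gene_b[swap] <- tmp
  }
  list(gene_a = gene_a, gene_b = gene_b)
}

# Key for an unordered pair; "\r" cannot occur in a TSV gene id.
.pair_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\r")

# 6 significant digits, always with a decimal point or exponent so that
# written files are byte-reproducible and visibly numeric.
.fmt_num <- function(x) {
  s <- sprintf("%.6g", x)
  plain <- !grepl("[.eE]", s) & is.finite(x)
  s[plain] <- paste0(s[plain], ".0")
  s
}

# Read a tab-delimited text file, dropping '#' comment lines and blank
# lines but remembering original line numbers for error messages.
# Returns list(fields = list of character vectors, lineno = integer).
.read_tsv_fields <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(
    fields = strsplit(lines[keep], "\t", fixed = TRUE),
    lineno = which(keep)
  )
}

.stop_parse <- function(path, lineno, msg) {
  stop(sprintf("parse error in '%s' line %d: %s", path, lineno, msg),
       call. = FALSE)
}

# Evaluate an expression with a private, restored RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.assert_gene_ids <- function(ids, what = "gene id") {
  ids <- as.character(ids)
  if (any(is.na(ids) | !nzchar(ids))) {
    stop("empty or missing ", what, call. = FALSE)
  }
  ids
}
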