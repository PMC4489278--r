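# Independent brute-force oracles and small fixture builders used
# across the test files.  The oracles never call the code paths they
# check.

# Upper-tail hypergeometric P(overlap >= k) by direct enumeration of
# the probability mass function from binomial coefficients.
oracle_hyper_upper <- function(k, K1, K2, N) {
  js <- k:min(K1, K2)
  sum(vapply(js, function(j)
    choose(K1, j) * choose(N - K1, K2 - j), numeric(1))) / choose(N, K2)
}

# ROC AUC by exhaustive pairwise comparison counting (ties = 1/2).
oracle_auc <- function(scores, pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (scores[[p]] > scores[[n]]) + 0.5 * (scores[[p]] == scores[[n]])
  }
  tot / (length(pos) * length(neg))
}

# Two-sided exact signed-rank p-value by enumerating all 2^n sign
# patterns of the absolute differences.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Mutual information (bits) between two binary vectors, plug-in
# estimate from the 2x2 joint table.
oracle_mi_bits <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in 0:1) for (b in 0:1) {
    pj <- mean(x == a & y == b)
    if (pj > 0) mi <- mi + pj * log2(pj / (mean(x == a) * mean(y == b)))
  }
  mi
}

# A tiny deterministic network from an edge triple list.
toy_network <- function(...) {
  tr <- list(...)
  gene_network(data.frame(
    gene_a = vapply(tr, function(e) as.character(e[[1]]), character(1)),
    gene_b = vapply(tr, function(e) as.character(e[[2]]), character(1)),
    weight = vapply(tr, function(e) as.numeric(e[[3]]), numeric(1)),
    stringsAsFactors = FALSE))
}

# A random gene network over n genes (seeded by caller).
random_network <- function(n_genes = 20, p = 0.3) {
  genes <- sprintf("r%03d", seq_len(n_genes))
  ut <- which(upper.tri(diag(n_genes)), arr.ind = TRUE)
  keep <- runif(nrow(ut)) < p
  gene_network(data.frame(gene_a = genes[ut[keep, 1]],
                          gene_b = genes[ut[keep, 2]],
                          weight = round(runif(sum(keep), 0.1, 5), 4),
                          stringsAsFactors = FALSE))
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
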