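test_that("direct neighborhood sums edge weights to guides", {
  net <- toy_network(list("c", "g1", 1.5), list("c", "g2", 2.5),
                     list("g1", "g2", 0.7), list("d", "e", 1.0))
  sc <- score_direct_neighborhood(net, c("g1", "g2"))
  expect_equal(unname(sc["c"]), 4.0)
  expect_equal(unname(sc["d"]), 0)          # no guide neighbors
  expect_equal(unname(sc["g1"]), 0.7)       # guides score the other guides

  # a single guide scores 0 itself; neighbors score their edge weight
  sc1 <- score_direct_neighborhood(net, "g1")
  expect_equal(unname(sc1["g1"]), 0)
  expect_equal(unname(sc1["c"]), 1.5)

  expect_error(score_direct_neighborhood(net, c("zz", "qq")),
               "no guide gene.*zz")
  expect_message(score_direct_neighborhood(net, c("g1", "zz")), "ignoring 1")
})

test_that("diffusion matches the closed-form two-node solution", {
  net <- toy_network(list("a", "b", 1))
  f <- score_network_diffusion(net, "a", alpha = 0.5)
  expect_equal(unname(f["a"]), 4 / 3, tolerance = 1e-12)
  expect_equal(unname(f["b"]), 2 / 3, tolerance = 1e-12)

  f0 <- score_network_diffusion(net, character(0), alpha = 0.5)
  expect_equal(unname(f0), c(0, 0))
})

test_that("diffusion satisfies its linear system and matches a dense solve", {
  set.seed(41)
  for (rep in 1:3) {
    net <- random_network(50, 0.12)
    guides <- sample(net$genes, 5)
    alpha <- 0.8
    f_ex <- score_network_diffusion(net, guides, alpha = alpha,
                                    method = "exact")
    f_it <- score_network_diffusion(net, guides, alpha = alpha,
                                    method = "iterative", tol = 1e-10)
    expect_lt(max(abs(f_ex - f_it)), 1e-6)

    # independent dense oracle built straight from the edge table
    genes <- net$genes; n <- length(genes)
    W <- matrix(0, n, n, dimnames = list(genes, genes))
    for (k in seq_len(nrow(net$edges))) {
      a <- net$edges$gene_a[k]; b <- net$edges$gene_b[k]
      W[a, b] <- W[a, b] + net$edges$weight[k]
      W[b, a] <- W[b, a] + net$edges$weight[k]
    }
    d <- rowSums(W); dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
    S <- diag(dinv) %*% W %*% diag(dinv)
    y <- as.numeric(genes %in% guides)
    f_oracle <- solve(diag(n) - alpha * S, y)
    expect_equal(unname(f_ex[genes]), as.numeric(f_oracle),
                 tolerance = 1e-8)
    # residual of the propagation equation
    expect_lt(max(abs((diag(n) - alpha * S) %*% f_ex[genes] - y)), 1e-6)
  }
})

test_that("gene prioritization ranks deterministically and retrieves cliques", {
  # guides form a clique, everyone else is connected only among themselves
  net <- toy_network(list("g1", "g2", 2), list("g1", "g3", 2),
                     list("g2", "g3", 2), list("u1", "u2", 1),
                     list("u2", "u3", 1))
  res <- prioritize_genes(net, c("g1", "g2", "g3"), algorithm = "direct")
  expect_equal(res$auc, 1.0)
  expect_equal(res$records$rank, 1:6)
  expect_true(all(diff(res$records$score) <= 0))
  expect_setequal(res$candidates, c("u1", "u2", "u3"))
  # ties broken by gene id
  tied <- res$records[res$records$score == 0, ]
  expect_equal(tied$gene, sort(tied$gene))
  # relabeling invariance (up to the tie-break permutation)
  relabel <- function(g) chartr("gu", "xy", g)
  net2 <- gene_network(data.frame(gene_a = relabel(net$edges$gene_a),
                                  gene_b = relabel(net$edges$gene_b),
                                  weight = net$edges$weight))
  res2 <- prioritize_genes(net2, c("x1", "x2", "x3"), algorithm = "direct")
  expect_equal(res2$auc, res$auc)
  expect_equal(res2$records$score, res$records$score)
})

test_that("planted-module guides enrich the held-out members over a null", {
  spec <- synth_spec(seed = 17)
  sim <- gen_modular_network(spec)
  mem <- sim$membership
  mod <- mem$gene[!is.na(mem$module) & mem$module == "M03"]
  guides <- mod[1:10]; held <- mod[11:20]
  res <- prioritize_genes(sim$network, guides, algorithm = "diffusion")
  top <- utils::head(res$candidates, 30)
  hits <- sum(held %in% top)
  # permutation baseline: random guide sets of the same size
  set.seed(99)
  null_hits <- vapply(1:20, function(i) {
    rg <- sample(setdiff(sim$network$genes, mod), 10)
    rn <- prioritize_genes(sim$network, rg, algorithm = "diffusion")
    sum(held %in% utils::head(rn$candidates, 30))
  }, numeric(1))
  expect_gt(hits, mean(null_hits) + 3 * max(stats::sd(null_hits), 0.5))
})

test_that("function prioritization sums neighbor weights per term", {
  net <- toy_network(list("q", "n1", 2.0), list("q", "n2", 1.0),
                     list("n1", "n2", 5.0))
  ann <- annotation_set(list(T1 = c("n1", "n2"), T2 = c("n2"),
                             T3 = c("q"), T4 = c("zz")))
  out <- prioritize_functions(net, "q", ann)
  expect_equal(out$term, c("T1", "T2"))
  expect_equal(out$score, c(3.0, 1.0))
  # T3 annotates only the query -> omitted; T4 has no neighbors -> omitted
  expect_false(any(c("T3", "T4") %in% out$term))
  expect_error(prioritize_functions(net, "absent", ann), "absent")
  # term score never exceeds the direct-neighborhood score of the query
  # against the term's gene set
  for (t in out$term) {
    dn <- score_direct_neighborhood(net, ann$genes[[t]])
    expect_lte(out$score[out$term == t], dn[["q"]] + 1e-12)
  }

  lonely <- toy_network(list("q", "n1", 1), list("a", "b", 1))
  expect_equal(nrow(prioritize_functions(lonely, "a",
                                         annotation_set(list(T = "zz")))), 0L)
})

test_that("STNs filter edges by mean expression of both endpoints", {
  net <- toy_network(list("a", "b", 1), list("b", "c", 2))
  mat <- rbind(a = c(2, 2, 0.1, 0.1), b = c(2, 2, 2, 2),
               c = c(0.4, 0.6, 2, 2))
  colnames(mat) <- sprintf("s%d", 1:4)
  bundle <- expression_bundle(mat, data.frame(
    sample = colnames(mat), label = rep(c("EB", "AD"), each = 2),
    kind = "stage"))
  stns <- build_stns(net, bundle, threshold = 1)
  # EB: a,b expressed (mean 2), c mean 0.5 -> only a-b survives
  expect_equal(nrow(stns$networks$EB$edges), 1L)
  expect_equal(stns$networks$EB$edges$gene_a, "a")
  # AD: b,c expressed, a mean 0.1 -> only b-c survives
  expect_equal(stns$networks$AD$edges$gene_a, "b")
  # subset invariant and monotone filtering
  for (l in names(stns$networks)) {
    expect_true(all(paste(stns$networks[[l]]$edges$gene_a,
                          stns$networks[[l]]$edges$gene_b) %in%
                      paste(net$edges$gene_a, net$edges$gene_b)))
  }
  stricter <- build_stns(net, bundle, threshold = 3)
  for (l in names(stns$networks)) {
    expect_lte(nrow(stricter$networks[[l]]$edges),
               nrow(stns$networks[[l]]$edges))
  }
  # genes absent from the matrix are treated as unexpressed
  net2 <- toy_network(list("a", "zz", 5))
  expect_message(stns2 <- build_stns(net2, bundle, 1), "not expressed")
  expect_equal(nrow(stns2$networks$EB$edges), 0L)
})

test_that("STN neighbor counts aggregate unique neighbors and flag top context", {
  net <- toy_network(list("g1", "n1", 1), list("g1", "n2", 1),
                     list("g1", "n3", 1), list("g2", "n1", 1))
  mat <- matrix(2, nrow = 5, ncol = 2,
                dimnames = list(c("g1", "g2", "n1", "n2", "n3"),
                                c("s1", "s2")))
  mat[c("n2", "n3"), 2] <- 0  # silence n2,n3 in the second context
  bundle <- expression_bundle(mat, data.frame(
    sample = c("s1", "s2"), label = c("HD", "AG"), kind = "tissue"))
  stns <- build_stns(net, bundle, threshold = 1)
  counts <- stn_neighbor_counts(stns, c("g1", "g2"))
  expect_equal(counts$counts["g1", "HD"], 3L)
  expect_equal(counts$counts["g1", "AG"], 1L)
  # unique-neighbor aggregate counts the shared neighbor n1 once
  expect_equal(counts$counts["[set]", "HD"], 3L)
  expect_equal(counts$log_counts["g2", "AG"], log10(2))
  expect_equal(counts$log_counts["[set]", "AG"] , log10(2))  # n1 only
  expect_true(counts$counts["g2", "AG"] == 1L)
  expect_equal(unname(counts$top_context["tissue"]), "HD")
  # zero count maps to log 0
  counts0 <- stn_neighbor_counts(stns, "n2")
  expect_equal(counts0$log_counts["n2", "AG"], 0)
})

test_that("context-specific links are edges present in one context of their kind", {
  net <- toy_network(list("a", "b", 1), list("b", "c", 2))
  mat <- rbind(a = c(2, 0), b = c(2, 2), c = c(2, 2))
  colnames(mat) <- c("s1", "s2")
  bundle <- expression_bundle(mat, data.frame(
    sample = c("s1", "s2"), label = c("HD", "AG"), kind = "tissue"))
  spec_links <- stn_specific_links(build_stns(net, bundle, 1))
  expect_equal(nrow(spec_links), 1L)
  expect_equal(spec_links$gene_a, "a")
  expect_equal(spec_links$label, "HD")
})

test_that("disease prioritization maps guides and tiers candidates", {
  # network in the model-organism namespace
  net <- toy_network(list("f1", "f2", 2), list("f2", "f3", 1),
                     list("f1", "f4", 3), list("f4", "f5", 1))
  omap <- ortholog_map(data.frame(
    source = c("h1", "h1", "h2", "h3", "h4", "h5"),
    target = c("f1", "f2", "f3", "f4", "f5", "f2")))
  # a disease guide with two orthologs: both enter the guide set
  res <- prioritize_disease(net, omap, "h1", namespace = "disease",
                            support = NULL)
  expect_setequal(res$result$guides, c("f1", "f2"))
  expect_length(res$first_tier, 0L)               # no support genes
  expect_gt(length(res$second_tier), 0L)
  expect_true(all(res$first_tier %in% res$second_tier))

  res2 <- prioritize_disease(net, omap, "h1", namespace = "disease",
                             support = c("h3", "h9"))
  expect_equal(res2$first_tier,
               res2$second_tier[res2$second_tier %in% c("h3", "h9")])
  expect_equal(res2$support_genes_used, c("h3", "h9"))

  # network-namespace guides skip the forward mapping
  res3 <- prioritize_disease(net, omap, c("f1", "f2"),
                             namespace = "network")
  expect_setequal(res3$result$guides, c("f1", "f2"))

  expect_error(prioritize_disease(net, omap, "h99", namespace = "disease"),
               "no guide gene maps")
  expect_message(prioritize_disease(net, omap, c("h1", "h99"),
                                    namespace = "disease"), "no ortholog")
})
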