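test_that("gold standard derivation enumerates co-annotated and disjoint pairs", {
  ann <- annotation_set(list(T1 = c("g1", "g2", "g3"), T2 = c("g4", "g5")))
  gold <- derive_gold_standard(ann, min_term = 2, max_term = 1000)
  expect_equal(nrow(gold$positives), 4L)   # 3 from T1 + 1 from T2
  expect_equal(nrow(gold$negatives), 6L)   # all cross-term pairs
  # disjointness invariant
  pk <- paste(gold$positives$gene_a, gold$positives$gene_b)
  nk <- paste(gold$negatives$gene_a, gold$negatives$gene_b)
  expect_length(intersect(pk, nk), 0L)

  tiny <- derive_gold_standard(annotation_set(list(T = c("a", "b"))),
                               min_term = 2, max_term = 10)
  expect_equal(nrow(tiny$positives), 1L)
  expect_equal(nrow(tiny$negatives), 0L)

  expect_error(derive_gold_standard(
    structure(list(genes = list(), description = character(),
                   source = character()), class = "annotation_set")),
    "empty annotation")
})

test_that("terms outside the size bounds give no positives but allow negatives", {
  ann <- annotation_set(list(BIG = c("g1", "g2", "g3", "g4"),
                             S = c("g1", "g2")))
  gold <- derive_gold_standard(ann, min_term = 2, max_term = 3)
  # only the small term creates a positive
  expect_equal(nrow(gold$positives), 1L)
  expect_equal(gold$positives$gene_a, "g1")
  # g3-g4 share only the oversized term: they count as a negative
  expect_true(any(gold$negatives$gene_a == "g3" &
                    gold$negatives$gene_b == "g4"))
  # unannotated genes appear nowhere
  g <- derive_gold_standard(ann, 2, 3,
                            universe = c("g1", "g2", "g3", "g4", "zz"))
  expect_false("zz" %in% unlist(g$positives) || "zz" %in% unlist(g$negatives))
})

# Build a scored pair set and gold standard with a planted bin layout:
# pairs x0001..x1100 with strictly descending scores; the top 20 gold
# pairs are 10 positives + 10 negatives; totals 100 pos / 1000 neg.
planted_calibration_fixture <- function() {
  n <- 1100
  ids <- sprintf("x%04d", seq_len(n))
  pairs <- scored_pairs(rep("hub", n), ids, seq(n, 1), code = "CX")
  lab <- c(rep(c("P", "N"), 10),                 # top 20: 10 P, 10 N
           rep("P", 90), rep("N", 990))          # remainder
  pos <- ids[lab == "P"]; neg <- ids[lab == "N"]
  gold <- gold_standard(data.frame(gene_a = "hub", gene_b = pos),
                        data.frame(gene_a = "hub", gene_b = neg))
  list(pairs = pairs, gold = gold)
}

test_that("per-bin LLS equals the log odds ratio against the priors", {
  fx <- planted_calibration_fixture()
  curve <- calibrate_lls(fx$pairs, fx$gold, n_bins = 55, min_bin_count = 10)
  top <- curve$bins[nrow(curve$bins), ]
  expect_equal(top$n_pos, 10L, ignore_attr = TRUE)
  expect_equal(top$n_neg, 10L, ignore_attr = TRUE)
  expect_equal(curve$prior_pos, 100L, ignore_attr = TRUE)
  expect_equal(curve$prior_neg, 1000L, ignore_attr = TRUE)
  expect_equal(top$lls, log((10 / 10) / (100 / 1000)), tolerance = 1e-12)
  expect_equal(round(top$lls, 4), 2.3026)
  # bin counts partition the scorable gold pairs
  expect_equal(sum(curve$bins$n_pos), 100)
  expect_equal(sum(curve$bins$n_neg), 1000)
  expect_true(all(curve$bins$n_pos + curve$bins$n_neg >= 10))
})

test_that("bins with prior odds score zero and coverage errors are raised", {
  ids <- sprintf("y%03d", 1:110)
  pairs <- scored_pairs(rep("hub", 110), ids, seq(110, 1), code = "CC")
  # every 11-pair stretch holds 1 positive and 10 negatives = prior odds
  lab <- rep(c("P", rep("N", 10)), 10)
  gold <- gold_standard(data.frame(gene_a = "hub", gene_b = ids[lab == "P"]),
                        data.frame(gene_a = "hub", gene_b = ids[lab == "N"]))
  curve <- calibrate_lls(pairs, gold, n_bins = 10, min_bin_count = 11)
  expect_equal(curve$bins$lls, rep(0, nrow(curve$bins)), tolerance = 1e-12)

  few <- scored_pairs("a", "b", 1, code = "CC")
  expect_error(calibrate_lls(few, gold, 10, 10), "insufficient gold")
})

test_that("planted score separation yields non-increasing LLS down the bins", {
  # average over seeds: positives drawn stochastically above negatives
  mean_spearman <- mean(vapply(1:5, function(s) {
    set.seed(s)
    ids <- sprintf("z%04d", 1:600)
    lab <- rep(c("P", "N"), c(150, 450))
    sc <- ifelse(lab == "P", rnorm(600, 1.2, 1), rnorm(600, 0, 1))
    pairs <- scored_pairs(rep("hub", 600), ids, sc, code = "CX")
    gold <- gold_standard(data.frame(gene_a = "hub", gene_b = ids[lab == "P"]),
                          data.frame(gene_a = "hub", gene_b = ids[lab == "N"]))
    curve <- calibrate_lls(pairs, gold, n_bins = 6, min_bin_count = 20)
    cor(seq_len(nrow(curve$bins)), curve$bins$lls, method = "spearman")
  }, numeric(1)))
  expect_gt(mean_spearman, 0.9)
})

test_that("apply_calibration looks up, clamps and drops non-positive LLS", {
  bins <- data.frame(lower = c(0, 1, 2), upper = c(1, 2, 3),
                     n_pos = c(1L, 5L, 20L), n_neg = c(20L, 5L, 1L),
                     lls = c(-1, 0.5, 2))
  curve <- calibration_curve("CX", bins, 26, 26)
  sp <- scored_pairs(c("a", "a", "a", "a"), c("b", "c", "d", "e"),
                     c(1.5, 2.5, -7, 99), code = "CX")
  net <- apply_calibration(sp, curve)
  w <- setNames(net$edges$weight, net$edges$gene_b)
  expect_equal(unname(w["b"]), 0.5)     # inside bin 2
  expect_equal(unname(w["c"]), 2)       # inside bin 3
  expect_false("d" %in% names(w))       # below lowest bin -> lls -1, dropped
  expect_equal(unname(w["e"]), 2)       # above all edges -> top bin

  all_neg <- calibration_curve("CX", transform(bins, lls = c(-1, -2, 0)),
                               26, 26)
  expect_equal(nrow(apply_calibration(sp, all_neg)$edges), 0L)

  wrong <- scored_pairs("a", "b", 1, code = "CC")
  expect_error(apply_calibration(wrong, curve), "fitted for CX")
})

test_that("calibration curves round-trip through TSV", {
  fx <- planted_calibration_fixture()
  curve <- calibrate_lls(fx$pairs, fx$gold, n_bins = 10, min_bin_count = 10)
  p <- tempfile()
  write_calibration_curve(curve, p)
  back <- read_calibration_curve(p)
  expect_equal(back$evidence_code, curve$evidence_code)
  expect_equal(back$bins$n_pos, curve$bins$n_pos)
  expect_equal(back$bins$lls, curve$bins$lls, tolerance = 1e-5)
  expect_equal(back$prior_pos, curve$prior_pos)
})

test_that("weighted-sum integration follows the rank-discounted formula", {
  n1 <- toy_network(list("a", "b", 3.0))
  n2 <- toy_network(list("a", "b", 2.0))
  n3 <- toy_network(list("a", "b", 1.0))

  single <- integrate_weighted_sum(list(n1), integration_params(2, 0))
  expect_equal(single$edges$weight, 3.0)

  ws <- integrate_weighted_sum(list(n1, n2, n3), integration_params(1, 0))
  expect_equal(ws$edges$weight, 3 + 2 / 1 + 1 / 2)

  # D -> Inf approaches the max component
  big_d <- integrate_weighted_sum(list(n1, n2, n3),
                                  integration_params(1e9, 0))
  expect_equal(big_d$edges$weight, 3.0, tolerance = 1e-8)

  # T excludes weak components entirely
  cut <- integrate_weighted_sum(list(n1, n2, n3),
                                integration_params(1, 2.5))
  expect_equal(cut$edges$weight, 3.0)

  expect_error(integrate_weighted_sum(list(), integration_params()),
               "length\\(nets\\) >= 1")
})

test_that("integration is permutation-invariant and dominates the components", {
  set.seed(21)
  nets <- replicate(4, random_network(12, 0.5), simplify = FALSE)
  p <- integration_params(1.5, 0.2)
  a <- integrate_weighted_sum(nets, p)
  b <- integrate_weighted_sum(rev(nets), p)
  expect_equal(a$edges, b$edges)
  # WS >= max component LLS for every retained pair, equality iff one
  # component passes T
  key <- function(n) paste(n$edges$gene_a, n$edges$gene_b)
  comp <- do.call(rbind, lapply(nets, function(n) n$edges))
  comp <- comp[comp$weight >= p$T, ]
  best <- tapply(comp$weight, paste(comp$gene_a, comp$gene_b), max)
  cnt <- tapply(comp$weight, paste(comp$gene_a, comp$gene_b), length)
  expect_true(all(a$edges$weight >= best[key(a)] - 1e-12))
  one <- names(cnt)[cnt == 1]
  expect_equal(a$edges$weight[key(a) %in% one],
               as.numeric(best[key(a)[key(a) %in% one]]))
  expect_true(all(a$edges$weight[!key(a) %in% one] >
                    best[key(a)[!key(a) %in% one]]))
})

test_that("grid search selects parameters deterministically with tie rules", {
  # uniform weights: any T below the weight is equivalent -> tie rule
  # returns the largest D and the largest T with non-empty output
  ed <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                   weight = 2)
  net <- gene_network(ed)
  gold <- gold_standard(data.frame(gene_a = "a", gene_b = c("b", "c")),
                        data.frame(gene_a = "b", gene_b = "c"))
  sel <- optimize_integration_params(list(net), gold,
                                     D_grid = c(1, 2, 4),
                                     T_grid = c(0, 1, 9))
  expect_equal(sel$D, 4)
  expect_equal(sel$T, 1)

  sel2 <- optimize_integration_params(list(net), gold,
                                      D_grid = c(1, 2, 4),
                                      T_grid = c(0, 1, 9))
  expect_equal(unclass(sel)[c("D", "T")], unclass(sel2)[c("D", "T")])
})

test_that("grid search excludes a pure-noise component via the cutoff", {
  set.seed(31)
  ids <- sprintf("q%03d", 1:60)
  pos <- t(combn(ids[1:12], 2))
  neg <- t(combn(ids[41:60], 2))
  gold <- gold_standard(data.frame(gene_a = pos[, 1], gene_b = pos[, 2]),
                        data.frame(gene_a = neg[, 1], gene_b = neg[, 2]))
  informative <- gene_network(data.frame(
    gene_a = c(pos[, 1], neg[1:30, 1]), gene_b = c(pos[, 2], neg[1:30, 2]),
    weight = c(runif(nrow(pos), 2, 3), runif(30, 1.2, 1.9))))
  all_pairs <- t(combn(ids, 2))
  noise <- gene_network(data.frame(gene_a = all_pairs[, 1],
                                   gene_b = all_pairs[, 2],
                                   weight = runif(nrow(all_pairs), 0.1, 1)))
  sel <- optimize_integration_params(list(informative, noise), gold,
                                     D_grid = 1, T_grid = c(0, 1.05))
  expect_equal(sel$T, 1.05)  # the noise component's range is excluded
})
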