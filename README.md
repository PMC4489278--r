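# funcnet

Integrated functional gene networks and network-based prioritization of
genes, functions and disease candidates — an organism-agnostic toolkit
for the approach behind integrated co-functional networks such as the
*Drosophila* and yeast probabilistic gene networks.

## The problem

Reverse-genetics screens are expensive and noisy; ranking candidate
genes before screening makes them far more efficient. A well-calibrated
functional gene network supports this by *guilt by association*: genes
close in the network to the known genes of a trait (the **guide
genes**) are likely to participate in the same process. `funcnet`
builds such networks from heterogeneous evidence and runs the full
prioritization and assessment battery on them, for users who study
gene-to-function and gene-to-phenotype mapping in any organism with a
consistent gene-id namespace.

## The method

1. **Raw evidence scores.** Each evidence type scores gene pairs on its
   own scale: Pearson correlation for co-expression (`infer_coexpression`),
   −log10 hypergeometric tail probabilities for co-citation and domain
   co-occurrence (`infer_cocitation`, `infer_domain_cooccurrence`),
   mutual information between phylogenetic profiles
   (`infer_phylo_profile`), co-adjacency fraction of orthologs in
   reference genomes (`infer_gene_neighborhood`), and orthology
   transfer of networks from other species (`transfer_orthology`).
   Pre-scored protein-interaction edge lists are read directly.

2. **Log-likelihood calibration.** A gold standard of positive
   (co-annotated to a pathway/GO term of eligible size) and negative
   (annotated, sharing nothing) gene pairs is derived from annotations
   (`derive_gold_standard`). Raw scores are binned (equal-frequency,
   ≥ `min_bin_count` gold pairs per bin) and each bin receives a
   log-likelihood score in nats (`calibrate_lls`):

   `LLS = ln[ (P(L|E) / ¬P(L|E)) / (P(L) / ¬P(L)) ]`

   — the log ratio of the bin's positive:negative odds to the prior
   odds. Every scored pair then inherits its bin's LLS
   (`apply_calibration`); non-positive LLS edges are dropped.

3. **Weighted-sum integration.** For each pair, component LLS values
   ≥ `T` are sorted descending (`L0 ≥ L1 ≥ …`) and combined as

   `WS = L0 + Σ_{i≥1} L_i / (D·i)`

   a modified naive-Bayes sum whose degradation divisor `D` discounts
   correlated agreement (`integrate_weighted_sum`; `D`, `T` tunable by
   grid search with `optimize_integration_params`).

4. **Prioritization.** Gene ranking by the **direct neighborhood** sum
   of edge weights to guides or by **network diffusion**
   (Gaussian-field label propagation solving `(I − αS)f = y` on the
   symmetrically normalized weight matrix); function ranking by
   neighbor-weight sums per annotation term; **spatiotemporal-specific
   networks** (STNs) keeping only edges whose endpoints are expressed
   (mean BPKM > 1) in a stage or tissue; and a cross-species disease
   prioritizer with orthology mapping and support-gene tiers.

5. **Assessment.** Precision–recall over ranked edges against gold
   pairs, guide-retrieval ROC/AUC, top-k discovery rates with fold
   enrichment, hypergeometric gene-set enrichment with BH correction,
   degree-preserving null networks, and Wilcoxon signed-rank
   comparisons.

Seeded generators (`synth_spec`, `gen_modular_network`,
`gen_evidence_bundle`, …) produce toy data with planted functional
modules so the whole pipeline is testable offline.

## Worked example

```r
library(funcnet)

spec <- synth_spec(seed = 7)              # 300 genes, 10 planted modules
sim  <- gen_modular_network(spec)
ann  <- gen_annotations(sim$membership, seed = 17)
gold <- derive_gold_standard(subset_annotations(ann, source = "primary"))
ev   <- gen_evidence_bundle(sim$membership, spec)

built <- build_integrated_network(ev, gold)
built$curves$CX
#> calibration_curve[CX]: 10 bins, priors 910 pos / 8820 neg
#>       lower    upper n_pos n_neg    lls
#> 1  -0.41596 -0.19597     0   973 -4.610
#> ...
#> 10  0.52330  0.99787   910    63  4.942
built$network
#> gene_network: 300 genes, 23668 links
#>   weights: 0%=0.0707 25%=0.0934 50%=0.116 75%=0.357 100%=13.5

mod1 <- subset(sim$membership, !is.na(module) & module == "M01")$gene
res  <- prioritize_genes(built$network, mod1[1:10], algorithm = "diffusion")
res
#> prioritization_result (diffusion): 300 genes, 10 guides, AUC = 1.000
#>    gene    score rank is_guide
#> 1 g0006 2.476700    1     TRUE
#> ...
```

Reading the output: the co-expression calibration curve maps raw
correlations to LLS — only the top correlation bin carries positive
evidence (LLS ≈ 4.9 nats, bin odds 910:63 versus prior odds 910:8820).
The integrated network combines six calibrated layers; the
prioritization result ranks all 300 genes by diffusion from the ten
guide genes, and the guide-retrieval AUC of 1.0 says the guides
themselves are perfectly separated — the held-out half of the module
follows at the top of the candidate list.

A command-line wrapper over the same functions lives at
`inst/cli/funcnet.R` (subcommands `simulate`, `gold`, `lls`, `apply`,
`integrate`, `genes`, `functions`, `pr`, `null`); identical invocations
with identical seeds give byte-identical outputs.

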