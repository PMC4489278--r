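---
title: "Methods: calibrated network integration and prioritization in funcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated network integration and prioritization in funcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcnet)
```

This vignette is the package's account of its statistical machinery:
the models and their assumptions, the parameters that matter, the
numerical conventions, and what the synthetic fixtures do and do not
demonstrate.

## The probabilistic model

`funcnet` treats a functional gene network as a collection of
undirected gene pairs whose weights estimate the log odds that the pair
is *co-functional* — participates in the same biological process —
relative to the prior odds over all pairs. The estimate is built in
three stages.

### Raw evidence scores

Each evidence type produces a raw score that only needs to be
*monotone* in evidence strength, because calibration later re-maps it
onto a common scale:

* **Co-expression (CX)** — Pearson correlation between expression
  profiles within one data set. Zero-variance genes are excluded;
  negative correlations are retained and left to calibration, which
  assigns them negative log-likelihood scores if negatives are indeed
  depleted of co-functional pairs. With several independent expression
  series, each is scored and calibrated separately, so series-specific
  artifacts cannot masquerade as genome-wide signal.
* **Co-citation (CC)** and **domain co-occurrence (DC)** — the −log10
  upper-tail hypergeometric probability of the observed overlap of two
  genes' document or domain sets given their set sizes and the
  universe size. Computed on the log scale (`phyper(..., log.p =
  TRUE)`) so extreme overlaps never overflow to infinity.
* **Phylogenetic profiles (PG)** — plug-in mutual information (bits)
  between binary presence/absence profiles across reference genomes.
  All-present and all-absent profiles carry no information and are
  excluded.
* **Gene neighborhood (GN)** — the fraction of reference genomes, among
  those where both genes have orthologs, in which the orthologs lie
  within `window` gene-order positions. Pairs co-present in fewer than
  two genomes are unscorable and omitted.
* **Orthology transfer (XFER)** — source-species edges projected
  through a many-to-many ortholog map; duplicate target pairs keep the
  maximum score and self-pairs are suppressed.

The concrete statistics are fixed as this package's contract; they
follow the method lineage that integrated co-functional networks in
yeast, worm and fly have used, with deliberately conservative choices
where the originals are unpublished.

### Log-likelihood calibration

`derive_gold_standard()` turns an annotation set into positive pairs
(co-annotated to at least one term with between `min_term = 3` and
`max_term = 500` genes) and negative pairs (annotated genes sharing no
eligible term). The size bounds exclude terms too small to be reliable
and too broad to certify co-functionality; a pair sharing *only* an
oversized term is still treated as negative, the interpretation we
consider defensible — such terms (e.g. "metabolic process"-scale sets)
say almost nothing about shared function.

`calibrate_lls()` sorts gold-labeled scorable pairs by raw score and
cuts them into at most `n_bins = 10` equal-frequency bins, never
splitting tied scores and merging bins from the top of the score range
until each holds at least `min_bin_count = 10` gold pairs. Per bin,

$$LLS = \ln\frac{n_{pos}/n_{neg}}{prior_{pos}/prior_{neg}},$$

with add-one smoothing of the bin counts only when one class is empty.
Equal-frequency binning keeps per-bin variance comparable; the minimum
gold count keeps every LLS estimate away from pure noise at desk
scale. A step lookup (not a within-bin regression) maps scores to LLS:
scores below the lowest or above the highest bin clamp to the extreme
bins. Edges with $LLS \le 0$ are dropped at `apply_calibration()` —
network links are positive evidence by construction.

### Weighted-sum integration

For each pair, component LLS values at or above the cutoff `T` are
sorted descending, $L_0 \ge L_1 \ge \dots$, and combined as

$$WS = L_0 + \sum_{i \ge 1} \frac{L_i}{D \cdot i}.$$

This is a modified naive-Bayes combination: full naive Bayes would add
the component scores outright, overcounting because evidence types are
correlated (co-cited genes are often also co-expressed); the rank
discount $1/(D \cdot i)$ shrinks lower-ranked agreement instead of
modeling the dependence explicitly. `D = 1, T = 0` are the neutral
defaults; `optimize_integration_params()` grid-searches both against
the gold-standard precision–recall AUC, breaking ties toward larger
`D` and larger `T` (the least aggressive integration compatible with
the best benchmark). The PR-AUC used for this comparison is average
precision with the *total* gold-positive count in the denominator, so
a network that retains few positives cannot outscore one that ranks
them all well.

## Prioritization algorithms

**Direct neighborhood** scores a gene by the summed edge weights to the
guide genes (a guide sums its edges to the other guides). It sees only
first neighbors — precise near the guides, blind farther out.

**Network diffusion** solves the Gaussian-field label-propagation
system $(I - \alpha S)f = y$ with $S = D_g^{-1/2} W D_g^{-1/2}$ and
$y$ the guide indicator. `alpha = 0.9` (propagation strength,
dimensionless) follows common label-propagation practice: high enough
to exploit long-range structure, below 1 to keep the system
diagonally dominant and the solution unique. The solver uses a sparse
exact solve up to 2000 nodes and otherwise fixed-point iteration to a
maximum residual of `tol = 1e-8`; the two agree to well below 1e-6 on
the test fixtures, and isolated guides degenerate gracefully to their
own label with a warning.

Ranking is always by descending score with ties broken
lexicographically by gene id, so outputs are deterministic and
byte-reproducible. Guide-retrieval AUC is plain retrieval (guides
scored with self excluded, all other networked genes as negatives),
not leave-one-out re-fitting — a cheap, slightly optimistic
predictability gauge.

**Function prioritization** ranks terms by the summed weight of the
query's neighbors annotated with each term; the query's own
annotations never contribute, so the ranking is a genuine prediction.

**Spatiotemporal networks (STNs)** keep an edge iff both endpoints are
expressed — mean expression over the context's samples above
`threshold = 1` (BPKM-scale) — in that stage or tissue. The mean is
the simplest aggregate consistent with expression units; genes missing
from the expression matrix are conservatively treated as not
expressed. Context-specific links are reported as edges present in
exactly one context of their kind; this definition is the package's
own choice among several defensible ones.

**Disease prioritization** maps guide genes from the disease namespace
to the union of their model-organism orthologs, prioritizes on the
model-organism network, and maps candidates back (a disease gene
inherits the rank of its best network candidate). First-tier
candidates are exactly `second_tier ∩ support`, preserving rank
order — network evidence and external genetic evidence must agree.

## Assessment conventions

* Precision–recall walks ranked edges, skipping unlabeled pairs in the
  precision denominator — only gold-labeled pairs are benchmarked.
  Coverage mode replaces the x axis with the cumulative fraction of the
  gene universe seen, for validation sets whose positives are too
  numerous for recall.
* ROC AUC uses the Mann–Whitney rank-sum identity; ties count 1/2.
* The null model rewires by double-edge swaps (self-loops and
  multi-edges rejected), preserving every degree exactly, then
  shuffles the weights over the rewired edges; it is seeded and
  reproducible. Whether an edge-, weight- or label-shuffling null is
  "the" right baseline is underdetermined; degree-preserving rewiring
  is the most conservative standard choice.
* The Wilcoxon signed-rank comparison drops zero differences and uses
  the exact distribution for n ≤ 25 without ties, otherwise the normal
  approximation with continuity correction (delegated to
  `stats::wilcox.test`, cross-checked in the tests against sign-pattern
  enumeration).
* Multiple testing uses Benjamini–Hochberg.

## What the synthetic fixtures emulate — and what they do not

The generators plant `n_modules = 10` modules of `module_size = 20`
genes among `n_genes = 300`, connect within-module pairs with
`p_in = 0.3` versus `p_out = 0.01` background, give each module a
latent expression profile (noise `noise_sd = 0.2` around it) over
`n_samples = 28` samples spread round-robin across 4 stages and 10
tissues, and derive document, domain, profile and gene-order tables
whose within-module pairs score stochastically higher. One layer is
pure noise. These sizes keep the full pipeline under a couple of
seconds per seed while leaving enough gold pairs (~900 positives,
~8800 negatives at coverage 0.7) for stable 10-bin calibration; they
are the package's fixed study conditions, not tuning knobs.

Passing on these fixtures shows that the machinery is *correct* —
calibration recovers planted signal and flattens noise, integration
dominates single layers, diffusion and direct retrieval recover
held-out module members, silenced modules vanish from the right STN.
It does **not** show field performance on real genomes: real evidence
layers are far sparser and their errors are correlated; real modules
overlap and vary in size; microarray noise is not Gaussian; annotation
bias links the gold standard to the literature the evidence comes
from. Genome-scale benchmarking requires the external resources the
published networks used.

## Degenerate inputs and numerical conventions

Weights are written with 6 significant digits and a canonical pair and
row order, making file output byte-stable. Duplicate edges collapse
to the maximum weight (scores are confidences; maximum is conservative
under re-listing). Self-loops are dropped with a warning on read.
Hypergeometric scores are computed in log space. Mutual information
clips its tiny negative floating-point residue at zero. Empty guide
sets diffuse to all-zero scores; an all-non-positive calibration curve
yields an empty network; a gold standard missing one class is an
error, not a silent zero.

## Known limitations

* Evidence dependence is handled only through the rank discount `D`,
  not modeled; strongly redundant layers still inflate integrated
  scores somewhat.
* The calibration step function is piecewise constant; a monotone
  continuous fit (e.g. isotonic regression) could use the raw scale
  better and is intentionally out of scope.
* Guide-retrieval AUC shares information between guides; it
  overestimates prospective performance relative to cross-validation.
* The gold standard inherits annotation bias; calibrated scores are
  odds relative to *annotated* biology.
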