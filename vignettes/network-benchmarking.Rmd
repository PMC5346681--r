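---
title: "Benchmarking interactome networks for gene prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking interactome networks for gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprio)
```

## The model

`netprio` operationalizes the hub hypothesis: in protein-protein interaction
(PPI) networks, highly connected and highly central genes are enriched for
disease genes, so centrality alone — with no functional annotation — should
partially recover a curated disease gene catalogue. The package treats this
as a *benchmarking* problem: given several interactome maps and one gold
standard, which map's centrality ranking recovers the gold standard best,
and how trustworthy is that comparison?

Networks are simple undirected graphs over opaque gene identifiers.
Cleaning is deliberately minimal and mirrors standard interactome practice:
self-loops are dropped, and duplicate records — including mirrored
`(a,b)`/`(b,a)` pairs — collapse to one undirected edge. Edge weights or
evidence columns are ignored; all maps are compared as unweighted graphs.
By default the gene universe is the union of edge endpoints; an explicit
node list can declare isolated genes when a map's published gene count
includes them.

Two centralities are supported. **Degree** is the number of distinct
partners. **Betweenness** of gene $i$ is

$$BC_i = \sum_{j<k} \frac{g_{jk}(i)}{g_{jk}},$$

where $g_{jk}$ counts shortest paths between $j$ and $k$ and $g_{jk}(i)$
those passing through $i$; disconnected pairs contribute nothing. We report
*unnormalized* sums: any constant normalization cancels in a within-network
ranking, and the unnormalized value is the direct reading of the formula.
Computation uses Brandes' exact algorithm (via igraph), but the contract is
the formula itself — the test suite checks it against an independent
brute-force BFS path-counting oracle on hundreds of random small graphs.
Disconnected networks are allowed; no largest-component restriction is
applied.

Rankings must be total and reproducible, so ties are broken
deterministically: lexicographically by identifier (the default, in C-locale
order so results do not depend on the session locale), or by a seeded random
shuffle when a tie-neutral ranking is wanted. Degree ties are common in
sparse maps, so the tie rule genuinely matters for which genes enter a
top-$k$ block; every result object records the rule and seed used.

## Evaluation against a gold standard

Positives are the gold-standard genes *present in the network*
(`restrict_to_network()`); all remaining network genes are negatives. At
threshold fraction $t$, the first $\lfloor tN \rfloor$ ranked genes are
predicted positives, and

$$\mathrm{recall} = \frac{TP}{TP+FN}, \quad
  \mathrm{accuracy} = \frac{TP+TN}{N}, \quad
  \mathrm{specificity} = \frac{TN}{TN+FP}.$$

Choices worth making explicit:

* **Floor, not round.** The predicted-positive count is
  $\lfloor tN \rfloor$, computed as `floor(t*N + 1e-9)` to neutralize
  binary-float artifacts (`0.29 * 100` is `28.999…` in doubles). The
  alternative (rounding) moves at most one gene.
* **Recall denominator.** Within-network recall (denominator $TP+FN$) is
  the default, since the negatives are defined within the network. When
  comparing curves *across* networks of very different coverage, that
  denominator flatters small maps; `positives_total=` switches the recall
  denominator to a common value (e.g. the full gold-standard size) for a
  fair cross-map reading. Accuracy and specificity are unaffected.
* **Undefined metrics stay undefined.** A zero denominator yields `NA`
  with a note, never a silent 0.
* The default threshold grid is 1% steps from 0 to 100%.

## Permutation-null enrichment

Observed recovery at a cutoff is only interpretable against what random
ranking achieves. The null randomly permutes the same gene universe
`n_perm` times (default 1,000) and records recovery in the top
$\lfloor tN \rfloor$ block; this is sampling without edge rewiring, so the
null distribution is exactly hypergeometric with mean
$\lfloor tN \rfloor \cdot |P| / N$ — a closed form the tests use to verify
calibration to within 3 standard errors. Fold enrichment is the observed
recovered proportion over the null mean proportion. The empirical p-value
uses the add-one estimator $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) /
(n_{perm}+1)$, which cannot report 0 and is honest about the resolution
1,000 permutations afford (minimum $\approx 10^{-3}$). Default cutoff:
the top 10%.

## Robustness to map incompleteness

Interactome maps are incomplete, so a credible ranking method must be stable
to missing edges. `downsample_edges()` retains a uniform random edge subset
of size $|E| - \mathrm{round}(f\,|E|)$ while keeping the gene universe
fixed: genes that lose all interactions stay in the ranking with degree 0
(placed by the tie rule). Keeping $N$ and $|P|$ constant keeps the confusion
table denominators comparable across removal fractions — the quantity being
tested is the ranking, not the census. `robustness_profile()` repeats this
over a fraction grid (default 0–0.9 by 0.1) with replicates (default 10,
each cell seeded deterministically from the master seed and its grid
indices) and re-evaluates at a fixed cutoff (default the same 10% used for
enrichment). Degree is the default re-ranking metric: it is the robust,
fast choice, and the phenomenon of interest — metric steadiness under
moderate edge loss — is a degree-ranking property; betweenness is available
for completeness.

## Cross-network comparison

Absolute ranks are incomparable across maps of different size, so the
cross-network table uses the **relative rank**: rank divided by network
size, in $(0,1]$, smaller = more central; genes absent from a map get `NA`,
never an imputed value. `top_k_overlap()` takes the focal map's top $k$
(default 100) and reports how many appear in at least one other map and
which are *also* centrally ranked elsewhere. "Centrally ranked elsewhere"
needs a threshold; it is a parameter (`low_rank_cut`, default 0.10 to match
the evaluation cutoff) rather than a hidden constant, and every reported
summary prints the cut used, because the shared-vs-unique split can change
qualitatively with it.

## Mutation-frequency validation

An orthogonal check on a ranking is whether its top genes are mutated more
often in tumors than its bottom genes. Only a minimal MAF dialect is
parsed — gene symbol, tumor sample barcode, variant classification — since
those three columns determine the statistic; mutation frequency of a gene in
a cancer type is the number of *distinct* mutated samples over the total
sample count (duplicate calls in one sample count once). Totals can be
declared per cancer type; otherwise they are inferred from the distinct
barcodes observed, which is a lower bound since mutation-free samples leave
no records. All variant classes count by default (an exclude-silent switch
exists because practice varies). Top-vs-bottom groups are compared per
cancer type with the Wilcoxon rank-sum test, one-sided (`top > bottom`) by
default because the hypothesis is directional; genes with no records enter
at frequency 0. Exact p-values are used for small untied samples, the
normal approximation with tie correction otherwise; frequency data are
heavily tied, so the tie-corrected approximation is the common path. The
degenerate all-identical case reports p = 1 with a note instead of erroring.

## The synthetic-data generator

The generator produces data with exactly the structure the analysis assumes,
so that every stage has a recoverable ground truth:

* **Networks.** Preferential attachment (default, `m = 2`) gives the
  heavy-tailed degree distributions characteristic of PPI maps and a known
  closed-form edge count ($2n-3$ at $m=2$), which the tests assert. A
  configuration model with degree exponent $\gamma$ (default 2.5, the
  middle of the range reported for interactomes) is the alternative when
  the degree distribution itself must be controlled.
* **Positives.** Planted by weighted sampling without replacement with
  weight $(\mathrm{degree}+1)^\beta$. $\beta$ is the single effect-size
  knob tying the generator to the hub hypothesis: $\beta=0$ is a uniform
  draw (no signal), $\beta=2$ concentrates positives on hubs strongly
  enough that degree ranking recovers them. The $+1$ keeps isolated genes
  sampleable. R's weighted sampling is sequential, so inclusion
  probabilities are only approximately proportional to the weights; that
  approximation is irrelevant to the generator's purpose (creating a
  degree-correlated positive class of tunable strength).
* **Mutations.** Each (gene, sample) pair mutates independently — at
  `planted_rate` for positives, `baseline_rate` otherwise (defaults 0.10
  vs 0.01, echoing the contrast between recurrently mutated cancer genes
  and the background somatic rate at typical cohort sizes; default 100
  samples per cancer type). Output is the same minimal MAF dialect the
  parser reads, with the true per-cancer sample total carried alongside.

What the generator does **not** emulate: assay-specific false negatives and
study bias (literature maps oversample well-studied genes), spoke/matrix
expansion of complexes, correlated mutations, mutation-rate covariates
(gene length, replication timing). Passing tests therefore demonstrate that
the pipeline's statistics are correct and well calibrated under the stated
model — not that any particular real map will show a particular fold
enrichment.

## Problem sizes, seeds and numerical choices

The test suite and the acceptance script run the statistical checks at
1,000-gene networks with 50 planted positives, 1,000 permutations, 10
removal replicates, and 100-replicate detection-rate studies — sizes at
which the Monte-Carlo tolerances used (3 standard errors, binomial 99%
intervals) are meaningful while the whole suite stays fast on one CPU.
Every stochastic step takes an explicit seed, and grid cells derive
sub-seeds from (master seed, grid indices), so profiles and pipeline runs
are byte-reproducible. Output writers emit canonical orderings
(lexicographic edge pairs, sorted tables) so that equal results produce
identical files, and pipeline stages write a provenance JSON (parameters +
seed) beside their outputs.

Known limitations: no weighted or directed networks, no alternative
centralities (closeness, eigenvector, random-walk methods), no rank
aggregation across maps, no mutation-significance modeling beyond the
rank-sum comparison, and no identifier mapping — inputs are assumed
pre-mapped to a common namespace.
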