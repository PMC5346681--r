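# netprio

Benchmarking protein interactome networks for cancer gene prioritization.

## The problem

Highly connected genes ("hubs") in protein-protein interaction (PPI)
networks are enriched for essential and disease-associated genes, so network
centrality is a natural, annotation-free way to prioritize candidate cancer
genes. But published human interactome maps differ enormously — literature-
curated, computationally predicted, and systematic experimental maps cover
different genes with different biases — and the practical question for an
analyst is *which map gives the most predictive ranking, and how stable is
that ranking to the map's incompleteness?*

`netprio` answers this with a comparative benchmarking pipeline aimed at
computational biologists who have one or more PPI edge lists and a
gold-standard gene set (e.g. the Sanger Cancer Gene Census):

1. **Centrality ranking.** Genes are ranked by degree (number of partners)
   or betweenness centrality, defined for gene *i* as
   *BC<sub>i</sub> = Σ<sub>j&lt;k</sub> g<sub>jk</sub>(i) / g<sub>jk</sub>*,
   the sum over gene pairs of the fraction of shortest paths passing
   through *i* (unnormalized, computed exactly by Brandes' algorithm).
2. **Threshold-sweep evaluation.** Taking the top fraction *t* of the
   ranking as predicted positives, the pipeline computes
   recall = TP/(TP+FN), accuracy = (TP+TN)/N, specificity = TN/(TN+FP)
   for all thresholds. Positives are gold-standard genes present in the
   network; the remaining network genes are negative controls.
3. **Permutation-null enrichment.** Genes are randomly re-ranked (1,000
   times by default); fold enrichment is the observed proportion of
   gold-standard genes recovered in the top 10% divided by the mean
   proportion under random rankings, with an add-one empirical p-value.
4. **Robustness to incompleteness.** Increasing fractions of interactions
   are removed at random, genes re-ranked, and the metrics recomputed —
   quantifying whether predictions survive map incompleteness.
5. **Cross-network comparison.** Relative rank (rank / network size) of the
   focal network's top genes in every other network, plus top-k overlap
   counts.
6. **Mutation-frequency validation.** From MAF-format somatic mutation
   tables, per-gene mutation frequency (mutated samples / total samples per
   cancer) is compared between top- and bottom-ranked genes by a one-sided
   Wilcoxon rank-sum test.

A seeded synthetic-data generator (scale-free networks via preferential
attachment or a power-law configuration model, positives planted with
tunable hub bias β, mutation tables with planted rate differences) makes the
entire pipeline testable without any downloads.

## Worked example

```r
library(netprio)

# a 1000-gene scale-free network with 50 hub-biased "cancer genes"
net  <- generate_network(1000, seed = 42)
gold <- plant_positives(net, 50, beta = 2, seed = 7)

rk <- rank_genes(degree_scores(net))
en <- permutation_null(rk, gold, fraction = 0.10, n_perm = 1000, seed = 3)
print(en)
#> enrichment at top 10%: recovered 26 positives (null mean 4.97); fold = 5.23,
#> empirical p = 0.000999 (1000 permutations, seed 3)
```

Recovering 26 of 50 planted genes in the top-ranked 10% — 5.2-fold more than
the ~5 expected under random ranking, with the smallest p-value 1,000
permutations can resolve — confirms that degree ranking finds hub-planted
signal. The full study (curves, robustness, cross-network overlap, mutation
tests) runs as:

```r
res <- run_full(list(mynet = net), gold, out_dir = "results")
res$compare$summary   # one row per network x metric, best recall first
```

Real data enter through `read_edge_list()` (two-column edge list, `#`
comments; self-loops and redundant pairs are cleaned off with a logged
count), `read_gene_set()` (one ID per line), and `read_maf()` (minimal MAF
dialect: `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`).

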