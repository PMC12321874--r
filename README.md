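# specfp — spectral fingerprinting of pathway network collections

`specfp` compares *collections* of biological pathway networks — for
example, the KEGG pathways enriched in two co-occurring disorders — by the
spectra of their adjacency matrices, and then explains *which genes and
pathways drive the difference*. It is aimed at systems-biology analyses
where each condition is represented not by one network but by a set of
genes-only, undirected, unweighted pathway graphs keyed by NCBI gene IDs.

## The methods in brief

**Spectral comparison of graph sets.** Each graph's adjacency spectrum
λ₁ ≤ … ≤ λₙ is smoothed into a density on a grid shared by the whole
comparison (Gaussian kernels, Silverman's rule-of-thumb bandwidth
h = 0.9·min(σ̂, IQR/1.34)·n^(−1/5)). Two sets of graphs are compared by the
Jensen–Shannon divergence between their mean spectral densities,

&nbsp;&nbsp;&nbsp;&nbsp;JS(p, q) = ½ KL(p, m) + ½ KL(q, m),  m = (p + q)/2,

with significance from a permutation null that re-partitions the pooled
graphs (`takahashi_test()` for two sets, `anogva()` for k ≥ 2 groups).
Pooled collections are clustered by pairwise JS *distance* (√JS) under
complete-linkage agglomeration, with degree / betweenness / closeness
distribution baselines scored against known labels by the adjusted Rand
index.

**Gene distinctiveness and the fingerprint.** After clustering, every gene
g gets a per-cluster degree profile p_k — the distribution of its degree
across the cluster-k pathways containing it (α = 0.5 pseudocount
smoothing). Its distinctiveness is

&nbsp;&nbsp;&nbsp;&nbsp;D^g[k] = min_{l≠k} KL(p_k, p_l),

the divergence against the most similar opposing cluster. The top-D^g
"driving genes" D_k of each cluster induce a **network fingerprint**: every
pathway S_k is ranked by the Jaccard similarity J(D_k, S_k) =
|D_k ∩ S_k| / |D_k ∪ S_k|, sorted by KEGG class, and two conditions'
fingerprints can be differenced pathway-by-pathway and class-by-class.

**Inputs.** KEGG KGML XML (`parse_kgml()` builds the genes-only graph:
compounds contracted through, complexes expanded, multi-gene entries
split), tab-separated edge lists, or GraphML. Seeded synthetic generators
(`sample_graph_set()`, `build_planted_collection()`, `synth_kgml()`)
provide ground-truthed collections for calibration and testing.

## Worked example

A degree-confounded benchmark: ring lattices and random 4-regular graphs
have *identical* degree distributions, so degree-based comparison is blind
to their difference — the spectrum is not.

```r
library(specfp)

ring <- sample_graph_set("ring_lattice", 10, 50, k = 2, seed = 1, label = "ring")
reg  <- sample_graph_set("k_regular",  10, 50, k = 4, seed = 2, label = "reg")

takahashi_test(ring, reg, n_permutations = 1000, seed = 1)
#> <graph_test> takahashi: JS statistic = 0.0255209, p = 0.000999 (1000 permutations, seed 1)
#>   group sizes: 10, 10

pooled <- graph_set(c(unname(ring$graphs), unname(reg$graphs)), "pooled")
compare_methods(pooled, rep(c("ring", "reg"), each = 10), k = 2)
#>        method ari
#> 1    spectral   1
#> 3 betweenness   1
#> 4   closeness   1
#> 2      degree   0
```

The two models are significantly divergent (p ≈ 0.001, the add-one floor at
1000 permutations) and spectral clustering recovers the two groups exactly
(ARI = 1) while the degree baseline cannot (ARI = 0).

Gene prioritization on a planted two-cluster collection, where synthetic
gene `990001` has degree 2 in every cluster-A pathway hosting it but degree
12 in cluster B:

```r
pc <- build_planted_collection(n_pathways = 8, n = 30, p = 0.15,
                               degree_a = 2, degree_b = 12, seed = 1)
sc <- gene_scores(list(pc$a, pc$b))
ska <- sc[sc$cluster == "plantedA", ]
head(ska[order(-ska$distinctiveness), c("gene", "distinctiveness")], 3)
#>    gene distinctiveness
#>  990001       1.9982461
#>  900004       0.7965002
#>  900016       0.6841090

fp <- fingerprint(list(pc$a, pc$b), scores = sc, top_n = 10)
head(fp[fp$cluster == "plantedA", ], 3)
#>    pathway_id  cluster kegg_class   jaccard flagged
#>  plantedA_001 plantedA    unknown 0.3225806    TRUE
#>  plantedA_002 plantedA    unknown 0.3225806    TRUE
#>  plantedA_004 plantedA    unknown 0.3225806    TRUE
```

The planted gene tops the distinctiveness ranking (D^g ≈ 2.0 nats against a
background below 0.8), and exactly its host pathways attain the maximum
Jaccard score — the fingerprint flags them.

`run_pipeline()` chains everything (k-group test, pairwise tests against a
reference group, clustering of significant pairs gated at α = 0.05, gene
scores, fingerprints, differences) into a directory of CSV/JSON artifacts;
`inst/scripts/specfp` exposes the same steps as shell subcommands.

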