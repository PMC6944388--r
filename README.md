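# aptanet

Similarity-network analysis of riboswitch aptamer conservation.

## What this is for

The glycine riboswitch usually carries *two* homologous ligand-binding
aptamers in tandem (aptamer-1 at the 5′ end, aptamer-2 at the 3′ end);
a large minority of glycine riboswitches are *singletons* — one functional
aptamer plus a degenerate "ghost" stem, 3′ of the aptamer (type-1) or 5′ of
it (type-2). Which tandem aptamer is more conserved, and how singletons
relate to tandems, are awkward questions for tree-based phylogenetics:
the aptamers are ~100 nt, primary-sequence conservation is weak, and
function lives in secondary structure.

`aptanet` is for RNA biologists and molecular evolution researchers who
want to answer such questions with similarity networks instead. Each
aptamer is a vertex, each pair an edge weighted by a pairwise
sequence+structure score, and the conservation of a group *g* at threshold
*t* is its surviving edge density

    D_g(t) = #{(i,j) in g, i<j : w_ij >= t} / C(|g|, 2),

the complementary empirical CDF of the group's edge-weight multiset. A more
conserved group keeps high density up to higher thresholds. On top of this
core the package provides:

* **Classification** of aptamer hits into architectures and contexts:
  e-value filter (≤ 1e-5), tandem calling (hits ≤ 100 intervening nt),
  transcriptional aptamer-1/aptamer-2 ordering, singleton typing by ghost
  position, nearest-downstream-gene (≤ 500 nt) context binning
  (GCV / TP / Gly_Met / Other), and species-level deduplication.
* **A built-in metric**: Needleman–Wunsch percent identity combined
  equally with a normalised mountain-function distance between Nussinov
  folds — plus ingestion of externally computed score matrices (square or
  long TSV, similarity- or distance-oriented).
* **Consensus communities** across four igraph algorithms (fast-greedy,
  Walktrap, edge betweenness, leading eigenvector): the core is the
  intersection of best-Jaccard-matched communities, augmented by nodes
  co-clustered in at least half the algorithms.
* **Cluster stability** by parametric bootstrap: replace 5% of edges
  (k removed, k added, |E| preserved), re-cluster, report mean Jaccard
  over 100 replicates.
* **Wilcoxon rank-sum** comparison of edge-weight multisets (exact by
  enumeration for small tie-free samples, tie- and continuity-corrected
  normal approximation otherwise).
* **A synthetic cohort generator** with ground truth, emulating
  context-dependent tandem-to-singleton degradation, so the whole pipeline
  is testable without any external data.

## Worked example

Generate a cohort (two contexts; in GCV-context riboswitches aptamer-1 is
conserved, in TP-context aptamer-2), classify it, and measure conservation:

```r
library(aptanet)
co  <- generate_cohort(cohort_params(seed = 1))
rec <- classify_aptamers(co$hits, co$ghost_hits, co$annotations, co$metadata)
table(rec$role, rec$context)
#>                   GCV TP
#>   singleton_type1  15  0
#>   singleton_type2   0 15
#>   tandem_apt1      30 30
#>   tandem_apt2      30 30
```

Every GCV singleton is type-1 and every TP singleton type-2 — the
context–type association the classifier is meant to recover. Now the
network:

```r
sm    <- pairwise_matrix(co$sequences)
net   <- build_network(sm, truth_groups(co$truth))
curve <- density_curve(net, c(75, 85, 95))
subset(curve, group %in% c("apt1/GCV", "apt2/GCV"))
#>  threshold  type    group n_possible n_surviving     density
#>         75 intra apt1/GCV        435         435 1.000000000
#>         75 intra apt2/GCV        435         257 0.590804598
#>         85 intra apt1/GCV        435         419 0.963218391
#>         85 intra apt2/GCV        435           1 0.002298851
#>         95 intra apt1/GCV        435          68 0.156321839
#>         95 intra apt2/GCV        435           0 0.000000000
```

In the GCV context the aptamer-1 group stays near-complete (96% density) at
a threshold where the aptamer-2 group has essentially dissolved — aptamer-1
is the conserved aptamer. The rank statistic agrees:

```r
wilcoxon_rank_sum(group_edge_weights(net, "apt1/GCV"),
                  group_edge_weights(net, "apt2/GCV"))
#> Wilcoxon rank-sum (normal_approx): W = 283941, n = 435+435, two-sided p = 2.046e-143
```

(p-values on pairwise edge weights are anti-conservative — edges sharing a
node are dependent; treat them as direction summaries and see the vignette.)
Consensus communities join conserved tandem aptamers with the matching
singleton type, and the bootstrap quantifies their stability:

```r
tg    <- threshold_graph(net, 85)
parts <- lapply(community_algorithms(), function(a) detect(tg, a))
cl    <- consensus_core(parts)
length(cl)                                  # 3 clusters
sapply(cl, function(x) length(x$augmented)) # 45 45 4
bootstrap_stability(tg, cl[[1]]$augmented, "random_walk",
                    stability_config(seed = 1))
#> stability_report: random_walk - 100 replicates, mean Jaccard 0.7907
```

The two 45-node clusters are exactly {30 tandem aptamer-1 + 15 singleton
type-1} in GCV and {30 tandem aptamer-2 + 15 singleton type-2} in TP — the
degraded partners join neither. `run_pipeline(list(seed = 1), "out_dir")`
runs all stages end to end, writing CSV outputs and an MD5 manifest.

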