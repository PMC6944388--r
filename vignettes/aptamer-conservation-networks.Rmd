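---
title: "Measuring riboswitch aptamer conservation with similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring riboswitch aptamer conservation with similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptanet)
```

## The problem

The glycine riboswitch is a bacterial cis-regulatory RNA whose ligand-binding
domain often occurs as a *tandem*: two homologous aptamers (aptamer-1 at the
5' end, aptamer-2 at the 3' end) jointly regulating one expression platform.
A large minority of glycine riboswitches are instead *singletons* -- one
functional aptamer plus a degenerate "ghost" stem that supports tertiary
contacts.  Singletons come in two geometries: type-1 carries the ghost 3' of
the aptamer, type-2 carries it 5'.

Which tandem aptamer is under stronger purifying selection, and how
singletons relate to tandems, are hard questions for conventional
phylogenetics: the aptamers are only ~90--110 nt, primary sequence
conservation is weak, and function lives in secondary and tertiary structure.
`aptanet` takes the network route instead.  Each aptamer is a vertex; each
pair of aptamers is an edge weighted by a pairwise similarity score; and
*relative conservation* of a group of homologous aptamers is read off as the
group's edge density after thresholding:

$$
D_g(t) \;=\; \frac{\#\{\,(i,j) \in g \times g,\; i<j : w_{ij} \ge t\,\}}
                 {\binom{|g|}{2}},
$$

the fraction of possible within-group edges whose weight survives the
threshold $t$ (for a distance-like metric the inequality flips; boundary
edges always survive).  Swept across $t$, $D_g(t)$ is exactly the
complementary empirical CDF of the group's edge-weight multiset -- an
identity the test suite asserts against a direct recount.  A more conserved
group keeps high density to higher thresholds.  Between-group density uses
cross edges only, normalised by $|g_a| \cdot |g_b|$.

## Architecture and context classification

Aptamer hits (coordinates plus e-values, typically from covariance-model
scans supplied as a table) are classified before any network is built:

* hits with e-value above $10^{-5}$ are dropped (boundary inclusive);
* two hits on one contig and strand separated by at most 100 intervening
  nucleotides form a tandem, paired greedily from the 5' end; aptamer-1 is
  the 5' aptamer in transcription direction;
* an unpaired hit is typed by an externally supplied ghost interval:
  strictly 3' within the tandem window gives type-1, strictly 5' type-2,
  neither (or both) type-0;
* genomic context is the functional bin of the nearest same-strand gene
  starting within 500 nt downstream of the aptamer: `GCV` (glycine cleavage
  system), `TP` (transport proteins), `Gly_Met` (other glycine metabolism),
  else `Other`.  The keyword map is ordered, case-insensitive and fully
  user-overridable, because annotation vocabularies drift between
  databases;
* identical riboswitches from different strains of one species are
  deduplicated (tandems compare the concatenated ordered pair).

Coordinates are 1-based inclusive throughout; BED input is converted at the
boundary.  All distance rules (the 100 nt tandem window, the 500 nt context
window) are measured as intervening nucleotides in transcription direction
and are configurable, since the boundary convention behind such published
window rules is rarely stated exactly.

## The built-in similarity metric

Published analyses of this kind weight edges with external alignment tools.
Those can be ingested directly (`read_score_matrix()`, square or long
layout, with an explicit orientation flag because some metrics are
similarities and others distances).  So that the pipeline is self-contained
and its behaviour provable, `aptanet` also ships one transparent metric:

$$
S(a, b) \;=\; 100\left[\,w_{\mathrm{seq}}\,\frac{\mathrm{PID}(a,b)}{100}
  + w_{\mathrm{struct}}\,\bigl(1 - d_M(a, b)\bigr)\right],
\qquad w_{\mathrm{seq}} = w_{\mathrm{struct}} = \tfrac12 ,
$$

where PID is the percent identity of the optimal Needleman--Wunsch global
alignment (match $+1$, mismatch $0$, gap $-1$; deterministic traceback
preferring diagonal, then up, then left), and $d_M \in [0,1]$ is a
normalised mountain distance between predicted secondary structures.
Structures come from Nussinov base-pair maximisation over
$\{AU, UA, GC, CG, GU, UG\}$ with a minimum hairpin loop of 3 nt and a fixed
traceback tie-break (prefer unpaired, then the smallest partner), so every
component of the score is a deterministic function of the sequences.  The
mountain function $m[i]$ counts the pairs enclosing position $i$; for equal
lengths

$$
d_M = \frac{\frac{1}{L}\sum_i |m_a[i] - m_b[i]|}{\max(\max m_a, \max m_b, 1)},
$$

and for unequal lengths both mountains are mapped onto $[0,1]$ as step
functions of relative position and the same normalised $L_1$ distance is
integrated exactly.  Dividing by length and by the larger peak keeps scores
comparable across aptamers of different sizes, which matters when ~30 nt
ghost stems meet ~100 nt aptamers in one matrix.

Design notes: a thermodynamic folder or an ensemble (partition-function)
mountain height would be more realistic than single-structure Nussinov
folding; the simpler choice was made because the network machinery is
metric-agnostic and the dynamic programs can be pinned exactly against
brute-force enumeration (all alignments of length $\le 6$ pairs, all nested
structures of length $\le 12$), which a thermodynamic model would not allow.
Users wanting the published external metrics plug their matrices in at the
same interface.

## Communities, consensus and stability

Community detection runs on the thresholded topology, unweighted -- the same
object the stability bootstrap perturbs -- through four igraph algorithms:
fast-greedy modularity, Walktrap (walk length 4), edge betweenness and
leading eigenvector.  One guard is applied: a partition whose modularity is
below that of the trivial connected-components partition is replaced by the
latter (igraph's fast-greedy can otherwise split a lone vertex off a
complete graph on a dendrogram-cut tie).

The consensus rule formalises "core cluster present in all algorithms":
seed communities come from the first algorithm's partition; each seed is
matched to its best-Jaccard community in every partition (ties broken to the
smaller community, then lexicographically); the intersection of the matches
is the *core*, kept at `min_core_size >= 3`; and every node co-clustered
with the core by at least half of the algorithms (`ceiling(vote_fraction *
k)`, configurable, since "at least half" of four algorithms could also be
read strictly) joins the *augmented* cluster.  Seeding from the first
algorithm is arbitrary but fixed and configurable.

Cluster stability is a parametric bootstrap: per replicate,
$k = \max(1, \mathrm{round}(0.05\,|E|))$ edges are deleted uniformly and $k$
previously absent edges added (never re-adding a deleted edge), so the edge
count is preserved while 5% of edges connect different nodes; the graph is
re-clustered and the best-matching community's Jaccard similarity to the
original cluster recorded.  The mean over 100 replicates is the stability.
$k$ floors at 1 so tiny graphs still perturb; each replicate reseeds R's RNG
deterministically from the run seed, so reports are bit-reproducible.

## The synthetic cohort generator

Because the original genome-scale inputs are external scans, validation
rests on cohorts generated with known truth.  The generator encodes the
evolutionary scenario under test: per genomic context, a tandem ancestor
(two independently sampled aptamers, each with a designed P1 closing stem
and P2/P3 hairpins, 8 bp each, Watson-Crick complementary by construction)
produces descendants on a star phylogeny.  Defaults: 30 tandems and 15
singletons per context, aptamer length 100 nt, ghost length 30 nt,
conserved branch rate 0.03 substitutions/site, degraded branch rate 0.15,
conserved map `GCV -> apt1`, `TP -> apt2`.  Substitutions are single-round
uniform over the three alternative bases; a mutation at a paired site is
compensated at its partner with probability 0.7, mimicking covariation.
Singletons truncate the degraded aptamer to its P1 stem and place the ghost
3' of the aptamer when aptamer-2 degrades (type-1) and 5' when aptamer-1
degrades (type-2); the context-type association is idealised to 100%
(observed associations in real data are ~90%), with a `noise_fraction` knob
to reintroduce label noise.  A star phylogeny was chosen over a sampled tree
because the analysis measures group-wise pairwise similarity, not topology,
and the star makes expected pairwise divergence analytic (about twice the
branch rate).

Rates were chosen so that the three weight strata a real cohort would show
are present and ordered: conserved intra-group similarity ~90, degraded
~75, cross-ancestor ~65 on the built-in 0--100 scale.  The default analysis
threshold of 85 sits between the first two strata; the density sweep runs
over 70--95 in steps of 5.

What the generator does *not* emulate: indels (all descendants are
length-aligned), thermodynamic folding constraints, tree-structured
relatedness between descendants, horizontal transfer, and annotation noise
in gene products.  Passing tests therefore demonstrate that the machinery
recovers a planted conservation asymmetry of realistic magnitude -- not that
real aptamer cohorts are this clean.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, per invocation: one default
cohort (150 aptamers, 11,175 pairwise scores), two family-scale tandem-only
cohorts (84 and 36 pairs, ~21,000 scores together), and 100 small null
cohorts (24 sequences each).  Thresholding is boundary-inclusive; long-format
score input requires `(a,b)`/`(b,a)` duplicates to agree within $10^{-9}$;
output floats are written at 6 significant digits; Wilcoxon p-values below
$10^{-300}$ are flagged as underflow.

## Known limitations

* **Rank-sum p-values on pairwise edges are anti-conservative.**  The
  Wilcoxon comparison of two intra-group edge-weight multisets treats
  $\binom{n}{2}$ pairwise scores as independent observations, but every
  descendant contributes to $n-1$ of them and each group shares one
  ancestor.  Under a true null (equal branch rates) the false-positive rate
  at $\alpha = 0.05$ is far above nominal (~60--70% in the shipped null
  control, for the sequence and the structure component alike), even though
  the test itself is exactly calibrated on independent samples (type-I
  error within [0.03, 0.07] in the suite).  Astronomically small p-values
  from such comparisons -- including published ones of this design -- should
  be read as effect-direction summaries, not literal tail probabilities;
  the density curves carry the scientifically meaningful signal.
* Nussinov folding ignores stacking energies and pseudoknots; structures
  for sequences with few Watson-Crick constraints are noisy, which is why
  the combined metric keeps an equal sequence weight.
* The consensus-core construction is one formalisation of an informally
  stated rule; `min_core_size` and `vote_fraction` expose the free choices.
* Greedy 5'-first tandem pairing is deterministic but arbitrary when three
  or more hits are mutually within the window; real data reportedly never
  shows such triples (largest observed tandem gap: 32 nt).

## A worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_params(seed = 1))
rec <- classify_aptamers(co$hits, co$ghost_hits, co$annotations, co$metadata)
table(rec$role, rec$context)

sm <- pairwise_matrix(co$sequences)
net <- build_network(sm, truth_groups(co$truth))
density_curve(net, seq(70, 95, by = 5))

tg <- threshold_graph(net, 85)
parts <- lapply(community_algorithms(), function(a) detect(tg, a))
cl <- consensus_core(parts)
bootstrap_stability(tg, cl[[1]]$augmented, "random_walk",
                    stability_config(seed = 1))

wilcoxon_rank_sum(group_edge_weights(net, "apt1/GCV"),
                  group_edge_weights(net, "apt2/GCV"))
```

Or, end to end with CSV outputs and a hashed manifest:

```{r pipeline, eval = FALSE}
run_pipeline(list(seed = 1), out_dir = "aptanet_run")
```
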