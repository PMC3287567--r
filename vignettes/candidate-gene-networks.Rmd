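---
title: "Candidate-gene network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dignet)
```

`dignet` takes a prioritised disease candidate-gene list and asks three
questions of it: where do these genes sit in the interactome, which
functional annotations and pathway neighbourhoods do they concentrate in,
and can the list be condensed into a connected disease-specific
subnetwork whose members — including the newly recruited ones — carry
independent association signal? This vignette explains each model, the
parameters that matter, and the choices made where the design was
genuinely open.

## Interactome and topology statistics

The interactome is an undirected simple graph over genes. Raw interaction
records are cleaned once, at construction: self-interactions are removed
and `(A,B)`/`(B,A)` duplicates collapsed, with the removed counts
reported so the cleanup can be audited against the raw source.

Degree is the number of incident edges. Betweenness is Brandes'
unnormalised centrality: for every unordered pair of other nodes, a node
receives the fraction of that pair's shortest paths passing through it.
Two conventions here are worth making explicit because plain-language
definitions ("the number of shortest paths going through the node") do
not pin them down:

* **Tied geodesics receive fractional credit.** This is the field
  standard and keeps the sum rule Σ betweenness = Σ over connected pairs
  of (path length − 1), which the test suite verifies by exhaustive
  geodesic enumeration on small graphs.
* **Values are unnormalised raw counts.** On a 10⁴-node interactome raw
  betweenness values of order 10³–10⁴ are typical; normalised values
  would be harder to compare with published group averages.

Group comparisons use the two-sided Wilcoxon rank-sum test: exact
enumeration when the pooled sample is at most 12 and tie-free, otherwise
the normal approximation with tie and continuity correction. Degree bins
are left-closed, right-open `[lo, hi)` with an overflow bin; candidate
genes absent from the interactome are excluded from all topology
statistics and reported, since a gene without interaction annotations has
no defined degree (it is not degree 0).

## Enrichment statistics

Over-representation uses the upper-tail hypergeometric probability,
computed in log space through `phyper` for stability at extreme
significance; the one-sided Fisher framing is provided as well and is
numerically identical on the same margins (the suite checks the
equivalence on random tables). Correction across the tested sets is
Benjamini–Hochberg step-up.

The default background universe is the union of the collection's member
genes, which is what general-purpose web enrichment tools effectively
use; `enrichment_config(universe_mode = "interactome")` or an explicit
universe are available because the choice of background materially
shifts p-values and a pipeline mixing interactome-derived and
annotation-derived queries should make it deliberately. Hierarchical
structure among GO terms is *not* modelled: if a level-filtered
collection is wanted, filter the GMT upstream — ontology traversal is out
of scope and a pre-filtered input keeps the statistics reproducible.

## Pathway crosstalk

Two pathways crosstalk when their **observed candidate genes** — not
their full memberships — overlap. This is deliberate: the crosstalk
object describes how the candidate list distributes over pathway space,
so an edge between two pathways that share a thousand background genes
but no candidates would be meaningless here. With observed sets A and B,

* Jaccard coefficient: JC = |A∩B| / |A∪B|
* overlap coefficient: OC = |A∩B| / min(|A|, |B|)
* edge score: (JC + OC)/2, which always lies between the two.

For the canonical worked pair — 23 and 31 observed genes with all 23
shared — JC = 23/31, OC = 1 and the score is 0.87 to two decimals.

Filtering follows three conjunctive rules with defaults `min_genes = 5`
observed candidates per pathway, BH-adjusted p strictly `< 0.01`, and
`min_shared = 3` shared candidates per pair; edges are then ranked by
score and the top `top_fraction = 0.10` retained, keeping
`floor(top_fraction × n_candidates)` edges (571 candidates yield exactly
57). Scores tie easily on small integer overlaps, so ties at the cutoff
break deterministically: larger shared count first, then lexicographic
pathway pair. The threshold comparison is strict and boundary cases
(adjusted p exactly at the threshold) are reported. Pathways passing the
filters but incident to no retained edge are dropped from the graph by
default (`keep_isolated = FALSE`), since the crosstalk picture is about
connectivity; a flag restores them. No significance test is attached to
crosstalk scores — the score is a descriptive ranking, and pretending
otherwise would require a null model for pathway-overlap structure that
the object does not carry.

## Steiner subnetwork extraction

The subnetwork model is the node-weighted Steiner tree: connect the
candidate genes (terminals) through the interactome while minimising the
total weight of recruited non-terminals. Default weights are 0 on
terminals and 1 elsewhere, so the objective is the *count* of recruited
linker genes; per-gene weights (e.g. 1 − prioritisation score) are
accepted for score-aware variants but are off by default because the
plain minimum-recruitment objective is the one with a clean guarantee
and interpretation.

The solver is the Klein–Ravi spider-merging approximation. A forest
starts with each terminal as its own tree; each round selects a centre
node v and r ≥ 2 trees minimising

    (w(v) + Σ cheapest node-weighted path costs from v to each tree) / r

where a path's cost counts only its interior non-forest nodes, and merges
them; the recruited weight is at most 2·ln(k) times optimal for k
terminals. Implementation notes:

* Node-weighted shortest paths are delegated to igraph's Dijkstra by
  splitting each node weight onto incident edges as half-weights, which
  keeps the inner loop in C; a path a…b then costs interior weight plus
  boundary halves, corrected analytically.
* Merged paths can run through nodes of unselected trees at zero cost;
  any tree touched by a new path is folded into the merge.
* The union of merged paths can contain cycles, so the final structure is
  reduced to a BFS spanning tree and non-terminal leaves are pruned
  iteratively. After pruning, every leaf is a terminal, which guarantees
  that deleting any linker disconnects some terminal pair — the suite
  asserts this minimality property on random instances.
* Everything is deterministic: vertices are stored sorted, centre ties
  resolve to the smallest ratio then the lexicographically smallest node,
  and the output is invariant to permutations of the input edge list.
* Terminals split across graph components are connected within each
  component holding at least two of them; terminals alone in their
  component are reported as unconnected rather than silently dropped.
* By default the output is the merged tree; `induce_edges = TRUE`
  re-induces all parent-graph edges among the chosen nodes for display,
  since a published subnetwork figure is usually the induced subgraph
  rather than a strict tree.

`brute_force_steiner()` enumerates subsets of non-terminals (feasible to
about 20 of them) and returns the exact optimum, preferring smaller and
then lexicographically smaller node sets among ties. It exists to
validate the approximation: on random small instances the suite checks
`optimum ≤ approximation ≤ 2 ln(k) × optimum` and records how often the
approximation is exactly optimal (usually well over half the time at
that scale).

## GWAS evaluation

Gene-wise association uses the min-p statistic: a SNP maps to a gene when
it lies on the same chromosome within the closed interval
`[start − flank, end + flank]` (1-based coordinates), and a gene's p is
the minimum over its mapped SNPs. The default flank is 0 kb — the gene
region read literally — with the flag exposed because 5–20 kb flanks are
common in practice. A SNP inside two overlapping genes counts for both;
genes with no mapped SNP are omitted entirely rather than assigned p = 1.

Min-p is biased: under the global null, genes with more SNPs have
stochastically smaller minima. No correction is applied — the statistic
is reported as-is, the bias is documented here, and group comparisons
should be read accordingly (the synthetic generator reproduces the bias,
and the test suite demonstrates it with the closed form for Beta
alternatives).

Binned reporting uses edges {0.001, 0.01, 0.05}; bins are left-closed,
and following the conventional bin label "≥ 0.05" the last bin includes
0.05 itself, so nominal significance (strictly p < 0.05) coincides
exactly with membership in the first three bins. Partition tests compare
a gene group against a disjoint reference with one-sided Fisher's exact
test in the enrichment direction; one-sidedness is a choice — the
substantive question is whether subnetwork genes are *more* often
nominally significant — and the default reference for each subnetwork
class is the non-subnetwork remainder, excluding the other subnetwork
class so the groups stay disjoint.

## Synthetic data and what passing tests mean

The generators are pure functions of their parameters and a seed.

* `simulate_interactome(n, m, seed)` — preferential attachment: node i
  attaches `min(m, i−1)` edges to distinct earlier nodes with probability
  proportional to degree + 1. The graph is connected and simple with
  exactly `Σ min(m, i−1)` edges and a heavy-tailed degree distribution.
  Defaults in the pipeline use n = 2000, m = 3 (mean degree ≈ 5): large
  enough for hub structure, small enough that a full pipeline run takes
  tens of seconds.
* `plant_disease_module()` grows a path-biased random subtree and labels
  all its leaves (plus internal draws as needed) as terminals, the rest
  as linkers. Every linker is then an internal tree node on a path
  between terminals, so the planted linker set is genuinely required
  *within the planted tree* — the host graph may still offer cheaper
  routes, so the planted weight upper-bounds the optimum and recovery is
  asserted against the 2 ln(k) bound, not equality.
* `simulate_pathways()` draws null sets uniformly from the universe and
  enriched sets with a fraction (default 0.5) of members from the
  candidate list; overlap blocks force groups of enriched sets to share
  a candidate core, planting crosstalk edges. At the default scale
  (universe 10⁴, 150 candidates, sets of 20–60) an enriched set expects
  k ≈ 0.5·size·(150-candidate draw) against a null expectation below 1,
  so planted sets separate from null sets by many orders of magnitude in
  p — the recovery check (planted outrank all null sets in ≥ 95/100
  seeds) tests machinery, not statistical subtlety.
* `simulate_gwas()` gives null SNPs Uniform(0,1) p-values and SNPs in
  associated genes Beta(a, 1) with a < 1 (default 0.2). The Beta(a,1)
  alternative is chosen for its closed form: with s SNPs,
  P(p_min < q) = 1 − (1 − q^a)^s, which the tests verify within
  3 standard errors, and a is a single interpretable effect-strength
  knob (a → 1 recovers the null exactly).

What the synthetic layer does *not* emulate: linkage disequilibrium
(SNP p-values are independent), gene-length/SNP-density confounding
beyond the SNP-count mechanism, literature or ascertainment bias in
interaction data, annotation redundancy from ontology structure, and
duplication-driven network motifs. Passing the recovery suite therefore
shows the pipeline correctly extracts structure of the kind it assumes;
it says nothing about robustness to those real-data pathologies.

## Numerical and calibration choices

* Hypergeometric tails in log space; BH through `p.adjust`; Fisher
  through `fisher.test` — standard library routines wherever one exists.
* The null-calibration checks use large-margin regimes (universe 4000,
  sets of 200, query 1000; 500 genes × 3 SNPs for the Fisher check) so
  that the exact tests' discreteness is small against the
  Kolmogorov–Smirnov tolerance at 100 simulated seeds; exact one-sided
  tests are conservative, and at small margins their point masses would
  dominate a uniformity test without this being a calibration defect.
* Steiner oracle comparisons run on 200 random instances of at most 12
  nodes with 3–5 terminals — small enough for exhaustive search, large
  enough to exercise merges through intermediate trees.
* Problem sizes throughout the suite (2000-node pipeline graphs,
  500-node planted-recovery graphs, 100-seed calibration loops) are
  chosen so the whole test run completes in about a minute on one core
  while keeping every check at a scale where its asymptotics hold.

## Known limitations

* The crosstalk score carries no significance test (see above); the
  retained-edge set depends on the arbitrary but conventional 10%
  retention and on the three filter thresholds, all exposed in
  `crosstalk_config()`.
* Klein–Ravi is an approximation; on adversarial instances it may
  recruit up to 2 ln(k) times the optimal weight, and its output is one
  near-optimal tree among possibly many — biological interpretation of
  any single recruited linker should be correspondingly cautious.
* Min-p gene-based association inherits SNP-count bias and ignores LD;
  for real GWAS data a dedicated gene-based test (VEGAS or MAGMA style)
  is the appropriate confirmatory tool.
* Identifier mapping resolves symbols and unique aliases only; ambiguous
  aliases are discarded (with an audit trail) rather than guessed.
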