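---
title: "Inferring stress-signaling subnetworks by integer linear programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stress-signaling subnetworks by integer linear programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

A stress-response signaling network is observed only indirectly. Deleting a
regulator (a *source*) and profiling the transcriptome under stress reveals
which genes (*targets*) depend on it; competitive fitness screens reveal
proteins whose loss impairs the stress response (*fitness-contribution
hits*); phospho-proteomics reveals proteins whose phosphorylation changes
under stress (*phospho hits*). None of these says how the signal travels.
subnetIP infers a parsimonious, consistently directed subnetwork of a
background interaction network (protein–protein, kinase–substrate,
protein–DNA/RNA edges) that explains all three evidence types at once.

Genes may appear as two nodes: the protein, and the DNA/mRNA being
regulated. Gene/mRNA nodes are terminal — they carry no outgoing edges, and
every candidate explanation ends with exactly one regulatory interaction
into them.

## Candidate paths

The integer program chooses among *candidate paths* enumerated from the
background network, in four classes:

* **source–target** — source → up to 3 intermediate proteins → TF/RBP →
  target gene. The TF/RBP layer is restricted to *candidate regulators* of
  that source: regulators whose bound targets are enriched with the
  source's targets (inclusive upper-tail hypergeometric test, p < 0.05),
  plus any regulator known to bind targets under the stress condition,
  which is included unconditionally.
* **hit–source** and **source–source** — at most one intermediate protein;
  these document proximity between evidence proteins.
* **receptor–source** — at most four intermediates, anchoring the network
  to known membrane sensors.

Source–target enumeration uses iterative deepening: the segment length
grows until at least half of the source's candidate regulators are
reachable (a regulator counts as reached as soon as one simple path of the
current length exists), then stops. This keeps path counts manageable while
guaranteeing that the better-connected half of the regulator layer is
represented. A source that is itself a candidate regulator is "reached" at
depth zero and may explain its targets with a single regulatory edge.

Paths are simple, traverse directed edges forwards only, and record the
orientation they require for each undirected edge. They are emitted in
lexicographic node-sequence order, which makes everything downstream
deterministic.

## The integer program

Binary variables encode path selection (σ_p), edge relevance (x_e),
undirected-edge orientation (d_e, with 1 meaning the direction from the
lexicographically smaller endpoint), node relevance (y_n), and pair
connectivity (c_ij for every hit–source and unordered source–source pair).
The constraints:

1. every source–target pair that received candidate paths is covered by at
   least one selected path (pairs for which enumeration found nothing
   impose no constraint, which keeps the program feasible by construction);
2. every declared receptor–source pair is covered (enforced strictly — a
   declared pair with no candidate path fails at model-building time);
3. c_ij is exactly the indicator that some path of its pair is selected
   (both inequality directions are materialized);
4. an edge is relevant iff a selected path uses it; a node is relevant iff
   a relevant edge touches it;
5. all selected paths agree on the orientation of every undirected edge
   they share.

Four objectives are applied in a fixed order, each frozen as an equality
before the next: maximize the number of connected hit–source and
source–source pairs; maximize the number of fitness and phospho hits among
relevant nodes; minimize the number of relevant nodes, enumerating an
ensemble of solutions that all attain the minimum; and finally, per
solution, maximize the number of selected paths with the node set held
fixed, so each solution displays every connection its nodes support.

## How the solver works

At any optimum, x, y, and c are functions of the selected path set, so the
search space is really the set of path selections plus an orientation of
the undirected edges. The package exploits this:

* **Stages 1–2** branch only over *conflicted* undirected edges (edges that
  some candidate paths traverse in opposite orientations). With a full
  orientation fixed, selecting every compatible path simultaneously
  maximizes both the connection count and the hit count.
* **Stage 3** is an exact depth-first branch-and-bound implemented in C++
  over "requirements": each mandatory pair, each connection pair, and each
  hit node either is already satisfied or branches over its
  orientation-compatible candidate paths (cheapest-first), with optional
  requirements also allowed to stay unsatisfied unless a zero-cost
  candidate makes skipping provably dominated. Single-candidate mandatory
  pairs are unit-propagated before the search. The admissible lower bound
  charges every unmet requirement the minimum number of new nodes among its
  candidates while blocking double counting, so the charges add up.
  Identical search states are memoized. The pool phase re-runs the search
  at the proven optimum and collects distinct relevant-node sets, up to
  `pool_size`.
* **Stage 4** re-searches orientations among the paths that fit inside a
  solution's node set, keeping the mandatory coverage and both frozen
  optima, and returns the largest consistent path set.

The enumeration is deterministic: identical inputs produce identical pools
for any seed (the `seed` arguments exist for interface stability). Solution
distinctness is by relevant-node set; `check_solution()` independently
re-evaluates every constraint family plus the stage freezes from the raw
sets, without touching the solver, and is asserted over every pooled
solution in the test suite.

The program can be genuinely infeasible when two mandatory pairs force
opposite orientations of the same undirected edge and no alternative paths
exist; the solver reports this as an error rather than silently relaxing a
constraint.

## Confidence, consensus, and evaluation

Each node, edge, and path is scored by the fraction of pooled solutions
containing it. Edge confidence ignores orientation; the majority
orientation is reported separately with its own frequency. The consensus
subnetwork at threshold *t* (default 0.75) keeps elements at confidence ≥
*t*, pruning edges whose endpoints fall below the threshold. Consensus
subnetworks are nested across thresholds.

Precision–recall evaluation scores node confidences against curated
positive and negative labels, optionally excluding the experimental hits so
that inputs do not inflate accuracy. Two baselines are provided: the
*candidate baseline* treats every protein in any candidate path as
predicted, and the *permuted baseline* reruns the entire pipeline on
permuted evidence drawn to match the real sets in size and degree
distribution (logarithmic degree bins 1, 2–3, 4–7, …, widened when a bin
runs out of members; exact-degree matching is usually infeasible on sparse
graphs). Permuted receptors are random proteins, equal in number to the
real receptor pairs, each paired with a random permuted source; permuted
targets are uniform draws of matching size. Hub proteins accumulate
permuted confidence because many degree-matched evidence sets route
through them — the directional hub-versus-periphery check in the test
suite verifies exactly this behavior on a hub-and-spoke fixture.

## Bifurcation scoring

To rank nodes that separate induced from repressed downstream modules, the
consensus source–target paths (confidence ≥ 0.75) are filtered to those
whose terminal regulator is enriched for the cluster of its terminal target
(hypergeometric test, Benjamini–Hochberg FDR ≤ 0.1, applied jointly across
all regulator × cluster tests), and targets outside every cluster are
dropped. For a node *n*, its downstream targets are partitioned by the
combination of *n*'s children through which each is reachable. With
`C(T) = Σ_c −|T^c|·log2(|T^c|/|T|)` the *total* bits needed to encode
cluster membership, the information gain `I(n) = C(T(n)) − Σ_i C(P_i(n))`
is normalized by the split information `S(n)` — the plain entropy of the
partition proportions, in bits *per target* — giving `B(n) = I(n)/S(n)`.
The deliberate asymmetry (total bits over per-target bits) makes B grow
with the number of downstream targets, so the score prefers nodes with few,
cleanly split outgoing partitions and many targets: duplicating every
target doubles C and I, leaves S unchanged, and doubles B. Nodes with a
single partition (S = 0) are excluded from the ranking; ranking ties break
by node identifier.

## The synthetic-data generator

`generate_study()` builds a background network with preferential-attachment
protein degrees (so permuted baselines exercise realistic hub effects), a
TF/RBP layer with cluster-biased regulons over induced / repressed gene
modules, and plants a ground-truth subnetwork: per source, equal-length
directed kinase cascades to its regulators (existing directed edges are
reused; a pair already joined by an undirected edge is avoided so the
planted truth never competes for an edge orientation, with resampling of
intermediates on a clash), one short receptor chain, target sets equal to
the planted regulators' regulons, and hit annotations drawn from the
planted interior nodes. Sources and regulators are never hits, matching the
disjoint roles of the real evidence.

Key defaults: 200 proteins, 120 genes, 14 regulators, mean protein degree
4, half of protein edges directed, regulons of 8–20 genes with 85% drawn
from the regulator's own module, 5 sources with 2 planted routes each of
2–3 segment edges, full hit coverage, one receptor. These are the desk
study conditions used throughout the tests; they are small enough for the
exact solver to prove optimality in seconds to minutes per instance.

`target_noise` is the fraction of each target set that is spurious:
that fraction of the clean regulon-derived targets is *replaced* by random
genes, so the set size is preserved and noise 1 means a fully uncorrelated
target set. Replacement (rather than addition) is what makes noise costly:
it removes enrichment signal and planted explanations simultaneously.

What the generator does not emulate: expression values or phospho-site
intensities (only the derived sets the IP consumes), overlapping pathway
cross-talk beyond shared intermediates, correlated false annotations in the
binding map, or the curation biases of a literature-derived background
network. Recovery results on synthetic data therefore say that the
optimization recovers a parsimonious planted explanation under controlled
noise — not that a real compendium has the same signal-to-noise.

Two honest behaviors of the method visible at this scale: the 50% deepening
stop can leave a longer planted route unenumerated when a shorter
background path reaches one regulator first (costing recall), and a planted
regulator whose regulon is covered by another regulator's regulon can be
dropped entirely by node minimization. Both reflect the method's stated
parsimony bias rather than implementation artifacts.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | regulator-enrichment threshold per source (uncorrected) |
| `universe` | gene/mRNA node count | hypergeometric universe; configurable because the appropriate gene space depends on the platform |
| `max_intermediates` | 3 | source→regulator segment bound (five interactions in total with the terminal regulatory edge) |
| `coverage_stop` | 0.5 | iterative-deepening stop fraction |
| hit/source/receptor intermediates | 1 / 1 / 4 | auxiliary path bounds |
| `pool_size` | 1000 (100 in the recovery tests) | stage-3 ensemble size |
| `conf_threshold` | 0.75 | consensus confidence threshold |
| `bifurcation_fdr` | 0.1 | BH FDR for module-regulator enrichment |

## Worked example

```{r}
library(subnetIP)

study <- generate_study(seed = 1)
res <- infer_subnetwork_ensemble(study$net, study$evidence,
                                 pool_size = 100, seed = 1)
res$model
consensus <- consensus_subnetwork(res$ensemble, 0.75)
length(consensus$nodes)

# recovery of the planted truth
mean(study$labels$positives %in% consensus$nodes)

# bifurcation ranking over the generator's gene modules
subnet <- extract_module_paths(res$ensemble, res$paths,
                               attr(study$net, "cluster_map"),
                               study$evidence$regulator_binding,
                               universe = length(gene_nodes(study$net)))
head(rank_bifurcation_points(subnet))
```

## Known limitations

* The exact solver is designed for desk-scale studies (hundreds of
  proteins, hundreds of candidate paths). Genome-scale compendia with tens
  of thousands of candidate paths would need a commercial-grade MIP
  solver; the model builder's LP export (`write_lp()`) provides a bridge.
* Stage-3 distinctness is by node set; solutions differing only in path
  choice over the same nodes are represented once (the stage-4
  augmentation then includes all paths the node set supports).
* Bifurcation scoring is binary (induced vs repressed); finer module
  structure must be collapsed onto two clusters before scoring.
* The permuted baseline matches degree bins, not exact degrees, and
  silently widens a bin when the network cannot supply enough
  degree-matched proteins.
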