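---
title: "Refining protein interaction networks by critical-module discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining protein interaction networks by critical-module discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinrefine)
```

## The problem

Node-ranking (centrality) methods predict essential proteins from the
topology of a protein-protein interaction network (PIN), but
high-throughput interactomes carry substantial false-positive and
false-negative noise, and that noise caps what any centrality can achieve.
Two classical edge filters remove part of it: the *D-PIN* keeps an
interaction only if its two proteins are co-active somewhere in an
expression time course, and the *RD-PIN* additionally requires the pair to
share a subcellular compartment. Both act edge by edge and ignore a strong
regularity of interactomes: they are modular, and essential proteins
concentrate in a subset of dense, evolutionarily conserved,
nucleus-associated modules.

`pinrefine` implements a refinement that acts at the module level. The
*CM-PIN* ("critical-module PIN") is built in four steps:

1. extract the maximal connected subgraph of the input PIN (real PINs keep
   well over 90% of their interactions in the giant component);
2. partition it into modules by fast unfolding (Louvain) modularity
   optimisation;
3. score each module with three signals — orthology correlation (PC),
   nuclear localization (NSL) and internal-edge density (TF) — and select
   the *critical* modules;
4. keep exactly the interactions whose two endpoints both lie in critical
   modules, leaving the node set untouched.

Centralities are then recomputed on the CM-PIN, where essential proteins
rank measurably higher than on the unrefined network.

## The refinement chain

A protein $v_i$ with expression values $e_{i1},\dots,e_{in}$ is *active*
at time $t_k$ when $e_{ik} > \tau_i$ with
$\tau_i = \mu_i + \sigma_i$, where $\mu_i$ is the mean and $\sigma_i$ the
*population* standard deviation ($\div n$, not $n-1$) of the profile. The
inequality is strict, so a constant profile is never active. An S-PIN edge
survives into the D-PIN iff both endpoints are active at some common time
point; a D-PIN edge survives into the RD-PIN iff both endpoints have a
positive localization count in a common compartment. Localization is
stored as nonnegative evidence *counts* rather than 0/1 flags — per-module
nucleus scores above 1 are meaningful and occur in practice.

Proteins missing from an annotation table are treated conservatively:
never active (expression), localized nowhere (compartments), orthology
score 0. This keeps the pipeline total on partially annotated data; the
alternative (exempting unannotated edges from filtering) would silently
retain exactly the edges with the least supporting evidence.

```{r refinement}
cfg <- synthetic_config()
planted <- generate_network(cfg, seed = 1)
bundle <- generate_annotations(planted, cfg, seed = 1)
spin <- planted$network
dpin <- build_dpin(spin, bundle$expression)
rdpin <- build_rdpin(dpin, bundle$localization)
c(S = n_edges(spin), D = n_edges(dpin), RD = n_edges(rdpin))
```

Edge sets only shrink along the chain and all three networks share one
node set, so downstream results are always comparable protein by protein.

## Module discovery

Partition quality is Newman modularity
$Q = \sum_i (e_{ii} - a_i^2)$, with $e_{ii}$ the fraction of edges inside
module $i$ and $a_i$ its fraction of edge endpoints. `fast_unfolding()`
implements the two-phase Louvain heuristic: local moving (each node is
offered to the neighbouring module with the largest modularity gain,
accepted only when the gain is *strictly* positive — ties never move)
followed by aggregation of modules into super-nodes, repeated until a full
level makes no move. The per-move gain uses the standard constant-time
formula; a tolerance of $10^{-12}$ guards against floating-point
near-ties. The running $Q$ is recorded after every accepted move, so the
strict-increase property (which also proves termination) is directly
testable, and the final $Q$ is verified against an independent
recomputation of the definition.

Two determinism controls matter for reproducibility. The visit order is
either `sorted` (lexicographic node ids; fully deterministic, the
default) or `shuffled` (a fresh seeded permutation per sweep). Module ids
are canonicalised to 1..m ordered by each module's lexicographically
smallest member, so partitions are stable under node relabeling and
comparable across runs. On graphs small enough to enumerate every set
partition, the package's test suite checks that the heuristic never
reports a $Q$ above the exhaustive optimum, and that it attains the
optimum on the classic two-triangles-plus-bridge graph ($Q = 5/14$).

```{r modules}
core <- maximal_connected_subgraph(spin)
part <- fast_unfolding(core)
part
```

## Scoring and selecting critical modules

Three per-module scores, each aimed at one marker of essentiality:

* **PC** — Pearson correlation between the module's 0/1 membership
  indicator and the orthology-score vector over the clustered proteins.
  Essential proteins evolve slowly, so conserved modules matter.
  The correlation is computed from its raw-sum definition; it is undefined
  (reported `NA`, and excluded from selection by the orthology rule) when
  either vector is constant.
* **NSL** — mean nucleus evidence count, $N(c)/n(c)$. Essential proteins
  are most widely distributed in the nucleus.
* **TF** — $(I(c) - O(c))/n(c)$: internal minus boundary interactions per
  protein. Dense, inward-looking modules score high; a module dominated by
  boundary edges can score negative.

Selection combines them as
$C_\mathrm{critical} = C_\mathrm{orth} \cup (C_\mathrm{sub} \setminus
C_\mathrm{topo})$ with $C_\mathrm{orth} = \{PC \ge th_1\}$,
$C_\mathrm{sub} = \{NSL \ge th_2\}$ and
$C_\mathrm{topo} = \{TF \le th_3\}$, all inequalities inclusive. The
topology rule is subtractive: it vetoes sparsely connected modules that
the localization signal alone would admit. A consequence worth noting is
that the number of selected modules is monotone non-increasing in all
three thresholds — raising $th_3$ makes the veto set larger, not smaller.

Defaults are $th_1 = 0.1$, $th_2 = 2$, $th_3 = 0.25$. The latter two are
the values at which the refinement performs best in published yeast
analyses of this method. $th_1$ deserves a comment: on genome-scale PINs a
single module is a tiny fraction of thousands of proteins and PC values
live within a few hundredths of zero (published sweeps probe
$th_1 \in [-0.02, 0.015]$), whereas on the package's synthetic fixtures a
critical module is an eighth of the network and planted PC values are
around $\pm 0.5$; 0.1 separates those cleanly. On real data the threshold
should be chosen from the observed PC distribution, which is what
`threshold_sweep()` is for — the package deliberately provides grid
inspection rather than automatic threshold optimisation.

```{r selection}
scores <- module_scores(core, part, bundle$orthology, bundle$localization)
scores
sel <- select_critical_modules(scores)
sel
cmpin <- build_cmpin(spin, part, sel)
cmpin
```

`build_cmpin()` keeps an edge iff both endpoints' modules are critical —
including endpoints in two *different* critical modules, a literal reading
of "both in the critical modules" that retains the biologically plausible
bridges between conserved complexes. The node set is never reduced;
proteins stripped of all edges stay as isolated, bottom-ranked nodes so
that rankings on different network variants remain permutations of the
same protein universe.

## Ranking and evaluation

`compute_centrality()` exposes a registry of eight methods: degree (DC),
Wasserman–Faust component-scaled closeness (CC, finite on the
disconnected refined networks), normalized Brandes betweenness (BC),
PageRank (PR, damping 0.85), LeaderRank (LR, a ground node attached to
every protein, its converged score redistributed uniformly), local
average connectivity (LAC), node clustering centrality from edge
clustering coefficients (NC), and the density of the maximum neighbourhood
component (DMNC, $\varepsilon = 1.7$). Expression-weighted centralities
(PeC, WDC) and topological potential are registry extension points via
`register_centrality()` rather than built-ins. Rankings order proteins by
descending score with ties broken by ascending id — a detail that makes
every downstream number reproducible to the last decimal.

Evaluation treats essential-protein prediction as ranked retrieval with
class imbalance: confusion matrices at a cutoff $K$ (conventionally
$K = P$, the number of essentials, where the identities force
$SN = PPV = FM$ and $SP = NPV$), the seven standard metrics, top-$k$
counts, jackknife curves, and precision–recall curves whose area is the
step-wise average precision $\frac{1}{P}\sum_{\text{hits}} \text{prec@hit}$
(not a trapezoid rule — the step-wise form is the standard estimator for
ranked retrieval and is what the package's hand-computed test cases pin
down). Essential proteins absent from the network are excluded from $P$
by default, making evaluation network-relative; set
`network_relative = FALSE` to score against the full reference list.

```{r evaluation}
for (m in c("DC", "LAC")) {
  pr_s <- pr_curve(compute_centrality(spin, m), bundle$essential)$prauc
  pr_c <- pr_curve(compute_centrality(cmpin, m), bundle$essential)$prauc
  cat(sprintf("%-4s PRAUC  S-PIN %.3f   CM-PIN %.3f\n", m, pr_s, pr_c))
}
```

## What the synthetic generator emulates — and what it does not

`generate_network()` draws a planted-partition (stochastic block) graph:
by default eight modules of 20 proteins, within-module edge probability
0.3 against 0.01 between modules, with two modules planted as critical.
`generate_annotations()` then ties every input signal to that ground
truth: orthology scores are Poisson with mean 8 in critical modules
against 1 elsewhere; nucleus counts Poisson 3 against 0.3 (ten further
compartments at mean 0.3, eleven compartments total, matching the usual
localization vocabularies); each module owns a 6-point activity window in
a 36-point time course (the length of a yeast metabolic-cycle series)
which critical-module proteins follow with probability 0.95 and background
proteins with 0.5; and essentiality is Bernoulli 0.5 in critical against
0.1 in background modules. The block sizes and edge probabilities sit in
the same regime the recovery benchmarks in the test suite use, safely
above the resolution limit at which Louvain merges planted blocks. All
draws flow from one seed through per-annotation derived streams, so
adding a generator never perturbs the others, and fixtures written twice
with one seed are byte-identical.

These choices make the *signal structure* of the real datasets
reproducible, not their statistics: real PINs are scale-free and orders of
magnitude larger, annotation noise is not Poisson, and real module sizes
are heterogeneous. A Barabási–Albert-style preset is deliberately absent
from the assertions for that reason. Passing the recovery tests therefore
demonstrates that the pipeline's machinery is correct and that the method
works when its assumptions hold — it does not certify performance on any
particular organism's interactome.

## Numerical choices and degenerate inputs

* Activity and selection inequalities are exactly as defined: strict for
  activity ($e_{ik} > \tau_i$), inclusive for selection thresholds.
* Louvain move acceptance requires a gain above $10^{-12}$; ties and
  zero-gain moves are rejected, which makes the move trace strictly
  increasing and the algorithm provably terminating.
* Component and ranking ties break lexicographically (smallest node id);
  module ids canonicalise by smallest member.
* Modularity and fast unfolding raise an error on edgeless graphs, where
  $Q$ is undefined; empty networks propagate as empty networks through the
  refinement chain.
* PC is `NA` (never silently 0) for constant inputs; metrics with zero
  denominators are `NA`, except the $0/0$ F-measure which follows the
  retrieval convention $FM = 0$.
* Expression fixtures are rounded to 4 decimals at generation so that TSV
  round-trips are lossless and byte-stable.

## Validation scale

The test suite and the acceptance script run entirely on synthetic
fixtures: 160-node default networks (20 seeds for module and
critical-module recovery), 200 random graphs for the modularity oracle,
exhaustive partition enumeration on graphs of up to 8 nodes, and a
200-seed Monte Carlo check that a random ranking's average precision
concentrates at the class prevalence ($|V| = 2000$, $P = 200$). These
sizes were chosen so the whole validation completes in seconds while
every property is still sharply testable; the pipeline itself has no
size-dependent logic and scales to genome-sized networks (the Louvain
implementation is pure R, so expect minutes, not seconds, beyond
$10^5$ edges).

## Known limitations

* No identifier mapping: protein ids are opaque case-sensitive strings,
  and reconciling DIP/GEO/InParanoid/COMPARTMENTS vocabularies is the
  caller's responsibility.
* Modules are non-overlapping by construction; overlapping-complex
  methods (clique percolation, link clustering) are out of scope.
* Threshold selection is by grid inspection (`threshold_sweep()`), not
  optimisation, mirroring how the method is tuned in practice.
* The fast-unfolding result is a local optimum that depends on visit
  order; the package offers deterministic and seeded-shuffle orders, but
  exact replication of any particular published partition is not a goal.
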