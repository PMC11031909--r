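# pinrefine

Refines protein–protein interaction networks (PINs) so that node-ranking
(centrality) methods identify essential proteins more accurately. The
package is aimed at computational/systems biologists who work with
interactome data and want a reproducible, testable implementation of
module-level network refinement.

High-throughput interactomes are noisy, and edge-level filters — the
**D-PIN** (keep an interaction only if both proteins are co-active in an
expression time course, activity defined by the per-protein threshold
τᵢ = μᵢ + σᵢ with the population standard deviation) and the **RD-PIN**
(additionally require a shared subcellular compartment) — remove only part
of that noise. `pinrefine` adds the module-level refinement: the
**CM-PIN** keeps exactly the interactions whose endpoints both lie in
*critical modules*, built in four steps:

1. extract the maximal connected subgraph of the PIN;
2. partition it by fast-unfolding (Louvain) modularity optimisation,
   Q = Σᵢ (eᵢᵢ − aᵢ²);
3. score each module c with three signals —
   **PC(c)**: Pearson correlation of the module indicator with the
   orthology-score vector (evolutionary conservation),
   **NSL(c) = N(c)/n(c)**: mean nucleus evidence count,
   **TF(c) = (I(c) − O(c))/n(c)**: internal minus boundary edges per
   protein — and select
   `C_critical = C_orth ∪ (C_sub \ C_topo)` with
   C_orth = {PC ≥ th₁}, C_sub = {NSL ≥ th₂}, C_topo = {TF ≤ th₃};
4. keep edges with both endpoints in critical modules; the node set is
   never reduced.

The package also provides a centrality registry (DC, CC, BC, PR,
LeaderRank, LAC, NC, DMNC, plus `register_centrality()` for extensions),
ranked-retrieval evaluation (confusion metrics at K = P, top-k counts,
jackknife curves, precision–recall with average precision), and a
synthetic planted-module generator so the whole pipeline is verifiable
without downloading any database.

## Worked example

```r
library(pinrefine)

cfg     <- synthetic_config()                  # 8 planted modules, 2 critical
planted <- generate_network(cfg, seed = 1)
bundle  <- generate_annotations(planted, cfg, seed = 1)

report <- run_pipeline(
  network      = planted$network,
  localization = bundle$localization,
  orthology    = bundle$orthology,
  essential    = bundle$essential,
  refine       = "none",                       # refine the S-PIN itself
  methods      = c("DC", "LAC")
)
report
#> <cmpin_report> none base: 160 proteins, 581 edges -> CM-PIN 105 edges; 8 modules (Q = 0.6626), 2 critical
report$selection
#> <critical_module_set> 2 critical (orth 2, sub 2, topo 0) at th = (0.1, 2, 0.25)

round(sapply(report$evaluation,
             function(ev) c(spin = ev$base$prauc, cmpin = ev$cmpin$prauc)), 3)
#>          DC   LAC
#> spin  0.203 0.212
#> cmpin 0.409 0.407
```

The partition recovers the eight planted modules (Q = 0.66) and the
selection finds exactly the two planted critical modules — both pass the
orthology rule (PC ≈ 0.5 vs ≈ −0.2 for background modules) and the
localization rule (NSL ≥ 3 vs ≤ 0.5). Restricting the network to those
modules roughly doubles the precision–recall area of both centralities,
because the planted essential proteins concentrate there: the ranking no
longer wastes its top positions on hubs of non-critical modules. At the
cutoff K = P the confusion-matrix identities force SN = PPV = FM and
SP = NPV, so a single row summarises the seven standard metrics:

```r
round(report$evaluation$LAC$cmpin$metrics, 3)
#>    SN    SP   PPV   NPV    FM   MCC   ACC
#> 0.444 0.839 0.444 0.839 0.444 0.283 0.750
```

A command-line wrapper with the same stages (`simulate`, `dpin`, `rdpin`,
`modules`, `cmpin`, `rank`, `evaluate`, `pipeline`) ships in
`inst/cli/pinrefine.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/pinrefine.R", package = "pinrefine"))')
Rscript "$CLI" simulate --seed 42 -o fx
Rscript "$CLI" cmpin --network fx/network.tsv --orthology fx/orthology.tsv \
    --localization fx/localization.tsv -o cm.tsv --scores scores.tsv
Rscript "$CLI" rank --network cm.tsv --method LAC -o ranks.tsv
```

## Vignette

`vignettes/critical-module-refinement.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical edge cases,
and known limitations.
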