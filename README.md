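# myconet

Stability analysis of soil fungal co-occurrence networks from ITS
amplicon (ASV) count tables.

Field studies increasingly ask not just *which* fungi a treatment
favours, but whether the community's interaction network stays complex
and robust. `myconet` implements that question as a tested pipeline:

* **Community profiling** — rarefaction, bias-corrected Chao1
  (S<sub>obs</sub> + F₁(F₁−1)/(2(F₂+1))), Shannon (natural log),
  Bray–Curtis distances, PCoA, PERMANOVA.
* **Functional guilds** — lookup-table assignment of taxa to trophic
  guilds (Saprotroph, Symbiotroph, Pathotroph and their mixtures) at the
  most specific matching lineage rank, with per-sample relative
  abundances and rank-sum group tests.
* **Co-occurrence networks** — per-treatment graphs with an edge iff
  Spearman |ρ| > 0.8 *and* Bonferroni-adjusted p < 0.05; isolated taxa
  are not counted as nodes.
* **Topology** — nodes, edges, average degree 2E/N, density
  2E/(N(N−1)), clustering, path length/diameter (raw and
  node-normalised), greedy modularity Q.
* **Stability** — null-model *cohesion*: observed pairwise correlations
  corrected by a taxon-shuffle null, per-taxon positive/negative
  connectedness, abundance-weighted per-sample cohesion C⁺ ≥ 0 and
  C⁻ ≤ 0, and the **stability ratio** |C⁻|/C⁺; plus robustness under
  random and degree-targeted node removal (giant-component fraction
  among survivors).
* **Guild–stability link** — Pearson R between each guild's relative
  abundance and the per-sample stability ratio.
* **Synthetic data** — a generator that plants co-abundance modules,
  guild mixes and group effects, so every stage is validated by
  parameter recovery without any raw sequencing data.

## Worked example

Three simulated treatments share a 60-taxon universe, with the densest
planted correlation structure in "CF", intermediate in "CK", and sparse,
fragmented structure in "BF":

```r
library(myconet)

fix  <- generateContrastFixture(seed = 1)          # CK / CF / BF design
rare <- rarefy(fix$asv, "auto", seed = 1)
nets <- lapply(c(CK = "CK", CF = "CF", BF = "BF"),
               function(g) groupNetwork(rare, g))  # |rho|>0.8, Bonferroni
compareTopology(lapply(nets, summarizeTopology), control = "CK")
```

```
 group nodes edges averageDegree   density clusteringCoefficient modularity
    CK    39   119      6.102564 0.1605938             0.7414530  0.6753760
    CF    38   150      7.894737 0.2133713             0.6886759  0.4793778
    BF    22    27      2.454545 0.1168831             0.7878788  0.8120713
```

CF's network has the most edges and highest average degree; BF's is
sparser on every count. Robustness (mean giant-component fraction among
survivors after removing 50% of nodes at random, 100 replicates) ranks
the same way:

```r
sapply(nets, function(n)
  mean(robustness(n, "random", removalFraction = 0.5,
                  replicates = 100, seed = 1)@values))
#>    CK    CF    BF
#> 0.318 0.523 0.277
```

Per-sample cohesion and the |C⁻|/C⁺ stability ratio, compared across
treatments by rank-sum tests:

```r
ratios <- lapply(c(CK = "CK", CF = "CF", BF = "BF"), function(g) {
  sub <- rare[, treatments(rare) == g]
  stabilityRatio(communityCohesion(filterTaxa(sub),
                                   nullIterations = 200, seed = 1))
})
compareStability(ratios)
#>  group1 group2   median1   median2   W            p stars
#>      CK     CF 0.7455861 0.7449457 124 6.528700e-01    ns
#>      CK     BF 0.7455861 0.8686384   6 3.868035e-07  ****
#>      CF     BF 0.7449457 0.8686384  39 1.665215e-03    **
```

For a full run — alpha/beta diversity, PERMANOVA, guild tables and
tests, networks, topology, cohesion, robustness, guild–stability
correlations and a manifest — use `runPipeline()` with a
`pipelineConfig()` (or a YAML file via `readPipelineConfig()`); every
table is also written as TSV/GraphML when `outDir` is given. A thin
command-line wrapper over the same functions lives at
`inst/scripts/myconet.R`.

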