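---
title: "Fungal co-occurrence network stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fungal co-occurrence network stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myconet)
```

## The problem

Soil fungal communities can look healthy by composition yet be fragile as
an interaction system. `myconet` quantifies that fragility from ITS
amplicon data: starting from an ASV count table with treatment metadata,
it builds per-treatment co-occurrence networks, summarises their topology,
computes a null-model *cohesion* index and the negative-to-positive
cohesion *stability ratio*, simulates robustness to node loss, and asks
whether functional guilds (saprotrophs, symbiotrophs, pathotrophs and
their mixtures) track network stability. The motivating application is
comparing a control soil (CK) against soils amended with conventional
polyethylene (CF) or biodegradable (BF) mulch-film residues, but every
stage is treatment-agnostic.

## Community profiling

Samples are rarefied to even depth (`rarefy()`, default the minimum column
sum) by subsampling reads without replacement; samples below the target
depth are dropped with a warning, never silently. Alpha diversity uses the
bias-corrected Chao1 estimator

$$\hat S = S_{obs} + \frac{F_1 (F_1 - 1)}{2 (F_2 + 1)}$$

(chosen over the classic form so doubleton-free samples remain defined)
and the Shannon index in natural log units, the `vegan` convention.
Between-sample structure uses Bray–Curtis dissimilarity (`vegan::vegdist`),
classical-scaling PCoA, and PERMANOVA via `vegan::adonis2` with
unrestricted label permutations, so
$p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})$. PCoA axes are
ordered by eigenvalue, proportions of variance are taken over positive
eigenvalues only, and each axis is oriented so its first nonzero loading
is positive — a deterministic sign convention that makes coordinates
reproducible. Axis choice for plotting is left to the caller, since
ordinations are sometimes reported on non-consecutive axes.

## Guild assignment

`assignGuilds()` is a lookup-table engine: a reference maps lineage rank
tokens (e.g. `g__Mortierella`) to one of seven labels — Saprotroph,
Symbiotroph, Pathotroph, the three pairwise mixtures, the triple mixture —
plus `Unassigned`. Matching proceeds from the most specific rank present
(species, genus, family, ..., kingdom), so a genus entry always overrides
a conflicting family entry. Confidence ranks of curated guild databases
are deliberately not modelled; the bundled synthetic references exist to
exercise the machinery, not to make biological claims. Guild relative
abundances are computed per sample on rarefied counts by default
(`guildsOnRarefied`), since the downstream comparisons are across samples
of unequal raw depth; a flag restores raw counts.

Group comparisons use two-sided Wilcoxon rank-sum tests (exact for small
tie-free samples, tie-corrected normal approximation otherwise) plus
percent change of group means against the control.

## Co-occurrence networks

For each treatment group separately, taxa are pre-filtered (default:
present in ≥ 50% of the group's samples and mean relative abundance
≥ 1e-4) — an explicit, reported filter, because correlation estimates on
mostly-zero vectors are rank-degenerate. All pairwise Spearman
correlations are then computed on rarefied relative abundances; p-values
use the t approximation for n ≥ 10 samples and exact/per-pair evaluation
below that. An edge requires **|rho| > 0.8 and Bonferroni-adjusted
p < 0.05**, both strict. Two numerical choices matter:

* the Bonferroni denominator `m` counts only *testable* pairs — pairs
  involving a constant taxon have no defined correlation, and counting
  them would inflate the correction arbitrarily;
* taxa left without any edge are dropped from the node list, so "nodes"
  counts connected taxa. This matches how published node counts differ by
  treatment even when every network is built from the same taxon universe.

The gate has a hard power implication: with only 4–6 replicates, no
Spearman p-value can survive Bonferroni over thousands of pairs, whatever
the effect size. The package therefore treats replication as free in
simulations and defaults to 15 replicates per group for network work;
real studies at n = 4 must either pool samples or accept that the gate is
effectively |rho|-only.

## Topology panel

`summarizeTopology()` reports nodes, edges, average degree `2E/N`, density
`2E/(N(N-1))`, mean local clustering (0 for degree < 2), average shortest
path length and diameter on the largest connected component, and
modularity Q. Published topology tables sometimes print path lengths and
diameters below 1, which is impossible for raw hop counts; we interpret
such values as node-normalised and therefore emit both the raw and the
`/N`-normalised variants rather than guessing silently. Modularity uses
igraph's fast-greedy (CNM) agglomeration — deterministic for a fixed
graph — in preference to Louvain's marginally better but
stochastic partitions. `topologyClosedForms()` exposes the degree/density
identities directly so published (N, E) pairs can be checked without
rebuilding a network.

## Cohesion and the stability ratio

Cohesion asks how strongly each sample's community is bound by positive
and negative taxon-taxon associations, with the spurious correlation
structure of compositional data subtracted by a null model:

1. observed correlations $r_{jk}$ between taxa across samples (Pearson by
   default — the index's conventional choice; Spearman available to match
   the network stage, since the original description does not bind the
   network's correlation choice to the index's);
2. null expectation $E_0[r_{jk}]$: mean correlation over `nullIterations`
   (default 200) randomisations that independently permute each taxon's
   abundance vector across samples ("taxon shuffle");
3. corrected $r'_{jk} = r_{jk} - E_0[r_{jk}]$;
4. per-taxon connectedness: mean of the positive $r'_{jk}$ (and,
   separately, of the negative ones);
5. per-sample cohesion: relative-abundance-weighted sums
   $C^+_i = \sum_j a_{ij}\,\mathrm{conn}^+_j \ge 0$ and
   $C^-_i = \sum_j a_{ij}\,\mathrm{conn}^-_j \le 0$.

The **stability ratio** is $|C^-_i| / C^+_i$: communities dominated by
competition (negative association) score above 1, cooperation-dominated
ones below. It is undefined when $C^+_i = 0$ — which happens in degenerate
toys such as a pure two-taxon anti-correlated community, where no positive
corrected correlation exists — and is then flagged `NA` rather than
coerced. With 200 iterations the null estimate is stable: doubling to 400
moves corrected correlations by ~0.01 RMS on a 40-taxon, 15-sample
fixture, under the package's shared-stream seeding.

## Robustness

`robustness()` removes `floor(f N)` nodes — uniformly at random
(replicated, default 100) or in descending degree order with ties broken
by node id (deterministic, one replicate). Degree-targeted attack is the
cheapest defensible reading of "targeted"; betweenness ordering is a
plug-in alternative but not the default. The reported metric is the
largest-component fraction among *survivors* (in [0, 1]); natural
connectivity (post/pre ratio of $\ln \bar{e^{\lambda}}$) is offered as an
alternative because the literature rarely states which connectivity
functional it used. Closed-form cases anchor the implementation: complete
graphs always score 1, and removing the hub of a 10-node star leaves
giant-component fraction 1/9.

## Linking guilds to stability

`correlateGuildStability()` correlates each guild's per-sample relative
abundance with the per-sample stability ratio, pooled across groups,
aligning strictly by sample id. Pearson R with a two-sided t test is the
default because this kind of result is conventionally displayed with a
fitted line and an R value; a Spearman option is provided for consistency
with the rank-based tests elsewhere. Per-sample (rather than per-network)
stability is used as the x-variable: it preserves within-group variation
and honest degrees of freedom.

## Multi-group tests and letters

`kruskalPosthoc()` computes tie-corrected Kruskal–Wallis H, then pairwise
Conover-style t tests on mean ranks with pooled variance
$S^2 (N-1-H)/(N-k)$, Holm-adjusted, and a Piepho insert-and-absorb compact
letter display. Conover-on-ranks was chosen over Dunn z tests because at
the small group sizes typical of field studies (n = 4) Dunn's z for
adjacent groups cannot reach 0.05 even under complete separation, whereas
the Conover test — the procedure behind the common agronomy-package letter
displays — can; with Holm adjustment, three fully separated n = 4 groups
earn three distinct letters. Star labelling everywhere uses the strict
convention `*` < 0.05 ... `****` < 0.0001.

## The synthetic generator

`generateDataset()` draws taxa × samples counts in four stages: lognormal
baseline abundances (meanlog 0, sdlog 1.5 — the rank-abundance skew
typical of ITS communities; published studies rarely state an abundance
model, so this is the package's choice), latent Gaussian module factors
shared within planted co-abundance blocks and scaled by a per-group
loading (a latent-factor construction is positive-definite at any module
count, unlike hand-built covariance matrices), per-group guild
reweighting toward a target guild mix, and multinomial sampling at exact
depth, so column sums equal the design's `sequencingDepth` by
construction. Latent and noise terms are mean-corrected on the log scale
so module membership does not bias expected abundance. A master seed
spawns fixed per-stage substreams, making stages independently
reproducible.

What it emulates: compositionality at realistic depth, planted
correlation blocks of controllable strength, treatment-specific guild
shifts, configurable replication (≥ 3, default 15 — see the power note
above). What it does not: read-level error, chimeras, taxonomy-classifier
mistakes, spatial autocorrelation between field replicates, or genuine
ecological interaction dynamics. Passing recovery tests therefore show
the *pipeline* is correct and well-calibrated, not that real soil data
will be as clean.

`plantGroupEffect()` rescales a guild's sampling probability within one
group and redraws each affected sample multinomially at its original
total. Because relative abundances renormalise, the raw proportion ratio
overshoots the planted fold; the odds ratio
$\frac{p'/(1-p')}{p/(1-p)}$ recovers it exactly in expectation and is the
estimator used in recovery checks. `generateContrastFixture()` combines
three single-group designs — two large high-loading blocks for CF, three
medium blocks for CK, six small low-loading blocks for BF — into the
standard fixture whose networks order CF > CK > BF in edge count and
random-removal robustness.

## Problem sizes and validation scope

The shipped tests and the acceptance script run at desk scale, sizes
chosen as representative rather than exhaustive: 10–80 taxa, 10–15
replicates per group, depths of 5,000–30,000 reads, 20–50 simulation
seeds per property, 500 null datasets for PERMANOVA calibration (99
permutations each), and 200/400 cohesion null iterations. Published
summary statistics that are pure functions of printed counts (average
degree, density, the BF/CF microplastic multiple) are recomputed exactly;
sequencing-derived results from the motivating study are validated by
property (type-I control, parameter recovery, oracle equivalence,
closed-form graph cases, qualitative treatment ordering) because the raw
reads are not shipped with the package.

## Known limitations

* Plain Spearman on relative abundances ignores compositional coupling;
  CLR-based or SparCC-style inference is explicitly out of scope.
* Cohesion weights *all* retained taxa, not only network nodes; with the
  default prevalence filter the difference is small, but it is a choice.
* The Bonferroni-over-testable-pairs rule makes `m` data-dependent;
  comparisons across groups with different constant-taxon counts use
  slightly different corrections.
* Guild assignment is only as good as its reference table; the synthetic
  references bundled for testing are labelled as such and carry no
  biological authority.
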