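---
title: "Methods: phylogenetic and trait diversity of layered microbial communities"
author: "matdiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic and trait diversity of layered microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matdiversity)
```

# The scientific setting

Intertidal microbial mats are layered on a millimeter scale: light, oxygen
and sulfide gradients stack distinct bacterial guilds — oxygenic
cyanobacteria at the surface, purple sulfur bacteria below the photic
transition, sulfate reducers at depth — into adjacent microhabitats. Because
metabolic strategies are substantially conserved on the 16S phylogeny, an
assembly process that filters colonists by their (heritable) traits should
leave a *phylogenetic clustering* signature inside each layer, while
competitive exclusion of close relatives predicts *overdispersion*. This
package implements the quantitative machinery for asking those questions
from an OTU count table, a support-annotated phylogeny, a taxonomy, and an
ortholog-group (KO/COG/NOG) trait table — together with a synthetic-data
generator that makes every stage testable with known truth.

# Diversity profiles

## Naive and similarity-sensitive Hill numbers

For relative abundances $p_i$ the Hill number of order $q$ is
$^qD = \left(\sum_{i:p_i>0} p_i^q\right)^{1/(1-q)}$, with the analytic
limits $^1D = \exp(-\sum_i p_i \ln p_i)$ and $^\infty D = 1/\max_i p_i$.
At $q=0$ it is the taxonomic richness $S$; increasing $q$ discounts rare
taxa, so the profile over $q$ summarizes richness *and* evenness at once.
The similarity-sensitive generalization replaces each taxon's abundance by
its *ordinariness* $(Zp)_i = \sum_j Z_{ij} p_j$ under a similarity matrix
$Z \in [0,1]$ with unit diagonal:
$^qD^Z = \left(\sum_i p_i (Zp)_i^{\,q-1}\right)^{1/(1-q)}$. The identity
matrix recovers the naive number exactly (`similarityHill(p, diag(k), q)`
equals `naiveHill(p, q)` to $10^{-9}$ across the default grid).

## The phylogenetic variant and the historical-species decomposition

The phylogenetic profile treats each pairing of an extant taxon $i$ with a
branch $b$ on its root-to-tip path as a *historical species* $(i,b)$ with
abundance $\pi_{(i,b)} = \ell_b\, p_i / T_i$, where $\ell_b$ is the branch
length and $T_i = \sum_{b \ni i} \ell_b$ the root-to-tip depth of $i$
(depths are per tip, so non-ultrametric trees are fully supported). These
abundances sum to one whenever $p$ does. The ordinariness of $(i,b)$ under
the ancestry-indicator similarity is the *branch abundance*
$a_b = \sum_{j \in I_b} p_j$, the summed abundance of the clade below $b$,
so the profile is

$$^qD^Z(\pi) = \Big(\sum_{b}\, c_b\, a_b^{\,q-1}\Big)^{1/(1-q)},
\qquad c_b = \ell_b \sum_{i \in I_b} p_i / T_i .$$

This branch-level form is what `phyloHill()` evaluates; the quadratic
$(i,b)\times(j,c)$ relatedness matrix is never materialized, because its
action on $\pi$ is exactly $a_b$ — identical output at a footprint linear
in the number of branches. Correctness is guarded two ways: on equal-branch
star trees the phylogenetic and naive numbers coincide for every $q$, and
on ultrametric trees the implementation is checked against an independently
coded branch-formula oracle
$\big(\sum_b (\ell_b/T)\, a_b^q\big)^{1/(1-q)}$ at $10^{-9}$.

## Rarefaction and averaging

Libraries of unequal size are compared by subsampling counts without
replacement to a common depth (the smallest library by default) and
averaging the *diversity values* over replicates (`rarefiedProfile()`,
default 100 replicates, $q$ from 0 to 5 in steps of 0.1; the step and the
inclusion of the analytic $q=1$ point are configurable since profile
resolution is a presentation choice). Averaging the values rather than the
rarefied counts keeps each replicate a valid diversity and makes the
reported profile the mean of an ensemble of subsampled communities.
Zero-abundance taxa are excluded from every sum, so rarefaction-induced
absences need no special handling.

# Phylogenetic dispersion

## MPD and its standardized effect size

The mean pairwise distance of a community is the average cophenetic
distance over unordered pairs of present taxa (presence weighting), or
$\sum_{i \ne j} p_i p_j d_{ij} / \sum_{i \ne j} p_i p_j$ (proportional
weighting; identical when abundances are equal). `sesMPD()` standardizes
the observed, optionally rarefaction-averaged, MPD against `nNull`
randomized communities: $\mathrm{SES} = (\mathrm{obs} -
\bar{x}_{\mathrm{null}})/s_{\mathrm{null}}$. Negative SES means closer
relatives than the null expects (clustering); positive means
overdispersion.

Significance uses the rank of the observed value in the reference set of
size `nNull + 1` (observed included), with mid-rank averaging for ties:
$p_{\mathrm{low}} = \mathrm{rank}/(n+1)$ and $p_{\mathrm{high}} =
(n+2-\mathrm{rank})/(n+1)$, one-tailed at $\alpha = 0.05$ per direction —
so rank 15 among 999 nulls gives $p_{\mathrm{low}} = 0.015$. No
multiple-testing correction is applied across samples or factorial cells;
the design reports every cell and leaves family-wise control to the
analyst, which is a deliberate caveat, not an oversight.

## Null models, pools and degenerate cases

Three randomizations with different constraint structures are provided:

* `taxa.labels` — permute the labels of the cophenetic matrix within the
  taxa pool; the distance multiset is invariant.
* `phylogeny.pool` — draw a community of the observed richness uniformly
  from the pool; abundances are reassigned to the drawn taxa in random
  order.
* `independent.swap` — randomize the whole table by 2×2 checkerboard swaps
  that preserve per-row and per-column occupancy totals exactly (counts
  travel with the swap). The chain uses 10,000 attempted swaps of burn-in
  and 1,000 attempts between successive draws; the published description of
  the algorithm names no iteration counts, so both are exposed as
  configuration. The swap kernel is compiled (Rcpp) because the factorial
  design draws hundreds of thousands of candidate submatrices. A
  `binarize` flag collapses counts to presence first; the default carries
  counts, since the choice is not documented in the antecedent literature
  (both behaviors are available).

The taxa pool scopes the hypothesis: all samples (`all`), samples from the
same collection year (`year`), or the same core (`core`); core pools nest
inside year pools inside the global pool, and the nesting is asserted
structurally in the tests. Calibration studies can supply an explicit pool
(e.g. every tree tip). A sample invariant under its null — for instance one
containing every pool taxon under `taxa.labels` — has zero null variance
and is flagged `degenerate` rather than assigned an SES; samples with
fewer than two present taxa are `undefined`.

Rarefaction inside the SES loop applies the same
subsample-and-average statistic to the observed and to every null
community. Because checkerboard swaps move counts across columns, and guild
tables can be sparse, the depth is capped at each community's own total;
the cap is recorded here as the package's resolution of an ambiguity the
antecedent methods leave open.

## Guilds and support collapsing

`guildDispersion()` restricts the table and tree (via `pruneToTips()`,
which preserves pairwise distances exactly) to taxa whose lineage strings
match a guild's substrings — defaults cover oxygenic phototrophs
(Cyanobacteria), purple sulfur bacteria (Chromatiales) and sulfate reducers
(Desulfobacterales, Desulfovibrionales, Syntrophobacterales,
Clostridiales) — rebuilds the pool within the guild, and delegates to
`sesMPD()`.

Robustness to topological uncertainty is probed by dissolving weakly
supported bifurcations: `collapseLowSupport(tree, thr)` deletes every
internal non-root node with support below `thr` (50 and 80 are the
conventional thresholds) and reattaches its children with the deleted
branch's length *added to each child*. This keeps every root-to-tip depth
$T_i$ — and with it the historical-species abundances — exactly unchanged,
making the collapse a pure topology perturbation; the alternative of
discarding the length would conflate topological uncertainty with depth
shrinkage. Nodes without a numeric support are treated as fully supported
and never collapsed, nor is the root.

# Beta diversity

`unweightedUnifrac()` is the fraction of branch length unique to one of two
communities, over the root-inclusive branch sets (every branch from the
root to a present tip) — the original convention, stated explicitly because
rooting changes the value. `unifracMatrix()` averages pairwise distances
over matched rarefactions of all samples to the smallest library.
Unweighted UniFrac depends on presence only; doubling all counts leaves
full-depth distances unchanged (property-tested).

# Trait richness and resampling nulls

Ortholog-group richness proxies trait richness. All draw sizes are counted
in gene *instances*, never group counts: the observed statistic is the mean
distinct-group count in without-replacement subsamples of `depth` instances
(`rarefiedTraitRichness()`), and the null draws the same number of
instances from the pooled, instance-weighted multiset of the pool group's
samples (`traitNull()`), so abundant groups are drawn more often. A
group-weighted (deduplicated) pool is available behind a flag for
sensitivity analysis. Category analyses (photosynthesis, sulfur metabolism,
carbohydrate metabolism, ABC transporters, oxidative phosphorylation, total
metabolism) rarefy at the whole-pool depth and then restrict the richness
count to the category's groups — whole-pool randomization rather than
within-category rarefaction, matching the framing in which category curves
are read against the same global null. Ranks, p-values and the
depleted/enriched calls reuse the MPD conventions.

# The synthetic-data generator

The generator produces the study *shape*, not the study: its parameters are
stand-ins chosen once, and everything downstream is tested against them.

* **Trees** (`simulateTree`): forward birth-death simulation stopped the
  first time `nTips` lineages are extant, with the present extended by one
  further exponential waiting time so every pendant branch is positive;
  extinct lineages are pruned. Default pure birth (`deathRate = 0`) avoids
  extinct-lineage bookkeeping; birth-death is supported for more realistic
  depth distributions. Supports are uniform on [0, 100] because the
  analysis uses them only as collapse thresholds.
* **Traits** (`evolveTrait`): Brownian motion from a root value of 0 —
  the minimal model of phylogenetic niche conservatism. A tip's variance is
  `traitSigma^2` times its depth (checked against chi-square bounds on a
  1000-tip star tree).
* **Communities** (`assembleCommunity`): *filtering* draws taxa with weight
  $e^{-s(x_i - x^*)^2}$ around the trait of a randomly chosen seed taxon —
  per sample, so distinct layers filter toward different clades and
  between-sample turnover emerges; *competition* is greedy maximin
  selection on cophenetic distance, with probability $s/(1+s)$ of a greedy
  step; *neutral* is uniform. Strength 0 reduces every regime to uniform
  sampling (verified distributionally against binomial bounds).
* **Counts** (`sampleCounts`): lognormal relative abundances — the
  canonical microbial rank-abundance shape; the source study describes no
  abundance model — followed by a multinomial of the library size.
* **Trait tables** (`simulateTraitTable`): each sample draws gene instances
  from a shared ortholog pool, optionally enriching one category or
  restricting a sample to a random fraction of the pool (the depleted-layer
  scenario).

## Calibration, and an honest power ceiling

Under self-generated null data all three dispersion nulls and the trait
null produce significant calls at the nominal 5% rate (the acceptance suite
measures this over 400 samples per model against 99% binomial bounds). The
trait tables used in those checks are sized so that a sample's instance
count does not saturate the group pool (2,000 groups at 1,500 instances):
saturated tables make the rank distribution tie-ridden and the test
artificially conservative, a regime the real data are nowhere near.

Power is a different story, and the package reports it as measured rather
than as hoped. With one-dimensional Brownian traits, filtering at strength
10 (30 taxa from a 200-tip pure-birth tree) is called clustered in roughly
55–60% of replicates, although the mean SES is clearly negative. The
ceiling is *trait convergence*: under 1-D Brownian motion, distant clades
routinely wander into the optimum's trait band, so part of every filtered
community is phylogenetically scattered. The rate is flat in filtering
strength (the infinite-strength limit — taking the trait-nearest set — is
*worse*), invariant to `traitSigma` (a pure rescaling), and rises only
modestly with extinction-shaped trees. Selecting a monophyletic clade of
the same size is detected in 100% of replicates with mean SES near −18,
confirming the detector itself is sharp. The same convergence leaves a
minority of filtering replicates with SES near zero, whose *sign* then
flips easily when low-support nodes are collapsed; strongly clustered
replicates keep their sign across the 50% and 80% collapse levels. Passing
the synthetic tests therefore demonstrates calibration exactly, and
direction of effect robustly — but real communities filtered on
multidimensional, conserved trait syndromes should show stronger clustering
per unit of "true" filtering than this deliberately minimal 1-D generator.

# Numerical and design choices

* $q = 1$ and $q = \infty$ are evaluated analytically; $q$ within $10^{-9}$
  of 1 routes to the analytic branch, and the numeric values at
  $1 \pm 10^{-4}$ bracket it within $10^{-3}$ relative error.
* Rank ties are mid-averaged, which keeps the discrete p-values unbiased.
* Greedy competition ties (equal maximin distance) break uniformly at
  random.
* All stochastic functions take a `seed` and restore the caller's RNG
  state; with `seed = NULL` they consume the current stream, which is how a
  single top-level seed drives a whole pipeline deterministically. Output
  files carry the configuration hash and seed, and re-running a
  configuration reproduces every output byte-identically.
* Problem sizes in the tests and the acceptance script (150-tip fixture
  trees, 15 samples, 199 nulls, 5–10 rarefaction replicates) are chosen to
  exercise every code path at interactive speed; publication-grade runs
  use 999 nulls and 100 rarefactions via the same configuration keys.
* Depth intervals are stored half-open (`[top_mm, bottom_mm)`) so adjacent
  layers never overlap.
* Sequence counts are an imperfect proxy for organismal abundance; the
  pipeline surfaces this as a logged note when proportional weighting is
  requested, and always reports presence-based results alongside.

# Results containers

The central data objects are S4: `MatCommunity` and `TraitExperiment`
extend `SummarizedExperiment` (counts assay, sample metadata in `colData`,
taxonomy in `rowData`, tree in a dedicated slot), and
`HistoricalDecomposition` carries the branch-level quantities of the
diversity equation. Result *tables* (dispersion rows, trait calls,
profiles) are deliberately plain long-format `data.frame`s, following the
convention of the community-phylogenetics toolchain this package slots
into, where results feed directly into downstream tabular tooling.

# Limitations

* The generator starts at count tables: no read-level simulation, chimeras
  or primer bias, and no OTU-clustering artifacts.
* Downstream clustering/ordination statistics (Ward dendrograms with
  AU p-values, permutational ANOVA, regressions against abiotic
  covariates) are out of scope; the package emits the distance matrices and
  per-sample statistics those methods consume.
* Guild definitions are substring matches on lineage strings; they are only
  as monophyletic as the taxonomy is.
* No Chao-style asymptotic richness estimation, no alpha/beta/gamma
  decomposition of Hill numbers, no weighted/generalized UniFrac, and no
  MNTD-family dispersion statistics.

```{r session}
sessionInfo()
```
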