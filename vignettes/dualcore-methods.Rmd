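---
title: "Methods: dual core rhizobiomes, MIC networks, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual core rhizobiomes, MIC networks, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcore)
```

## The problem

A crop's rhizosphere hosts thousands of bacterial amplicon sequence
variants (ASVs), but only a fraction recur across fields, seasons and
studies. `dualcore` characterizes that recurring fraction in two
complementary ways and then asks how the two views relate:

* the **taxonomic core**: ASVs present in at least a cut-off fraction of
  samples (default 75%), the classic prevalence definition;
* the **functional core**: ASVs qualified through *functions* rather than
  identity. KEGG orthologs (KOs) predicted for the community that are
  present in at least the cut-off fraction of samples are "core KOs", and
  ASVs carrying core KOs form the functional core.

The two sets overlap only partially: taxa below the prevalence cut-off can
still carry core functions (functional redundancy), which is the
structural phenomenon the package is designed to expose. A
habitat-corrected co-occurrence network over the union of the two cores
then identifies hub taxa and records which core each hub belongs to.

## Core definitions and the redundancy rule

Presence is raw count > 0 (the QIIME-style core-features default); an
optional minimum-abundance floor is exposed but off by default. Cores are
computed per study — tables from different studies should never be pooled
before core extraction.

The functional-core membership rule needs care, because the natural
reading "ASVs assigned to core KOs in at least 75% of the samples" is
ambiguous. A pure conjunction (carries a core KO AND is individually
present in ≥ 75% of samples) would make the functional core a subset of
the taxonomic core, since both would use the same prevalence threshold —
contradicting the observation that functional cores are typically larger
and partially disjoint. `dualcore` therefore implements:

> member ⇔ (carries ≥ 1 core KO AND prevalence ≥ cutoff) OR
> (carries ≥ `redundancy_min_kos` core KOs),

with `redundancy_min_kos = 2` by default. The second disjunct is the
redundancy inclusion: an ASV assigned to more than one core KO is kept
even when individually sparse, because the functions it carries are
community-wide properties. Setting `redundancy_min_kos = NULL` recovers
the pure conjunction. A second ambiguity — whether prevalence is
conditioned on all samples or only on samples where the ASV's core KOs
are detected — is exposed as `conditioning = c("all_samples",
"ko_detected")`, defaulting to all samples.

Every functional-core member records its *provenance*: the set of core
KOs that qualified it. Multi-KO ASVs appear once.

## Function prediction

KO abundances are predicted from a user-supplied genome-content table
(per-ASV KO copy numbers plus 16S copy numbers):

$$\mathrm{KO}_{k,j} = \sum_a \frac{x_{aj}}{c^{16S}_a}\, n_{ak},$$

where $x_{aj}$ is the ASV count, $c^{16S}_a$ its 16S copy number
(normalization on by default; exposed as a flag) and $n_{ak}$ the KO copy
number. Pathway abundances are plain sums over member KOs, with multi-
mapped KOs contributing fully to each pathway. This deliberately replaces
the reference tool's hidden-state reconstruction and MinPath-style
pathway scoring: the genome content is taken as given, and the summation
rule is transparent and linear. Consequences: predictions are exactly
linear in the input table, and with an identity genome-content table
(each ASV carrying one private KO, copy 1, one 16S copy) the KO table
equals the ASV table — a cross-module consistency check the test suite
asserts as set equality of the resulting cores.

## Community statistics

* Normalization is total-sum scaling (proportions). Samples are never
  rarefied.
* Bray–Curtis and unweighted UniFrac are both computed; UniFrac uses the
  fraction of branch length unique to either sample's presence set over
  the branch length of the union.
* PCoA is classical metric scaling of $-\tfrac12 D^2$ double-centered;
  axes come from positive eigenvalues only and negative eigenvalues are
  dropped with a message.
* ANOSIM uses midranks for ties and
  $R = (\bar r_B - \bar r_W)/(M/2)$ with $M = n(n-1)/2$; PERMANOVA is the
  one-way distance partitioning with $R^2 = SS_B / SS_T$.
* All permutation p-values use $(1 + \#\{stat_{perm} \ge
  stat_{obs}\})/(1 + N)$, which cannot return zero; every permuting
  function takes an explicit seed.
* Differential abundance at phylum/genus/pathway/KO level uses Welch's
  t-test on untransformed proportions with Welch–Satterthwaite degrees of
  freedom, followed by Benjamini–Hochberg step-up over all tested
  features. Features with fewer than two observations per group, or zero
  variance in both groups with unequal means, are skipped with a log
  message.

## The MIC engine

Edges are scored with the maximal information coefficient: the maximum
over axis grids with at most $B(n)$ cells of the grid mutual information
normalized by $\log_2 \min(n_x, n_y)$. Parameters follow the reference
implementation of the statistic, since the source analysis states none:
$B(n) = n^{0.6}$ (floored at 4 so the smallest usable grid exists at
$n = 10$) and a clump refinement factor of 15.

Two routes compute the statistic:

* **exact** (default for $n \le 30$): every partition of the row axis is
  enumerated (cuts between distinct values only) and the column partition
  is solved exactly by dynamic programming over clumps. This is a true
  maximization, so it must — and in the test suite does, to $10^{-9}$ —
  agree with a brute-force enumeration of *both* axes.
* **approximate** (larger $n$): the standard heuristic — equipartition
  the row axis, restrict column cuts to clumps/superclumps, run the same
  DP, and take the maximum over both axis orientations. Orientation
  symmetrization makes `mic(x, y)` and `mic(y, x)` bit-identical, and the
  rank-based grids make the statistic exactly invariant under strictly
  monotone transforms of either variable.

The DP tabulates column terms $\sum_r n_{cr}\log_2 n_{cr} - n_c \log_2
n_c$ incrementally with an integer $k \log_2 k$ lookup table, which keeps
a single MIC evaluation below 0.1 ms at $n = 50$ — relevant because edge
calling uses per-pair permutation null distributions.

Edge significance: for each pair, one vector is permuted
(`n_permutations`, default 200) and $p = (1 + \#\{MIC_{perm} \ge
MIC_{obs}\})/(1+N)$; BH adjustment runs across all pairs and edges with
$q <$ `fdr_alpha` (default 0.05) are kept. Note the granularity
interaction: with $P$ pairs and a single true edge, BH's rank-1 threshold
is $\alpha/P$, so `n_permutations` must exceed $P/\alpha$ for a lone edge
to be callable at all. Pairs with a constant vector are degenerate: they
receive `NA` and are excluded from testing rather than silently scored.

An edge is called **non-linear** when $\mathrm{MIC} - r^2 > 0$ (the
statistic's own non-linearity measure; the threshold is configurable).

## Habitat correction

Samples collected from different habitats share habitat-driven abundance
shifts that masquerade as co-occurrence. The correction implemented here
divides each ASV's relative abundance by its habitat mean (zeros stay
zero), so the corrected habitat means are 1 and a pure shared shift
cancels. The exact formula of the originating script is not restated in
the source analysis; this division-by-habitat-mean definition is a
documented stand-in with the property the correction is meant to have —
a planted two-habitat confounder that doubles two independent ASVs
induces a strong spurious correlation before correction and a mean
correlation below 0.05 after it (asserted in the tests). Habitats with
fewer than three samples make the mean unstable and are an error.

## Hub detection

Centralities are computed on the undirected, unweighted graph of
significant edges: degree; closeness $1/\sum d$ (within connected
components — unreachable nodes are excluded from the sum, and the
harmonic convention is deliberately not used); betweenness as the
fraction of shortest paths through the node. Hubs are nodes
simultaneously among the top $k = \max(1, \lfloor (1-q) n \rfloor)$ of
all three centralities ($q = 0.9$: the top decile by rank), with ties at
the $k$-th value included.

The rank-based rule (rather than a quantile of the centrality *values*)
is a deliberate choice: betweenness is exactly zero for most nodes of
sparse networks, so a value-quantile threshold degenerates — the 90th
percentile of a mostly-zero vector is zero and every node "passes". With
the rank rule a star's center is the unique hub, while a cycle (all
centralities equal) flags every node, which is the documented tie
behavior on fully symmetric graphs.

## The synthetic testbed: what is emulated, what is not

`generate_scenario()` draws a stated world with known ground truth:

* **Occupancy first**: each planted-core ASV is present in a sample with
  probability `core_prevalence` (default 0.9) and every other ASV with
  `background_prevalence` (default 0.3). Controlling presence directly —
  rather than hoping abundances produce the right zeros — is what makes
  planted prevalence exactly calibrated to the presence = count > 0
  convention.
* **Abundances**: present ASVs get fixed lognormal base weights
  (meanlog 0, sdlog 1; planted core ASVs use meanlog 1, sdlog 0.7 — core
  taxa are typically among the more abundant members, and the higher
  weights keep multinomial/Dirichlet thinning from violating the planted
  presence probability the generator promises), a per-habitat
  multiplicative shift
  $e^{\pm\text{habitat\_effect}}$ on a random 30% of ASVs, Dirichlet
  perturbation with concentration 200 (mild overdispersion; small enough
  to look like amplicon noise, large enough that multinomial thinning
  shaves only a few points off the planted presence rate), and a
  multinomial draw of 10,000 reads per sample.
* **Genome content**: a quarter of KOs are designated core; each planted
  taxonomic-core ASV carries a random ~30% of them, and each planted
  redundant ASV carries 2–4 (so the redundancy rule detects them).
  Copy numbers sit in {1, 2, 3}, 16S copies in {1..7}. Core KOs are
  assigned *only* to planted ASVs and every non-core KO has at most two
  background carriers — this is what makes ground truth exactly
  recoverable in the noise-free regime, and it is the main concession to
  testability: real genome content is not block-structured.
* **Tree**: a random bifurcating topology with exponential branch
  lengths. It supports UniFrac but carries no relationship to the
  abundance structure, so a green UniFrac test establishes correctness of
  the computation, not realism of phylogenetic signal.

Not emulated: sequencing error, chimeras, variable library sizes,
taxon-taxon ecological interactions in the count model, and any
phylogenetic correlation of abundances or gene content. Green tests on
this world certify the pipeline's statistical machinery, not performance
on real data.

`simulate_hub_table()` is the network-stage testbed. On the latent log
scale the hub is $(f_1 + f_2)/\sqrt 2$ for two independent standard
normal factors; satellites follow one factor each plus noise (sd 0.15),
so hub–satellite correlation is ≈ 0.70, within-clique correlation ≈ 0.98,
and cross-clique satellites are independent — the hub is the unique
bridge, hence the unique top node in degree, closeness and betweenness.
Two implementation details matter: the factors are orthogonalized
in-sample (a chance factor correlation would couple all 25 cross-clique
pairs at once and occasionally wire the two cliques together), and a
large near-constant filler taxon absorbs the compositional closure so
that the planted dependence survives conversion to relative abundances.
The hub is labeled functional-only, which makes the scenario the
structural analogue of the finding that hub taxa belong mostly to the
functional core.

## Numerical and interface choices

* Configs are flat JSON (no YAML parser is assumed on the target
  system); all randomness flows from one master seed through fixed
  per-stage offsets, making rerun outputs byte-identical.
* TSV numbers are written with `%.17g`, so doubles round-trip exactly.
* Good's coverage is `1 - S/N` with `S` = singleton ASVs (count exactly
  1) and `N` = observed ASVs (count > 0), following the source formula
  literally; note the classical estimator divides by total reads
  instead, so values here are not comparable to textbook Good's
  coverage.
* The sensitivity sweep (cut-offs 0.70–0.90 by 0.05) asserts that core
  sizes are monotone non-increasing in the cut-off, which is a theorem
  for both core definitions and therefore a cheap invariant to check.
* Bipartite-only edge scanning (`pairs = "bipartite"`) is available
  because "associations between taxonomic and functional core ASVs" can
  be read either way; the default scores all pairs.

## Known limitations

* The HF correction is a stand-in; results will differ from the original
  script in detail, though not in the property it exists for.
* The approximate MIC is a heuristic: it can undershoot the true
  statistic for adversarial configurations. The exact mode bounds the
  cost of verifying it only for small n.
* Closeness across components is not comparable; hub detection on highly
  fragmented networks should be read with that in mind (the function
  logs when the graph is disconnected).
* Pathway abundances are sums, not minimal-pathway reconstructions.
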