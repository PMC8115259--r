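# dualcore

Dual characterization of crop core rhizobiomes: a **taxonomic core**
(prevalence-based) and a **functional core** (mediated by predicted KEGG
orthologs), the statistics that compare them, and a habitat-corrected
co-occurrence network — built on the maximal information coefficient
(MIC) — that identifies hub taxa and labels them by core membership.

## Who this is for

Microbiome researchers working with ASV count tables (16S rRNA amplicon
data) who want to ask, per study: *which taxa recur across samples, which
functions recur, do the two sets coincide, and which taxa sit at the
center of the co-occurrence structure?* The package ships a synthetic-data
generator with planted ground truth, so every stage of the pipeline can be
validated end to end without any external data.

## The model in brief

With presence defined as count > 0 and a prevalence cut-off *c* (default
0.75):

* taxonomic core = { ASV *a* : prev(*a*) ≥ *c* };
* KO abundance in sample *j* is `sum_a count[a,j] / copies16S[a] * copy[a,k]`
  (a PICRUSt-style prediction from a user-supplied genome-content table);
  core KOs = KOs with presence in ≥ *c* of samples;
* functional core = { *a* : *a* carries ≥ 1 core KO and prev(*a*) ≥ *c* } ∪
  { *a* : *a* carries ≥ 2 core KOs } — the second term is the functional
  redundancy inclusion;
* communities filtered to each core are compared with Bray–Curtis and
  unweighted UniFrac distances, PCoA, ANOSIM, PERMANOVA (999
  permutations), and Welch's *t* + Benjamini–Hochberg FDR at
  phylum/genus/pathway/KO level;
* edges between core ASVs are MIC scores on habitat-corrected relative
  abundances with per-pair permutation p-values, BH-adjusted (FDR 5%);
  an edge is non-linear when MIC − r² > 0; hub taxa are nodes
  simultaneously in the top decile (by rank) of degree, closeness and
  betweenness centrality.

See `vignettes/dualcore-methods.Rmd` for assumptions, parameter meanings
and design decisions.

## Worked example

```r
library(dualcore)

sim <- generate_scenario(scenario_config(seed = 42))
sim$table
#> abundance_table: 150 ASVs x 60 samples (counts)

tax <- taxonomic_core(sim$table, cutoff = 0.75)
tax
#> core_set (taxonomic): 15 members at cutoff 0.75

kt  <- predict_metagenome(sim$table, sim$genome_content)
kos <- core_kos(kt, cutoff = 0.75)            # 30 core KOs
fun <- functional_core(sim$table, sim$genome_content, kos, cutoff = 0.75)
fun
#> core_set (functional): 25 members at cutoff 0.75

shared_core(tax, fun)$pct_shared
#> [1] 60
```

The scenario plants 15 high-prevalence ASVs (presence probability 0.9 per
sample); the taxonomic core recovers exactly those 15. The functional
core is larger (25) because 10 ASVs qualify only through carried core
KOs: the planted functional-redundancy group, sitting below the 75%
prevalence cut-off. Comparing the two core rhizobiomes:

```r
pooled <- pool_rhizobiomes(filter_to_core(sim$table, tax),
                           filter_to_core(sim$table, fun))
dm <- bray_curtis(relative_abundance(pooled$table))
anosim(dm, pooled$groups, n_permutations = 999, seed = 42)
#> R = 0.036, p = 0.012
permanova(dm, pooled$groups, n_permutations = 999, seed = 42)
#> R2 = 0.028, F = 3.36, p = 0.007
```

Small-but-significant R/R²: the two cores share most members, so their
filtered communities differ modestly but consistently. Network stage on
the hub-structured testbed:

```r
hub   <- simulate_hub_table(n_samples = 100, n_decoys = 2, seed = 7)
edges <- edge_scan(hub$table, hub$core_labels,
                   mic_params(n_permutations = 200, seed = 7))
net   <- build_network(edges, hub$core_labels)
hub_taxa(net)   # significant edges: 32 of 78 pairs; MIC range 0.33-0.98
#>       id core_label degree closeness betweenness is_hub
#>  ASV_hub functional     10    0.0833       0.445    TRUE
```

The planted hub is the unique node at the top of all three centralities,
and it carries the functional-core label.

## Full pipeline

```sh
Rscript inst/cli/dualcore.R simulate --out sim_dir --seed 1
Rscript inst/cli/dualcore.R run --config run.json
Rscript inst/cli/dualcore.R sensitivity --config run.json
```

where `run.json` names the inputs (`table`, `taxonomy`, `genome_content`,
`ko_map`, `tree`, `metadata`), the `out_dir`, the cut-off, permutation
counts and the master seed. `run_study()` / `cutoff_sensitivity()` expose
the same from R. Outputs: core-set TSVs, filtered core-rhizobiome tables,
KO/pathway predictions, distance matrices, PCoA coordinates, ANOSIM /
PERMANOVA results, Welch+BH tables, the edge table, a GraphML network and
a hub report — rerunning the same config reproduces every file
byte-identically.

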