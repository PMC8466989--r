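# cryonet

Co-occurrence network analysis for soil fungal (zOTU) communities, built
for studies of permafrost-affected soils where taxa are profiled across
soil horizons (topsoil, cryoturbated organic matter, subsoil,
permafrost) and tundra sites.

## What it does

Starting from a zOTU count table (taxa × samples), sample metadata with
stratum labels and 11 environmental factors, a taxonomy table and a
FungalTraits-style genus → lifestyle lookup, `cryonet` runs the standard
co-occurrence workflow, one network per stratum:

1. **Filter** — relative-abundance normalisation, then keep taxa present
   in strictly more than 30% of the stratum's samples with mean relative
   abundance ≥ 0.1%.
2. **Network inference** — tie-aware Spearman correlation of all taxon
   pairs; p-values from the t statistic
   `t = ρ√((n−2)/(1−ρ²))` on n−2 df; Benjamini–Hochberg FDR over all
   pairs; keep edge (i, j) iff `|ρ| ≥ 0.6` and (adjusted) `p < 0.01`;
   nodes without edges are dropped.
3. **Topology** — APL (over connected pairs), degree, closeness
   (natural-log scale), betweenness, edge density, diameter, global
   transitivity, module count and Newman–Girvan modularity Q, plus a
   seeded Erdős–Rényi **G(n,m) null ensemble** (same node and edge
   counts) summarising APL, CC and M over replicates.
4. **Keystones (Zi–Pi)** — within-module degree z-score
   `Zi = (κᵢ − mean κ)/sd κ` and participation coefficient
   `Pi = 1 − Σₛ (κᵢₛ/kᵢ)²`, with roles at the (2.5, 0.62) thresholds:
   peripheral, connector, module hub, network hub; role-shift tables
   compare the same taxon across strata.
5. **Environment** — per-sample module profiles (sum of member relative
   abundances) and keystone taxa, Spearman-correlated against
   ln-transformed environmental factors (pH exempt), starred at
   raw p < 0.05 (\*) and p < 0.01 (\*\*).

A synthetic community generator (`simulate_community()`) plants known
module, hub and connector structure in sparse compositional counts so
the whole pipeline is testable end-to-end without any sequencing data.

## Worked example

```r
library(cryonet)

sim  <- simulate_community(default_paper_like_spec())
rel  <- relative_abundance(sim$zotu)
filt <- filter_taxa(rel)                       # 500 -> 227 taxa
corr <- spearman_matrix(filt)
net  <- build_network(corr, edge_thresholds(),
                      data.frame(taxon_id = rownames(filt),
                                 abundance = rowMeans(filt),
                                 lifestyle = "unassigned"))
part <- detect_modules(net)
topology_report(net, part)
```

```
co-occurrence network report
  nodes 70, edges 186 (+183 / -3), density 0.07702
  APL 3.005, diameter 6, transitivity 0.446
  degree 5.31 +/- 4.71, ln-closeness -4.96 +/- 1.24
  betweenness 61.5 +/- 112.5
  modules 6, modularity 0.520 (greedy)
```

70 of the 227 filtered taxa carry at least one robust correlation; the
network splits into 6 modules with modularity 0.52 — above the 0.4
convention for modular structure, and above its own random ensemble:

```r
random_ensemble(igraph::vcount(net), igraph::ecount(net),
                reps = 1000, seed = 1)
```

```
G(n=70, m=186) ensemble, 1000 reps (seed 1)
  APL 2.688 +/- 0.030 | CC 0.0770 +/- 0.0147 | M 0.362 +/- 0.015
```

The empirical Q (0.52) clearly exceeds the null mean (0.36): the planted
modules are real. `zipi(net, part)` then scores every node and
`classify_role()` calls the keystones.

Full pipeline (simulate → per-horizon networks → role shift →
environment correlation), from R or the CLI:

```r
run_pipeline(pipeline_config(spec = default_paper_like_spec(),
                             group = "horizon", null_reps = 1000,
                             seed = 1, out_dir = "out"))
```

```sh
Rscript inst/cli/cryonet.R run --config config.yaml
```

The YAML config mirrors `pipeline_config()`: either `inputs:` (paths
`zotu`, `metadata`, `taxonomy`, `traits`) or `spec:` (the
`simulation_spec()` fields), plus `group`, `filter`, `thresholds`,
`null_reps`, `algorithm`, `seed`, `out_dir`. Other CLI verbs:
`simulate`, `filter`, `network`, `props`, `zipi`, `roleshift`,
`envcorr`.

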