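---
title: "Methods: co-occurrence networks, null ensembles and Zi-Pi keystones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, null ensembles and Zi-Pi keystones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`cryonet` infers co-occurrence networks from zOTU (zero-radius OTU)
abundance tables of soil fungal communities, one network per stratum
(soil horizon or tundra site). A node is a taxon; an edge is a strong,
significant rank correlation between two taxa's relative-abundance
profiles across the stratum's samples. On top of the network it
computes the standard topology report, compares it with an Erdős–Rényi
null ensemble, classifies node roles with the Zi–Pi framework, and
correlates modules and keystone taxa with environmental factors.

This vignette records the methodological choices, their defaults, and
the limits of what the synthetic benchmark can establish.

## Filtering

Relative abundances are per-sample fractions (no rarefaction). Within a
stratum, a taxon is retained when

* prevalence is **strictly greater** than 30% of the stratum's samples
  (a taxon present in exactly 3 of 10 samples is dropped), and
* its **mean** relative abundance over those samples is at least 0.1%.

"Relative proportions of less than 0.1%" admits a per-sample and a
mean reading; the per-sample reading interacts incoherently with the
prevalence rule (a taxon could be "present" yet have all its values
excluded), so the mean is the default and a `max` rule is available via
`filter_params(abundance_rule = "max")`. Samples are restricted to the
stratum *before* filtering, and retained values are **not**
renormalised, so fractions stay interpretable against the whole
community. The filter is idempotent.

Alpha diversity uses the bias-corrected Chao1
$S_{obs} + f_1(f_1-1)/(2(f_2+1))$ (defined when there are no
doubletons; the classic $f_1^2/(2f_2)$ form is an option), Shannon in
natural-log units, and Simpson evenness (inverse Simpson over observed
richness) — the conventions of the microbiome R ecosystem.

## Network inference

Spearman's rho is Pearson correlation of average ranks (tie-aware);
p-values use $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df, the
behaviour of the standard correlation-matrix packages, with $p = 0$ at
$|\rho| = 1$ and constant taxa flagged ($\rho = 0$, $p = 1$) rather
than erroring. Benjamini–Hochberg adjustment runs over the upper
triangle only (the diagonal is excluded from multiple testing).

An edge requires $|\rho| \ge 0.6$ (the boundary value is kept: "equal
or greater") **and** $p < 0.01$. The 0.01 cutoff is applied to the
**BH-adjusted** p by default: the workflow this package implements
computes an FDR correction and then applies a significance cutoff
without saying which p it binds, and applying it to the adjusted value
is the conservative, standard reading. `edge_thresholds(use_adjusted_p
= FALSE)` reproduces the raw-p reading; reports record which was used.
Nodes with no retained edge are removed, which is why a network's node
count is below the filtered-taxa count.

One practical consequence worth knowing: the BH step-up couples all
pairs, so when a data set has few strong correlations the effective
p-threshold tightens and the network can collapse to (near) empty.
Empty networks are legal outputs, not errors.

## Topology and the null ensemble

* **APL** averages shortest-path lengths over *connected* ordered pairs
  only — these networks are disconnected, and this is the igraph
  convention under which Erdős–Rényi theory reproduces the reference
  random-network APL values.
* **Diameter** is the largest finite shortest path.
* **CC** is global transitivity (3 × triangles / connected triples); the
  average-local variant is also reported. A graph with no connected
  triple reports 0.
* **Closeness** is computed within components and reported as mean ± sd
  of its natural log (the reference tables print negative "average
  closeness" values, consistent with a log scale; the untransformed
  mean is also emitted, and the log-scale choice is never used in
  acceptance checks). Betweenness is unnormalised.
* **Modularity** Q is the Newman–Girvan quantity on the unweighted
  graph. Q > 0.4 is the conventional threshold for "modular" structure.

Module detection defaults to deterministic fast-greedy modularity
optimisation; Louvain is available and every report embeds the
algorithm name and seed. Detection never returns a partition worse than
the trivial single community (fast-greedy can cut a clique at negative
Q on ties). Module ids are relabelled by decreasing size (ties: lowest
vertex index), so "module 1" is always a largest module. A caveat
established while validating the package: fast-greedy's well-known
resolution limit occasionally merges planted modules in small networks,
which depresses participation coefficients of true connectors; the
recovery benchmark therefore partitions with Louvain (see below).

The null model is **G(n,m)** — uniform simple graphs with exactly the
empirical node and edge counts, not G(n,p) — because the comparison
fixes "the same nodes and edges". Each ensemble (default 1000
replicates, seeded) reports mean ± sd of APL, CC and M. For ER graphs
the expected transitivity equals the edge density $2m/(n(n-1))$, which
the test suite verifies at n = 200.

## Zi–Pi roles

With $\kappa_{is}$ the number of links node $i$ has into module $s$ and
$k_i$ its degree:

$$Z_i = \frac{\kappa_i - \overline{\kappa}_{s_i}}{\sigma(\kappa_{s_i})},
\qquad P_i = 1 - \sum_s \left(\frac{\kappa_{is}}{k_i}\right)^2$$

The z-score uses the **population** sd within the module (a z-score
over the module's members); a zero-variance module gives $Z_i = 0$ —
such nodes are structurally indistinguishable, not undefined. Roles
use the conventional thresholds: peripheral ($Z_i < 2.5$, $P_i <
0.62$), connector ($Z_i < 2.5$, $P_i > 0.62$), module hub ($Z_i > 2.5$,
$P_i < 0.62$), network hub (both high). The thresholds are strict on
both sides, leaving equality undefined in the source convention;
equality maps to the peripheral side — conservative keystone calling.
Role-shift tables list every taxon that is a generalist (connector or
hub) in at least one stratum, with `absent` where the taxon is not a
node; summaries include % peripherals and % of peripherals with
$P_i = 0$ (no edge outside the own module).

## Module–environment correlation

How a module becomes a sample-wise variable is the largest interpretive
gap in this workflow; `cryonet` uses the per-sample **sum of member
relative abundances** (simple and abundance-weighted). Environmental
factors are transformed $\ln(x + \varepsilon)$ with $\varepsilon$ half
the smallest positive observed value of that factor — enzyme activities
contain zeros — except pH, which is already a logarithmic quantity.
Correlation is Spearman with pairwise deletion of missing values (the
reference data have strata with n = 1–2); pairs with fewer than 5
complete samples or a constant side are flagged and reported as
$\rho = 0, p = 1$. Stars follow the heatmap convention — `**` for
p < 0.01, `*` for p < 0.05 — on **raw** p, with no FDR, matching how
such heatmaps are conventionally starred. Profiles are correlated
against the stratum's own samples only.

# The synthetic world

`simulate_community()` generates everything downstream stages need:
counts, metadata with 11 environmental factors, taxonomy, traits, and a
truth table of planted modules and roles.

**Construction.** Each module $m$ has a latent Gaussian factor; module
factors are equi-correlated at `module_factor_cor` (default 0.7),
modelling shared environmental forcing across modules. A member's
latent value is $a_i F_m + \sqrt{1-a_i^2}\,\epsilon$; the mean loading
$a = \sqrt{2\sin(\pi\rho_S/6)}$ targets the pairwise Spearman
`within_module_rho` through the Gaussian-copula rank-correlation map
(approximate by design — acceptance statements are inequalities).
Loadings are jittered ±15% around the target (shrinking as the loading
approaches 1) because real modules are core–periphery structures, not
cliques. Hubs load 1.0 — they correlate more strongly with every member
than members do with each other. Connectors load equally on
`min(n_modules, 4)` consecutive module factors plus a small
idiosyncratic term. Counts are multinomial draws at `sequencing_depth`
over the softmax of $\mu_i + 1.5 z_i$ plus optional log-normal
overdispersion noise; $\mu_i \sim N(0, 1.25)$ gives a realistic
abundance distribution, with hubs and connectors pinned near
$\mu = 1.4$ so that role-recovery benchmarks measure classification,
not the abundance filter. Environmental factors linked to a module are
$e\,F_m + \sqrt{1-e^2}\,\eta$ on the latent scale ($e$ = the
factor–module correlation), mapped to field-realistic units (moisture
in %, pH near 6.5, enzyme activities log-normal).

**Why correlated module factors are not optional.** A node's squared
correlations with orthogonal factors sum to at most 1, so against three
independent modules no taxon can exceed $1/\sqrt{3} \approx 0.577$ per
factor — below the 0.6 edge threshold. With orthogonal modules,
network connectors *cannot exist* at these thresholds; any appearing
would be sampling artefacts. Shared forcing at 0.7 lifts
connector–member correlations to ≈ 0.7 while member pairs across
modules stay near 0.5, below threshold. This is also the ecologically
realistic regime: soil modules respond to common gradients.

**Compositional closure.** Because counts are compositional, the
softmax denominator partially cancels the shared-forcing component:
realised cross-module correlations are systematically smaller than the
latent ones, and large planted mass induces spurious background
correlations. The generator keeps planted taxa a modest share of the
community; the defaults were chosen once, on these grounds, and the
null benchmark (background-only data → empty networks) guards the
false-positive side.

**What a green benchmark does and does not establish.** The recovery
benchmark (within-module Spearman 0.8, 5×10⁴ reads, 40 samples, 20
seeds) shows ≥ 90% of planted connectors are classified connector or
network hub and ≥ 90% of background taxa entering the network stay
peripheral — under Louvain partitions, since fast-greedy's resolution
limit merges planted modules in roughly 1 seed in 10 and the merge is a
property of the detector, not the classifier. The generator does not
emulate real data's phylogenetic correlation of abundances, taxonomy
assignment error, variable library sizes, or chimeras; green tests
establish that the machinery recovers structure of the planted kind,
not that real permafrost networks are correctly inferred.

**Hub detectability.** Planted hubs reliably have the highest
within-module connectivity (their mean Zi exceeds ordinary members' by
> 1.5 z-units in the default world), but clearing the absolute
Zi > 2.5 bar in every network is not attainable at 30 samples: detected
modules there hold 10–25 nodes, and the z-score of the maximum of n
values is bounded near $\sqrt{n}$, so small or evenly-connected modules
cap Zi below 2.5 regardless of how dominant the hub is. The Zi
machinery itself is verified exactly on a deterministic star fixture
(hub Zi = 3.0). Role-recovery claims for hubs in simulated communities
are therefore comparative, not absolute.

# Numerical choices and degenerate inputs

* Spearman p at $|\rho| = 1$ is 0 by convention (the t statistic
  diverges).
* `bh_adjust` is the textbook step-up ($q_{(i)} = \min_{j \ge i}
  p_{(j)} m / j$, clipped at 1), verified against `stats::p.adjust`.
* Constant taxa and constant environmental factors never error; they
  are flagged and neutralised ($\rho = 0$).
* Empty networks propagate cleanly: zero-row Zi–Pi tables, `absent`
  cells in role-shift tables, and skipped topology reports.
* All artifacts are plain TSV/JSON at full double precision; GraphML
  round-trips edge weights to ≥ 12 decimal digits.
* Every stochastic stage takes an explicit integer seed; the pipeline
  manifest records seeds, thresholds and algorithm names, and reruns
  are byte-identical.

# Known limitations

* Only Spearman/FDR edge inference is provided (no SparCC, SPIEC-EASI
  or proportionality); compositional effects on correlation are
  documented but not corrected.
* The "Abundance (%)" summary is stratum-level (share of the stratum's
  reads belonging to retained taxa); whether the reference tables used
  stratum-level or study-level percentages is not stated, and no
  acceptance claim is made for it.
* The log-scale closeness report is a documented interpretation of
  negative printed closeness values, excluded from acceptance.
* Networks are per-stratum by design; the package never pools strata
  into one network.
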