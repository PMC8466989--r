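Package: cryonet
Title: Fungal Co-Occurrence Networks for Permafrost-Affected Soils
Version: 0.1.0
Authors@R:
    person("Cryonet", "Developers", email = "cryonet@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses microbial co-occurrence networks from
    zOTU (zero-radius OTU) count tables, as used in studies of
    permafrost-affected soil fungal communities. Provides prevalence and
    relative-abundance filtering, tie-aware Spearman correlation with
    Benjamini-Hochberg false-discovery-rate control, thresholded network
    construction, topological property reports with Erdos-Renyi G(n,m)
    null ensembles, Zi-Pi (within-module connectivity / participation
    coefficient) keystone classification with cross-stratum role-shift
    tables, module- and keystone-environment Spearman correlation, and a
    synthetic community generator with planted module, hub and connector
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
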