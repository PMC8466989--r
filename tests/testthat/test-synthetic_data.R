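test_that("simulation specs validate their invariants", {
  expect_error(simulation_spec(module_sizes = c(10L, 10L)), "length")
  expect_error(simulation_spec(n_taxa = 50L, module_sizes = rep(20L, 3L)),
               "exceed n_taxa")
  expect_error(simulation_spec(n_taxa = 80L, module_sizes = rep(20L, 3L),
                               background_taxa = 5L),
               "must equal n_taxa")
  expect_error(simulation_spec(within_module_rho = 1.2), "0, 1")
  expect_error(simulation_spec(n_modules = 2L, module_sizes = rep(10L, 2L),
                               n_taxa = 30L, n_connectors = 2L,
                               background_taxa = 8L),
               "3 modules")
  expect_error(simulation_spec(sequencing_depth = 10L), "1000")
})

test_that("simulation is deterministic and conserves sequencing depth", {
  spec <- simulation_spec(n_samples = 10L, n_taxa = 60L,
                          module_sizes = rep(15L, 3L),
                          sequencing_depth = 2000L, seed = 99L)
  s1 <- simulate_community(spec)
  s2 <- simulate_community(spec)
  expect_identical(unclass(s1$zotu), unclass(s2$zotu))
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(colSums(s1$zotu) == 2000L))
  # every sample covered by metadata, taxonomy covers every taxon
  expect_true(check_samples_covered(s1$zotu, s1$metadata))
  expect_setequal(s1$taxonomy$taxon_id, rownames(s1$zotu))
  # default spec is itself deterministic and valid
  expect_identical(default_paper_like_spec(), default_paper_like_spec())
})

test_that("noise-free limit yields near-perfect within-module correlation", {
  spec <- simulation_spec(n_samples = 30L, n_taxa = 40L, n_modules = 1L,
                          module_sizes = 5L, within_module_rho = 0.95,
                          background_taxa = 35L, sequencing_depth = 100000L,
                          overdispersion = 0, seed = 5L)
  sim <- simulate_community(spec)
  rel <- relative_abundance(sim$zotu)
  members <- sim$truth$taxon_id[sim$truth$module == "1"]
  rho <- cor(t(rel[members, ]), method = "spearman")
  expect_true(all(rho[upper.tri(rho)] >= 0.9))
})

test_that("background-only data yields a null Spearman distribution", {
  # fraction of |rho| >= 0.6 among background pairs at n = 30 stays below
  # 1%: at pop rho 0, P(|sample rho| >= 0.6) ~ 2 * pnorm(-0.693 * sqrt(27))
  # which is << 0.01 (Fisher-z argument; brute-force tail of the null)
  spec <- simulation_spec(n_samples = 30L, n_taxa = 80L, n_modules = 3L,
                          module_sizes = rep(0L, 3L), background_taxa = 80L,
                          sequencing_depth = 50000L, seed = 17L)
  sim <- simulate_community(spec)
  rho <- cor(t(relative_abundance(sim$zotu)), method = "spearman")
  frac <- mean(abs(rho[upper.tri(rho)]) >= 0.6)
  expect_lt(frac, 0.01)
})

test_that("null data yields empty networks (median over 20 seeds)", {
  sizes <- vapply(1:20, function(sd) {
    spec <- simulation_spec(n_samples = 30L, n_taxa = 100L, n_modules = 3L,
                            module_sizes = rep(0L, 3L),
                            background_taxa = 100L,
                            sequencing_depth = 50000L, seed = sd)
    igraph::vcount(infer_network(simulate_community(spec)))
  }, numeric(1))
  expect_equal(median(sizes), 0)
})

test_that("within-module edges increase monotonically with the rho target", {
  med_edges <- vapply(c(0.5, 0.65, 0.8), function(rho) {
    median(vapply(1:10, function(sd) {
      spec <- simulation_spec(n_samples = 30L, n_taxa = 150L,
                              n_modules = 3L, module_sizes = rep(25L, 3L),
                              within_module_rho = rho,
                              background_taxa = 75L,
                              sequencing_depth = 50000L, seed = sd)
      sim <- simulate_community(spec)
      net <- infer_network(sim)
      if (igraph::ecount(net) == 0) return(0)
      el <- igraph::as_edgelist(net)
      mo <- function(v) sim$truth$module[match(v, sim$truth$taxon_id)]
      sum(mo(el[, 1]) == mo(el[, 2]) & mo(el[, 1]) != "background")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_edges) > 0))
})

test_that("simulated artifacts write out and the truth links survive", {
  spec <- simulation_spec(n_samples = 8L, n_taxa = 40L,
                          module_sizes = rep(10L, 3L),
                          sequencing_depth = 1000L,
                          env_spec = list(pH = list(module = 2L,
                                                    effect = 0.9)),
                          seed = 3L)
  sim <- simulate_community(spec)
  d <- withr::local_tempdir()
  write_simulated_community(sim, d)
  expect_true(all(file.exists(file.path(d, c(
    "zotu_table.tsv", "metadata.tsv", "taxonomy.tsv", "traits.tsv",
    "truth.json")))))
  back <- read_zotu_table(file.path(d, "zotu_table.tsv"))
  expect_identical(unclass(back), unclass(sim$zotu))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$env_links$pH$module, 2)
})
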