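test_that("Pi follows the participation-coefficient formula", {
  # node with all 4 edges inside its own module -> Pi = 0
  g <- named_graph(cbind(rep("x", 4), paste0("m", 1:4)))
  memb <- setNames(rep(1L, 5), c("x", paste0("m", 1:4)))
  zp <- zipi(g, manual_partition(g, memb))
  expect_equal(zp$Pi[zp$taxon_id == "x"], 0)
  # k = 4 split 2/2 across two modules -> Pi = 0.5
  memb2 <- setNames(c(1L, 1L, 1L, 2L, 2L), c("x", "m1", "m2", "m3", "m4"))
  zp2 <- zipi(g, manual_partition(g, memb2))
  expect_equal(zp2$Pi[zp2$taxon_id == "x"], 0.5)
  expect_equal(zp2$kappa[zp2$taxon_id == "x"], 2)
})

test_that("Zi is the within-module kappa z-score, 0 for flat modules", {
  # 11-node fixture: star hub with 9 spokes in one module, 2-node module
  # elsewhere; kappa over the star module = {9, 1 x 9}, population sd 2.4
  edges <- rbind(cbind(rep("hub", 9), paste0("s", 1:9)), c("a", "b"))
  g <- named_graph(edges)
  memb <- setNames(c(1L, rep(1L, 9), 2L, 2L),
                   c("hub", paste0("s", 1:9), "a", "b"))
  zp <- zipi(g, manual_partition(g, memb))
  hub <- zp[zp$taxon_id == "hub", ]
  expect_equal(hub$kappa, 9)
  expect_equal(hub$Zi, (9 - 1.8) / 2.4, tolerance = 1e-12)  # = 3.0
  expect_gt(hub$Zi, 2.5)
  expect_equal(hub$role, "module_hub")
  # module of equal within-degrees -> Zi = 0 for each
  ab <- zp[zp$taxon_id %in% c("a", "b"), ]
  expect_equal(ab$Zi, c(0, 0))
})

test_that("zipi conservation and range invariants hold on random graphs", {
  set.seed(14)
  for (i in 1:4) {
    g <- igraph::sample_gnm(40, 100)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    igraph::E(g)$rho <- 0.8
    part <- detect_modules(g)
    zp <- zipi(g, part)
    # sum over modules of kappa_is = k_i: kappa is own-module count; check
    # via explicit neighbour-module tabulation
    memb <- part$membership
    for (j in sample(nrow(zp), 5)) {
      v <- zp$taxon_id[j]
      nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
      expect_equal(zp$kappa[j], sum(memb[nb] == memb[v]))
      expect_equal(zp$k[j], length(nb))
      kis <- table(memb[nb])
      expect_equal(zp$Pi[j], 1 - sum((kis / length(nb))^2),
                   tolerance = 1e-12)
      # Pi <= 1 - 1/M where M = number of modules touched
      expect_lte(zp$Pi[j], 1 - 1 / length(kis) + 1e-12)
    }
    # mean Zi within any module with kappa-variance > 0 is 0
    for (mod in unique(memb)) {
      zi <- zp$Zi[zp$module == mod]
      kap <- zp$kappa[zp$module == mod]
      if (stats::sd(kap) > 0) expect_equal(mean(zi), 0, tolerance = 1e-9)
    }
  }
})

test_that("role classification is exhaustive, exclusive, boundary-safe", {
  expect_equal(classify_role(0, 0), "peripheral")
  expect_equal(classify_role(3.0, 0.7), "network_hub")
  expect_equal(classify_role(1.0, 0.7), "connector")
  expect_equal(classify_role(3.0, 0.1), "module_hub")
  # values exactly at a threshold fall to the peripheral side
  expect_equal(classify_role(2.5, 0.62), "peripheral")
  expect_equal(classify_role(2.5, 0.9), "connector")
  expect_equal(classify_role(5, 0.62), "module_hub")
  # exhaustive over a grid
  grid <- expand.grid(Zi = seq(-3, 5, by = 0.5), Pi = seq(0, 0.99, 0.11))
  roles <- classify_role(grid$Zi, grid$Pi)
  expect_true(all(roles %in% c("peripheral", "connector", "module_hub",
                               "network_hub")))
  expect_equal(length(roles), nrow(grid))
})

test_that("role_shift builds the generalist table with absent cells", {
  mk <- function(ids, roles, pis = 0)
    structure(data.frame(taxon_id = ids, module = 1L, k = 3L, kappa = 3L,
                         Zi = 0, Pi = pis, role = roles,
                         stringsAsFactors = FALSE),
              class = c("zipi_records", "data.frame"))
  recs <- list(
    topsoil = mk(c("z1", "z2", "z3"),
                 c("module_hub", "peripheral", "peripheral"),
                 c(0, 0, 0.4)),
    cryoOM  = mk(c("z2", "z4"), c("connector", "peripheral")))
  rs <- role_shift(recs)
  # z3 peripheral everywhere -> excluded; z4 peripheral only -> excluded
  expect_setequal(rs$table$taxon_id, c("z1", "z2"))
  z1 <- rs$table[rs$table$taxon_id == "z1", ]
  expect_equal(z1$topsoil, "Module hubs")
  expect_equal(z1$cryoOM, "absent")
  z2 <- rs$table[rs$table$taxon_id == "z2", ]
  expect_equal(z2$topsoil, "Peripheral")
  expect_equal(z2$cryoOM, "Connectors")
  # summary: % peripheral and % of peripherals with Pi = 0
  top <- rs$summary[rs$summary$stratum == "topsoil", ]
  expect_equal(top$n_generalists, 1)
  expect_equal(top$pct_peripheral, 200 / 3, tolerance = 1e-9)
  expect_equal(top$pct_peripheral_pi0, 50)
  expect_error(role_shift(recs["topsoil"]), "2 strata")
})

test_that("shared_unique_nodes gives exact Venn counts", {
  out <- shared_unique_nodes(list(A = c("x", "y", "z"),
                                  B = c("y", "z", "w"),
                                  C = c("z")))
  get <- function(comb) out$count[out$combination == comb]
  expect_equal(get("A"), 1)          # x
  expect_equal(get("B"), 1)          # w
  expect_equal(get("C"), 0)
  expect_equal(get("A&B"), 1)        # y
  expect_equal(get("A&B&C"), 1)      # z
  expect_equal(sum(out$count), 4)
  # identical sets: everything in the full intersection
  out2 <- shared_unique_nodes(list(A = c("p", "q"), B = c("p", "q")))
  expect_equal(out2$count[out2$combination == "A&B"], 2)
  expect_equal(sum(out2$count), 2)
  # disjoint sets: no sharing
  out3 <- shared_unique_nodes(list(A = "p", B = "q"))
  expect_equal(out3$count[out3$combination == "A&B"], 0)
})
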