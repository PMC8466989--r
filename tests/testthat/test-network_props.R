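test_that("topology_report matches closed forms on K3, P3 and the star", {
  k3 <- named_graph(cbind(c("a", "a", "b"), c("b", "c", "c")))
  r3 <- topology_report(k3, manual_partition(k3, c(a = 1L, b = 1L, c = 1L)))
  expect_equal(r3$apl, 1)
  expect_equal(r3$diameter, 1)
  expect_equal(r3$clustering_coefficient, 1)
  expect_equal(r3$edge_density, 1)
  expect_equal(r3$degree_mean, 2)

  p3 <- named_graph(cbind(c("a", "b"), c("b", "c")))
  rp <- topology_report(p3, manual_partition(p3, c(a = 1L, b = 1L, c = 1L)))
  expect_equal(rp$apl, 4 / 3)
  expect_equal(rp$diameter, 2)
  expect_equal(rp$clustering_coefficient, 0)

  star <- named_graph(cbind(rep("hub", 3), c("l1", "l2", "l3")))
  part <- manual_partition(star, setNames(rep(1L, 4),
                                          c("hub", "l1", "l2", "l3")))
  rs <- topology_report(star, part)
  expect_equal(rs$clustering_coefficient, 0)
  # center betweenness: 3 leaf pairs all route through the hub
  btw <- igraph::betweenness(star, directed = FALSE)
  expect_equal(unname(btw["hub"]), 3)
  expect_equal(rs$betweenness_mean, 3 / 4)
})

test_that("report identities hold exactly on arbitrary graphs (property)", {
  set.seed(5)
  for (i in 1:4) {
    g <- igraph::sample_gnm(30, 60)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    igraph::E(g)$rho <- runif(igraph::ecount(g), 0.6, 1)
    rep_ <- topology_report(g, detect_modules(g))
    nn <- rep_$n_nodes; ne <- rep_$n_edges
    expect_equal(rep_$edge_density, 2 * ne / (nn * (nn - 1)))
    expect_equal(rep_$degree_mean, 2 * ne / nn)
    expect_equal(rep_$n_significant_correlations, 2 * ne)
    expect_true(rep_$modularity >= -0.5 && rep_$modularity <= 1)
    expect_true(rep_$diameter >= rep_$apl)
  }
})

test_that("detect_modules finds the exhaustively optimal two-clique split", {
  g <- two_clique_graph()
  part <- detect_modules(g, "greedy")
  expect_equal(part$n_modules, 2)
  expect_equal(sort(unname(part$membership[paste0("n", 1:4)])), rep(1L, 4))
  # brute-force oracle: enumerate all set partitions of 8 nodes
  best <- -Inf
  rec <- function(s, m) {
    if (length(s) == 8L) {
      q <- igraph::modularity(g, s)
      if (q > best) best <<- q
      return()
    }
    for (v in seq_len(m + 1L)) rec(c(s, v), max(m, v))
  }
  rec(1L, 1L)
  expect_equal(part$modularity, best, tolerance = 1e-12)
  expect_equal(best, 11 / 26, tolerance = 1e-12)
})

test_that("complete graphs collapse to one module with Q = 0", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("v", 1:5)
  igraph::E(k5)$rho <- 0.9
  part <- detect_modules(k5)
  expect_equal(part$n_modules, 1)
  expect_equal(part$modularity, 0)
})

test_that("module detection is deterministic and size-ordered", {
  set.seed(8)
  g <- igraph::sample_gnm(40, 90)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  for (alg in c("greedy", "louvain")) {
    p1 <- detect_modules(g, alg, seed = 7)
    p2 <- detect_modules(g, alg, seed = 7)
    expect_identical(p1$membership, p2$membership)
    sizes <- tabulate(p1$membership)
    expect_true(all(diff(sizes) <= 0))  # module 1 is largest
  }
})

test_that("random_ensemble reproduces degenerate and theoretical cases", {
  # forced K4: every replicate is complete
  ens <- random_ensemble(4, 6, reps = 20, seed = 3)
  expect_equal(ens$apl_mean, 1)
  expect_equal(ens$apl_sd, 0)
  expect_equal(ens$cc_mean, 1)
  expect_error(random_ensemble(4, 7, reps = 2, seed = 1), "more edges")
  # ER transitivity converges to the edge density at n = 200
  n <- 200; mm <- 1990
  ens2 <- random_ensemble(n, mm, reps = 40, seed = 5, metrics = "cc")
  dens <- 2 * mm / (n * (n - 1))
  expect_lt(abs(ens2$cc_mean - dens), 3 * ens2$cc_sd)
  # determinism
  ens3 <- random_ensemble(n, mm, reps = 10, seed = 5, metrics = "cc")
  ens4 <- random_ensemble(n, mm, reps = 10, seed = 5, metrics = "cc")
  expect_identical(ens3$cc_mean, ens4$cc_mean)
})

test_that("paper-like networks beat their own null ensemble's modularity", {
  # 10 seeds; empirical Q must exceed the G(n,m) ensemble mean each time
  for (sd in 1:10) {
    spec <- default_paper_like_spec(); spec$seed <- as.integer(sd)
    net <- infer_network(simulate_community(spec))
    part <- detect_modules(net)
    nullq <- random_ensemble(igraph::vcount(net), igraph::ecount(net),
                             reps = 15, seed = 1,
                             metrics = "modularity")$modularity_mean
    expect_gt(part$modularity, nullq)
  }
})

test_that("topology report serialises to JSON and back", {
  g <- two_clique_graph()
  rep_ <- topology_report(g, detect_modules(g), n_taxa_filtered = 10,
                          abundance_pct = 61.1)
  f <- withr::local_tempfile(fileext = ".json")
  write_topology_report(rep_, f, random_ensemble(8, 13, reps = 5, seed = 2))
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$empirical$n_nodes, 8)
  expect_equal(back$empirical$edge_density, 13 / 28, tolerance = 1e-12)
  expect_equal(back$random$reps, 5)
})
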