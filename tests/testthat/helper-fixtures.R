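# Shared fixtures: tiny tables and graphs built in code.

# 3 taxa x 4 samples count table
tiny_counts <- function() {
  m <- matrix(c(5L, 0L, 2L, 1L,
                0L, 3L, 3L, 3L,
                10L, 7L, 0L, 6L), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"),
                              c("s1", "s2", "s3", "s4")))
  m
}

write_tiny_tsv <- function(m, path, transpose = FALSE) {
  if (transpose) m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# two K4 cliques joined by a single bridge edge (8 nodes, 13 edges)
two_clique_graph <- function() {
  el <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 5))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:8)
  igraph::E(g)$rho <- 0.9
  igraph::E(g)$sign <- "+"
  g
}

named_graph <- function(edges, rho = 0.8) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE)
  igraph::E(g)$rho <- rho
  igraph::E(g)$sign <- ifelse(rho >= 0, "+", "-")
  g
}

# hand-built partition object (bypasses detection)
manual_partition <- function(net, membership) {
  structure(list(membership = membership,
                 modularity = igraph::modularity(
                   net, membership[igraph::V(net)$name]),
                 n_modules = max(membership),
                 algorithm = "manual", seed = 0L),
            class = "module_partition")
}

# simulation spec used for the planted-role recovery benchmarks
recovery_spec <- function(seed) {
  simulation_spec(n_samples = 40L, n_taxa = 500L, n_modules = 4L,
                  module_sizes = rep(30L, 4L), within_module_rho = 0.8,
                  n_connectors = 5L, n_module_hubs = 4L,
                  background_taxa = 375L, sequencing_depth = 50000L,
                  overdispersion = 0.3, seed = seed)
}

# run table -> filtered -> network for a simulated community
infer_network <- function(sim, thr = edge_thresholds()) {
  filt <- suppressWarnings(filter_taxa(relative_abundance(sim$zotu)))
  build_network(spearman_matrix(filt), thr)
}
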