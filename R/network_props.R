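# Topological property report, modularity-based module detection, and the
# seeded Erdos-Renyi G(n,m) null ensemble used to show that empirical
# networks are non-random.

#' Detect modules by heuristic modularity maximisation
#'
#' `"greedy"` (default) is fast-greedy agglomerative modularity
#' optimisation, which is deterministic; `"louvain"` is multilevel
#' optimisation, made reproducible by the seed. Modularity Q is the
#' Newman-Girvan quantity on the unweighted graph. Module ids are
#' relabelled 1-based in decreasing order of module size, ties broken by
#' the lowest original vertex index, so module 1 is always (one of) the
#' largest.
#'
#' @param net co-occurrence network (igraph).
#' @param algorithm `"greedy"` or `"louvain"`.
#' @param seed integer; fixes the partition for stochastic algorithms.
#' @return object of class `module_partition`: list with named integer
#'   `membership`, `modularity`, `n_modules`, `algorithm`, `seed`.
#' @export
detect_modules <- function(net, algorithm = c("greedy", "louvain"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  nv <- igraph::vcount(net)
  if (nv == 0L)
    return(structure(list(membership = integer(0), modularity = NA_real_,
                          n_modules = 0L, algorithm = algorithm,
                          seed = as.integer(seed)),
                     class = "module_partition"))
  comm <- with_seed(seed, switch(algorithm,
    greedy = igraph::cluster_fast_greedy(net),
    louvain = igraph::cluster_louvain(net)))
  memb <- as.integer(igraph::membership(comm))
  # never return worse than the trivial single-community partition
  # (fast-greedy can cut a clique at negative modularity on ties)
  if (igraph::modularity(net, memb) < 0) memb <- rep(1L, nv)
  # relabel by decreasing size, ties by first (lowest-index) member
  sizes <- tabulate(memb)
  first <- vapply(seq_along(sizes), function(k) match(k, memb), integer(1))
  ord <- order(-sizes, first)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  memb <- relabel[memb]
  names(memb) <- igraph::V(net)$name
  structure(list(membership = memb,
                 modularity = igraph::modularity(net, memb),
                 n_modules = max(memb),
                 algorithm = algorithm, seed = as.integer(seed)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition (%s): %d modules, Q = %.4f\n",
              x$algorithm, x$n_modules, x$modularity))
  invisible(x)
}

# per-node closeness computed within components (all nodes have degree
# >= 1 so every component has >= 2 vertices)
.closeness_within_component <- function(net) {
  suppressWarnings(igraph::closeness(net, mode = "all"))
}

#' Full topological property report for one network
#'
#' Mirrors the usual co-occurrence-network summary: node/edge counts and
#' signs, average path length over connected pairs only (disconnected
#' pairs excluded), mean +/- sd degree, mean +/- sd of the natural log of
#' within-component closeness (plus the untransformed mean), mean +/- sd
#' unnormalised betweenness, edge density, diameter (largest finite
#' shortest path), global transitivity (and the average-local variant),
#' module count and modularity.
#'
#' @param net co-occurrence network with >= 2 nodes.
#' @param partition a [detect_modules()] result (computed if `NULL`).
#' @param n_taxa_filtered optional count of taxa that entered inference.
#' @param abundance_pct optional % of group reads retained by the filter.
#' @return object of class `topology_report` (a list).
#' @export
topology_report <- function(net, partition = NULL, n_taxa_filtered = NA,
                            abundance_pct = NA) {
  if (igraph::vcount(net) < 2L)
    abort("topology_report: need at least 2 nodes")
  if (is.null(partition)) partition <- detect_modules(net)
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  cl <- .closeness_within_component(net)
  signs <- edge_sign_counts(net)
  nn <- igraph::vcount(net)
  ne <- igraph::ecount(net)
  cc_global <- igraph::transitivity(net, type = "global")
  cc_local <- igraph::transitivity(net, type = "localaverage", isolates = "zero")
  structure(list(
    total_taxa_after_filter = n_taxa_filtered,
    abundance_pct_retained = abundance_pct,
    n_significant_correlations = 2L * ne,
    n_nodes = nn, n_edges = ne,
    n_pos_edges = unname(signs["positive"]),
    n_neg_edges = unname(signs["negative"]),
    apl = igraph::mean_distance(net, directed = FALSE, unconnected = TRUE),
    degree_mean = mean(deg), degree_sd = stats::sd(deg),
    closeness_mean = mean(cl),
    closeness_log_mean = mean(log(cl)),
    closeness_log_sd = stats::sd(log(cl)),
    betweenness_mean = mean(btw), betweenness_sd = stats::sd(btw),
    edge_density = 2 * ne / (nn * (nn - 1)),
    diameter = igraph::diameter(net, directed = FALSE, unconnected = TRUE),
    clustering_coefficient = if (is.nan(cc_global)) 0 else cc_global,
    clustering_coefficient_local = cc_local,
    n_modules = partition$n_modules,
    modularity = partition$modularity,
    module_algorithm = partition$algorithm),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(paste0(
    "co-occurrence network report\n",
    "  nodes %d, edges %d (+%d / -%d), density %.4g\n",
    "  APL %.3f, diameter %d, transitivity %.3f\n",
    "  degree %.2f +/- %.2f, ln-closeness %.2f +/- %.2f\n",
    "  betweenness %.1f +/- %.1f\n",
    "  modules %d, modularity %.3f (%s)\n"),
    x$n_nodes, x$n_edges, x$n_pos_edges, x$n_neg_edges, x$edge_density,
    x$apl, x$diameter, x$clustering_coefficient,
    x$degree_mean, x$degree_sd, x$closeness_log_mean, x$closeness_log_sd,
    x$betweenness_mean, x$betweenness_sd, x$n_modules, x$modularity,
    x$module_algorithm))
  invisible(x)
}

#' Erdos-Renyi G(n,m) null ensemble
#'
#' Draws `reps` uniform simple graphs with exactly `n_nodes` vertices and
#' `n_edges` edges (fixed edge count, no loops or multi-edges) and
#' summarises average path length (connected pairs only), global
#' transitivity, and modularity under the same module-detection
#' algorithm as the empirical network.
#'
#' @param n_nodes,n_edges size of each replicate graph.
#' @param reps number of replicates (1000 for the standard comparison).
#' @param seed integer RNG seed.
#' @param algorithm module-detection algorithm, as in [detect_modules()].
#' @param metrics character subset of `c("apl", "cc", "modularity")`;
#'   dropping `"modularity"` roughly halves the runtime.
#' @return object of class `null_ensemble_summary`: mean and sd per
#'   metric plus the ensemble parameters.
#' @export
random_ensemble <- function(n_nodes, n_edges, reps = 1000L, seed = 1L,
                            algorithm = c("greedy", "louvain"),
                            metrics = c("apl", "cc", "modularity")) {
  algorithm <- match.arg(algorithm)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    abort("random_ensemble: more edges than a simple graph on ",
          n_nodes, " nodes allows")
  stopifnot(reps >= 1)
  apl <- cc <- mod <- rep(NA_real_, reps)
  with_seed(seed, for (i in seq_len(reps)) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    if ("apl" %in% metrics)
      apl[i] <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    if ("cc" %in% metrics) {
      v <- igraph::transitivity(g, type = "global")
      cc[i] <- if (is.nan(v)) 0 else v
    }
    if ("modularity" %in% metrics) {
      g2 <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
      mod[i] <- if (igraph::vcount(g2) > 0)
        detect_modules(g2, algorithm, seed = seed)$modularity else NA_real_
    }
  })
  msd <- function(x) if (all(is.na(x))) c(NA_real_, NA_real_)
                     else c(mean(x), stats::sd(x))
  a <- msd(apl); c_ <- msd(cc); m <- msd(mod)
  structure(list(reps = as.integer(reps), n_nodes = n_nodes,
                 n_edges = n_edges,
                 apl_mean = a[1], apl_sd = a[2],
                 cc_mean = c_[1], cc_sd = c_[2],
                 modularity_mean = m[1], modularity_sd = m[2],
                 seed = as.integer(seed), algorithm = algorithm),
            class = "null_ensemble_summary")
}

#' @export
print.null_ensemble_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "G(n=%d, m=%d) ensemble, %d reps (seed %d)\n",
    "  APL %.3f +/- %.3f | CC %.4f +/- %.4f | M %.3f +/- %.3f\n"),
    x$n_nodes, x$n_edges, x$reps, x$seed,
    x$apl_mean, x$apl_sd, x$cc_mean, x$cc_sd,
    x$modularity_mean, x$modularity_sd))
  invisible(x)
}

#' Write a topology report (+ optional null summary) as JSON
#' @param report a [topology_report()].
#' @param path output path.
#' @param null_summary optional [random_ensemble()] result.
#' @export
write_topology_report <- function(report, path, null_summary = NULL) {
  payload <- list(empirical = unclass(report))
  if (!is.null(null_summary)) payload$random <- unclass(null_summary)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
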