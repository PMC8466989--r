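# End-to-end orchestration: (simulate | load) -> filter -> network ->
# topology + null ensemble -> Zi-Pi -> role shift -> environment
# correlation -> report, one network per group level, with a manifest
# that makes a run reproducible byte-for-byte.

#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to the four tables) or `spec` (a
#' [simulation_spec()]) must be supplied.
#'
#' @param inputs named list with paths `zotu`, `metadata`, and optionally
#'   `taxonomy`, `traits`.
#' @param spec a [simulation_spec()] for a synthetic run.
#' @param group grouping variable: `"horizon"` or `"site"`; one network
#'   is built per group level, never one pooled network.
#' @param filter a [filter_params()].
#' @param thresholds an [edge_thresholds()].
#' @param null_reps replicates for the random ensemble (0 disables it).
#' @param algorithm module detection algorithm.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir output directory.
#' @export
pipeline_config <- function(inputs = NULL, spec = NULL,
                            group = c("horizon", "site"),
                            filter = filter_params(),
                            thresholds = edge_thresholds(),
                            null_reps = 1000L,
                            algorithm = c("greedy", "louvain"),
                            seed = 1L, out_dir = "cryonet_out") {
  group <- match.arg(group)
  algorithm <- match.arg(algorithm)
  if (is.null(inputs) == is.null(spec))
    abort("pipeline_config: supply exactly one of inputs or spec")
  if (!is.null(spec)) stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(inputs) && !all(c("zotu", "metadata") %in% names(inputs)))
    abort("pipeline_config: inputs need at least 'zotu' and 'metadata'")
  structure(list(inputs = inputs, spec = spec, group = group,
                 filter = filter, thresholds = thresholds,
                 null_reps = as.integer(null_reps), algorithm = algorithm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, group, expr) {
  tryCatch(expr, error = function(e)
    abort(sprintf("pipeline stage '%s' failed for group '%s': %s",
                  name, group, conditionMessage(e))))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full co-occurrence analysis pipeline
#'
#' For every level of the grouping variable: prevalence/abundance filter,
#' Spearman/FDR network, topology report with Erdos-Renyi null ensemble,
#' Zi-Pi table, and module/keystone-environment correlation over that
#' group's samples only; then one role-shift table and shared/unique
#' node counts across levels. All artifacts are TSV/JSON under
#' `out_dir/<group level>/`; a `manifest.json` records versions, seeds,
#' thresholds, algorithm names and md5 hashes of every artifact, so a
#' rerun with the same config and seed is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  keep <- function(p) { artifacts[[length(artifacts) + 1L]] <<- p; p }

  # stage 1: acquire data
  if (!is.null(config$spec)) {
    message("stage simulate: seed ", config$spec$seed)
    sim <- .stage("simulate", "-", simulate_community(config$spec))
    zotu <- sim$zotu; meta <- sim$metadata
    taxonomy <- sim$taxonomy; traits <- sim$traits
    keep(.write_tsv(sim$truth, file.path(config$out_dir, "truth.tsv")))
  } else {
    message("stage load: ", config$inputs$zotu)
    zotu <- .stage("load", "-", read_zotu_table(config$inputs$zotu))
    meta <- .stage("load", "-", read_sample_metadata(config$inputs$metadata))
    taxonomy <- if (!is.null(config$inputs$taxonomy))
      read_taxonomy(config$inputs$taxonomy) else NULL
    traits <- if (!is.null(config$inputs$traits))
      read_traits(config$inputs$traits) else NULL
  }
  check_samples_covered(zotu, meta)
  rel <- relative_abundance(zotu)
  lifestyles <- if (!is.null(taxonomy) && !is.null(traits))
    assign_lifestyles(zotu, taxonomy, traits)
  else stats::setNames(rep("unassigned", nrow(zotu)), rownames(zotu))

  levels_ <- unique(as.character(meta[[config$group]]))
  nets <- list(); zipis <- list()
  for (lev in levels_) {
    gdir <- file.path(config$out_dir, paste0(config$group, "_", lev))
    dir.create(gdir, showWarnings = FALSE)
    samples <- meta$sample_id[as.character(meta[[config$group]]) == lev]

    message("stage filter [", lev, "]: ", length(samples), " samples")
    filt <- .stage("filter", lev,
                   suppressWarnings(filter_taxa(rel, config$filter, samples)))
    fs <- filter_summary(rel, filt)
    message("  taxa ", fs$n_taxa_before, " -> ", fs$n_taxa_after,
            sprintf(" (%.1f%% of reads retained)",
                    fs$abundance_pct_retained))
    keep(.write_tsv(cbind(data.frame(taxon_id = rownames(filt)),
                          as.data.frame(unclass(filt))),
                    file.path(gdir, "filtered.tsv")))

    message("stage network [", lev, "]")
    net <- .stage("network", lev, {
      corr <- spearman_matrix(filt)
      attrs <- data.frame(taxon_id = rownames(filt),
                          abundance = rowMeans(filt),
                          lifestyle = unname(lifestyles[rownames(filt)]),
                          stringsAsFactors = FALSE)
      keep(.write_tsv(significant_pairs(corr, config$thresholds),
                      file.path(gdir, "significant_pairs.tsv")))
      build_network(corr, config$thresholds, attrs)
    })
    nets[[lev]] <- net
    message("  nodes ", igraph::vcount(net), ", edges ", igraph::ecount(net))
    if (igraph::ecount(net) == 0) {
      zipis[[lev]] <- zipi(net, detect_modules(net))
      next  # empty network is legal; nothing more to report for it
    }
    keep(write_network(net, file.path(gdir, "network.graphml"), "graphml"))
    keep(write_network(net, file.path(gdir, "edges.tsv"), "edge_tsv"))

    message("stage props [", lev, "]")
    part <- .stage("props", lev,
                   detect_modules(net, config$algorithm, config$seed))
    report <- .stage("props", lev,
                     topology_report(net, part, fs$n_taxa_after,
                                     fs$abundance_pct_retained))
    null_sum <- if (config$null_reps > 0)
      .stage("null", lev,
             random_ensemble(igraph::vcount(net), igraph::ecount(net),
                             reps = config$null_reps, seed = config$seed,
                             algorithm = config$algorithm)) else NULL
    keep(write_topology_report(report, file.path(gdir, "report.json"),
                               null_sum))
    keep(.write_tsv(data.frame(taxon_id = names(part$membership),
                               module = unname(part$membership)),
                    file.path(gdir, "modules.tsv")))

    message("stage zipi [", lev, "]")
    zp <- .stage("zipi", lev, zipi(net, part))
    zipis[[lev]] <- zp
    keep(.write_tsv(zp, file.path(gdir, "zipi.tsv")))

    message("stage envcorr [", lev, "]")
    ec <- .stage("envcorr", lev, {
      profs <- module_profiles(net, part, filt, lifestyles, top_k = 5L)
      series <- stats::setNames(
        lapply(profs, `[[`, "abundance"),
        sprintf("module_%d", vapply(profs, `[[`, 1L, "module_id")))
      keys <- zp$taxon_id[zp$role %in% .generalist_roles]
      for (k in keys) series[[k]] <- filt[k, ]
      gm <- meta[meta$sample_id %in% samples, , drop = FALSE]
      env_correlate(series, gm)
    })
    keep(.write_tsv(ec, file.path(gdir, "env_correlation.tsv")))
    comp <- do.call(rbind, lapply(
      module_profiles(net, part, filt, lifestyles, top_k = 5L),
      function(p) data.frame(module = p$module_id,
                             lifestyle = names(p$composition),
                             fraction = as.numeric(p$composition))))
    keep(.write_tsv(comp, file.path(gdir, "module_lifestyles.tsv")))
  }

  message("stage roleshift")
  if (length(zipis) >= 2L) {
    rs <- .stage("roleshift", "-",
                 role_shift(zipis, taxonomy = taxonomy,
                            lifestyles = lifestyles))
    keep(.write_tsv(rs$table, file.path(config$out_dir, "role_shift.tsv")))
    keep(.write_tsv(rs$summary,
                    file.path(config$out_dir, "role_summary.tsv")))
    nonempty <- nets[vapply(nets, igraph::vcount, numeric(1)) > 0]
    if (length(nonempty) >= 2L)
      keep(.write_tsv(shared_unique_nodes(nonempty),
                      file.path(config$out_dir, "shared_nodes.tsv")))
  }

  manifest <- list(
    package = "cryonet",
    version = as.character(utils::packageVersion("cryonet")),
    seed = config$seed,
    group = config$group,
    group_levels = levels_,
    filter = unclass(config$filter),
    thresholds = unclass(config$thresholds),
    null_reps = config$null_reps,
    module_algorithm = config$algorithm,
    stages = c("simulate_or_load", "filter", "network", "props", "null",
               "zipi", "roleshift", "envcorr"),
    artifacts = lapply(
      stats::setNames(artifacts,
                      sub(paste0("^", config$out_dir, "/?"), "", artifacts)),
      function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
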