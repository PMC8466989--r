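# Zi-Pi topological roles: within-module degree z-score (Zi),
# participation coefficient (Pi), the four-way role classification, and
# cross-stratum role-shift tables.

#' Within-module connectivity (Zi) and participation coefficient (Pi)
#'
#' For node i with degree `k_i` and `kappa_is` links into module s,
#' `Zi = (kappa_i - mean kappa over i's module) / (sd kappa over module)`
#' using the population sd (z-score within the module; `Zi = 0` when that
#' sd is 0, i.e. all members are structurally equivalent), and
#' `Pi = 1 - sum_s (kappa_is / k_i)^2`, 0 when every edge stays inside
#' the node's own module.
#'
#' @param net co-occurrence network (igraph).
#' @param partition a [detect_modules()] partition covering all nodes.
#' @return data.frame (class `zipi_records`) with columns `taxon_id`,
#'   `module`, `k`, `kappa`, `Zi`, `Pi`, `role`.
#' @export
zipi <- function(net, partition) {
  nv <- igraph::vcount(net)
  if (nv == 0L)
    return(structure(data.frame(taxon_id = character(0), module = integer(0),
                                k = integer(0), kappa = integer(0),
                                Zi = numeric(0), Pi = numeric(0),
                                role = character(0),
                                stringsAsFactors = FALSE),
                     class = c("zipi_records", "data.frame")))
  memb <- partition$membership
  vn <- igraph::V(net)$name
  if (!all(vn %in% names(memb)))
    abort("zipi: partition does not cover all nodes")
  memb <- memb[vn]
  el <- igraph::as_edgelist(net, names = TRUE)
  # directed view of each undirected edge: node -> neighbour's module
  node <- c(el[, 1L], el[, 2L])
  nbr_mod <- c(memb[el[, 2L]], memb[el[, 1L]])
  k <- igraph::degree(net)
  # kappa_is table: rows nodes, cols modules
  kmat <- table(factor(node, levels = vn),
                factor(nbr_mod, levels = sort(unique(memb))))
  kmat <- matrix(as.integer(kmat), nrow = nv,
                 dimnames = dimnames(kmat))
  kappa <- kmat[cbind(seq_len(nv), match(memb, colnames(kmat)))]
  pi <- 1 - rowSums((kmat / k[vn])^2)
  # z-score of kappa within each module (population sd)
  zi <- numeric(nv)
  for (mod in unique(memb)) {
    idx <- which(memb == mod)
    mu <- mean(kappa[idx])
    sdev <- sqrt(mean((kappa[idx] - mu)^2))
    zi[idx] <- if (sdev > 0) (kappa[idx] - mu) / sdev else 0
  }
  out <- data.frame(taxon_id = vn, module = unname(memb),
                    k = unname(k[vn]), kappa = kappa, Zi = zi, Pi = pi,
                    role = classify_role(zi, pi),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("zipi_records", "data.frame")
  out
}

#' Four-way topological role from (Zi, Pi)
#'
#' peripheral (specialist): `Zi < 2.5` and `Pi < 0.62`; connector
#' (generalist): `Zi < 2.5`, `Pi > 0.62`; module hub (generalist):
#' `Zi > 2.5`, `Pi < 0.62`; network hub (supergeneralist): both high.
#' Values exactly at a threshold fall to the low (peripheral) side —
#' conservative keystone calling.
#'
#' @param Zi,Pi numeric vectors (recycled).
#' @param z_thresh,p_thresh thresholds, conventionally 2.5 and 0.62.
#' @return character vector of roles.
#' @export
classify_role <- function(Zi, Pi, z_thresh = 2.5, p_thresh = 0.62) {
  high_z <- Zi > z_thresh
  high_p <- Pi > p_thresh
  out <- rep("peripheral", length(high_z))
  out[!high_z & high_p] <- "connector"
  out[high_z & !high_p] <- "module_hub"
  out[high_z & high_p] <- "network_hub"
  out
}

.role_display <- c(peripheral = "Peripheral", connector = "Connectors",
                   module_hub = "Module hubs", network_hub = "Network hubs")
.generalist_roles <- c("connector", "module_hub", "network_hub")

#' Cross-stratum topological role-shift table
#'
#' Rows are taxa that are generalists (connector, module hub or network
#' hub) in at least one stratum; columns give the role display label per
#' stratum, with `"absent"` for taxa that are not nodes of that
#' stratum's network. Optional taxonomy / lifestyle annotations are
#' joined in. A per-stratum summary (generalist count, % peripherals,
#' % peripherals with Pi = 0) is attached.
#'
#' @param records_by_stratum named list (>= 2 strata) of [zipi()] tables.
#' @param taxonomy optional taxonomy table for genus/species columns.
#' @param lifestyles optional named vector taxon_id -> lifestyle.
#' @return list of class `role_shift_table` with elements `table` and
#'   `summary`.
#' @export
role_shift <- function(records_by_stratum, taxonomy = NULL,
                       lifestyles = NULL) {
  if (length(records_by_stratum) < 2L)
    abort("role_shift: need records for at least 2 strata")
  if (is.null(names(records_by_stratum)))
    abort("role_shift: records_by_stratum must be named by stratum")
  strata <- names(records_by_stratum)
  generalists <- unique(unlist(lapply(records_by_stratum, function(r)
    r$taxon_id[r$role %in% .generalist_roles])))
  generalists <- sort(generalists)
  tab <- data.frame(taxon_id = generalists, stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    i <- match(generalists, taxonomy$taxon_id)
    tab$genus <- taxonomy$genus[i]
    tab$species <- taxonomy$species[i]
  }
  if (!is.null(lifestyles))
    tab$lifestyle <- unname(lifestyles[generalists])
  for (s in strata) {
    r <- records_by_stratum[[s]]
    role <- r$role[match(generalists, r$taxon_id)]
    tab[[s]] <- ifelse(is.na(role), "absent",
                       unname(.role_display[role]))
  }
  summary <- do.call(rbind, lapply(strata, function(s) {
    r <- records_by_stratum[[s]]
    periph <- r$role == "peripheral"
    data.frame(stratum = s,
               n_nodes = nrow(r),
               n_generalists = sum(r$role %in% .generalist_roles),
               pct_peripheral = if (nrow(r)) 100 * mean(periph) else NA_real_,
               pct_peripheral_pi0 = if (any(periph))
                 100 * mean(r$Pi[periph] == 0) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, summary = summary),
            class = "role_shift_table")
}

#' Shared and unique node counts across stratum networks
#'
#' Venn semantics: for every non-empty combination of strata, the number
#' of node ids present in exactly those strata's networks.
#'
#' @param networks_by_stratum named list (>= 2) of igraph networks or
#'   character vectors of node ids.
#' @return data.frame with `combination` (strata joined by `&`),
#'   `n_strata`, `count`.
#' @export
shared_unique_nodes <- function(networks_by_stratum) {
  if (length(networks_by_stratum) < 2L)
    abort("shared_unique_nodes: need at least 2 strata")
  sets <- lapply(networks_by_stratum, function(x)
    if (igraph::is_igraph(x)) igraph::V(x)$name else as.character(x))
  strata <- names(sets)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, strata))
  key <- apply(member, 1L, function(row)
    paste(strata[row], collapse = "&"))
  combos <- unlist(lapply(seq_along(strata), function(k)
    utils::combn(strata, k, paste, collapse = "&")))
  counts <- table(factor(key, levels = combos))
  data.frame(combination = combos,
             n_strata = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = as.integer(counts),
             stringsAsFactors = FALSE)
}
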