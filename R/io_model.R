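# Core typed data model: zOTU count tables, relative-abundance tables,
# sample metadata, taxonomy, lifestyle traits, and co-occurrence networks,
# plus readers/writers for their plain-text representations.

#' Construct a validated zOTU count table
#'
#' The canonical internal layout is taxa in rows, samples in columns.
#' Counts must be non-negative integers; taxon and sample ids must be
#' unique; at least one taxon and two samples are required.
#'
#' @param counts numeric matrix, taxa x samples, with dimnames.
#' @return an integer matrix of class `zotu_table`.
#' @export
zotu_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("zotu_table: counts must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    abort("zotu_table: duplicate id among taxa: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    abort("zotu_table: duplicate id among samples")
  if (!is.numeric(counts) || anyNA(counts))
    abort("zotu_table: counts must be numeric and complete")
  if (any(counts < 0)) abort("zotu_table: negative counts")
  if (any(counts != round(counts))) abort("zotu_table: non-integer counts")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    abort("zotu_table: need at least 1 taxon and 2 samples")
  storage.mode(counts) <- "integer"
  class(counts) <- c("zotu_table", class(matrix()))
  counts
}

#' @export
print.zotu_table <- function(x, ...) {
  cat(sprintf("zOTU table: %d taxa x %d samples, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

.read_table_file <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"", fill = FALSE)
}

#' Read a zOTU count table from TSV/CSV
#'
#' Expects one header row and one leading id column. Both common
#' orientations are accepted; the result is always taxa x samples.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @param orientation `"taxa_rows"` (default) if rows are taxa,
#'   `"samples_rows"` if rows are samples.
#' @return a [zotu_table()].
#' @export
read_zotu_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- .read_table_file(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    abort("read_zotu_table: duplicate id '",
          ids[duplicated(ids)][1L], "' in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort("read_zotu_table: non-numeric counts in ", path)
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  zotu_table(m)
}

#' Write a zOTU table as TSV (taxa rows, leading `taxon_id` column)
#' @param x a [zotu_table()].
#' @param path output path.
#' @export
write_zotu_table <- function(x, path) {
  df <- data.frame(taxon_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' @param df data.frame with columns `sample_id`, `horizon`
#'   (one of [horizon_levels()]), `site` (1..4) and any of the
#'   [env_factor_names()] columns. Missing environmental values (`NA`)
#'   are permitted and are pairwise-deleted downstream.
#' @return data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "horizon", "site")
  if (!all(req %in% names(df)))
    abort("sample_metadata: need columns ", paste(req, collapse = ", "))
  if (anyDuplicated(df$sample_id)) abort("sample_metadata: duplicate sample_id")
  if (!all(df$horizon %in% horizon_levels()))
    abort("sample_metadata: horizon must be one of ",
          paste(horizon_levels(), collapse = "/"))
  if (!all(df$site %in% 1:4)) abort("sample_metadata: site must be in 1..4")
  if ("pH" %in% names(df) && any(df$pH < 0 | df$pH > 14, na.rm = TRUE))
    abort("sample_metadata: pH outside [0, 14]")
  if ("moisture" %in% names(df) &&
      any(df$moisture < 0 | df$moisture > 100, na.rm = TRUE))
    abort("sample_metadata: moisture outside [0, 100]")
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV/CSV
#' @param path file path.
#' @export
read_sample_metadata <- function(path) sample_metadata(.read_table_file(path))

#' Check that every sample of a table has a metadata row
#' @param table a [zotu_table()] or relative-abundance matrix.
#' @param meta a [sample_metadata()].
#' @export
check_samples_covered <- function(table, meta) {
  missing <- setdiff(colnames(table), meta$sample_id)
  if (length(missing))
    abort("samples without metadata: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

.tax_ranks <- c("kingdom", "phylum", "class", "order", "family",
                "genus", "species")

#' Parse semicolon-delimited lineages into a 7-rank taxonomy table
#'
#' Accepts UNITE-style lineage strings with or without `k__`-style rank
#' prefixes; ranks are stored positionally (kingdom..species) and missing
#' ranks become `"unidentified"`.
#'
#' @param taxon_ids character vector.
#' @param lineages character vector of semicolon-delimited lineages.
#' @return data.frame of class `taxonomy_table` with `taxon_id` plus the
#'   seven rank columns.
#' @export
parse_taxonomy <- function(taxon_ids, lineages) {
  if (anyDuplicated(taxon_ids)) abort("parse_taxonomy: duplicate taxon_id")
  ranks <- lapply(strsplit(lineages, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v <- sub("^[kpcofgs]__", "", v)
    v[v == "" | is.na(v)] <- "unidentified"
    length(v) <- 7L
    v[is.na(v)] <- "unidentified"
    v
  })
  out <- as.data.frame(do.call(rbind, ranks), stringsAsFactors = FALSE)
  names(out) <- .tax_ranks
  out <- cbind(data.frame(taxon_id = as.character(taxon_ids),
                          stringsAsFactors = FALSE), out)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Read a taxonomy table (taxon_id TAB lineage, or pre-split rank columns)
#' @param path file path.
#' @export
read_taxonomy <- function(path) {
  df <- .read_table_file(path)
  if (ncol(df) == 2L) return(parse_taxonomy(df[[1L]], df[[2L]]))
  if (!all(.tax_ranks %in% names(df)))
    abort("read_taxonomy: expected 'taxon_id<TAB>lineage' or rank columns")
  out <- df[, c(names(df)[1L], .tax_ranks)]
  names(out)[1L] <- "taxon_id"
  out$taxon_id <- as.character(out$taxon_id)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Construct a genus -> lifestyle/trophic-mode traits table
#'
#' FungalTraits-style lookup. Genera absent from the table map to
#' `"unassigned"` downstream.
#'
#' @param df data.frame with columns `genus`, `lifestyle` and optionally
#'   `trophic_mode` (pathotroph/saprotroph/symbiotroph).
#' @export
traits_table <- function(df) {
  if (!all(c("genus", "lifestyle") %in% names(df)))
    abort("traits_table: need columns genus, lifestyle")
  if (anyDuplicated(df$genus)) abort("traits_table: duplicate genus")
  if (is.null(df$trophic_mode))
    df$trophic_mode <- rep(NA_character_, nrow(df))
  class(df) <- c("traits_table", "data.frame")
  df
}

#' Read a traits table from TSV/CSV
#' @param path file path.
#' @export
read_traits <- function(path) traits_table(.read_table_file(path))

#' Map every taxon of a table to a fungal lifestyle
#'
#' Looks the taxon's genus up in the traits table. Taxa whose genus is
#' `"unidentified"`, or absent from the traits table, get
#' `"unassigned"`.
#'
#' @param table a [zotu_table()] (or anything with taxon rownames).
#' @param tax a taxonomy table covering the taxa.
#' @param traits a [traits_table()].
#' @return named character vector taxon_id -> lifestyle.
#' @export
assign_lifestyles <- function(table, tax, traits) {
  ids <- rownames(table)
  genus <- tax$genus[match(ids, tax$taxon_id)]
  lif <- traits$lifestyle[match(genus, traits$genus)]
  lif[is.na(lif) | is.na(genus) | genus == "unidentified"] <- "unassigned"
  names(lif) <- ids
  lif
}

# ---- co-occurrence network helpers -----------------------------------------

# A co-occurrence network is an undirected simple igraph whose vertices are
# zOTUs (attributes: name, abundance, lifestyle, and later module/Zi/Pi/role)
# and whose edges carry the Spearman rho and its sign ("+"/"-").

#' Validate a co-occurrence network object
#' @param net an igraph object.
#' @export
validate_network <- function(net) {
  if (!igraph::is_igraph(net)) abort("not an igraph object")
  if (igraph::is_directed(net)) abort("network must be undirected")
  if (any(igraph::which_loop(net))) abort("network contains self-loops")
  if (igraph::vcount(net) > 0 && any(igraph::degree(net) == 0))
    abort("network contains isolated nodes")
  if (igraph::ecount(net) > 0 && is.null(igraph::E(net)$rho))
    abort("edges must carry a 'rho' attribute")
  invisible(TRUE)
}

#' Write a co-occurrence network to GraphML or an edge TSV
#'
#' GraphML keeps all node attributes (abundance, lifestyle, and module /
#' Zi / Pi / role when present) and the edge attributes rho and sign.
#' The edge TSV has columns source, target, rho, sign.
#'
#' @param net co-occurrence network (igraph).
#' @param path output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  validate_network(net)
  if (igraph::ecount(net) == 0)
    abort("write_network: refusing to write an empty network ",
          "(networks never contain isolated nodes)")
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = TRUE)
    df <- data.frame(source = el[, 1L], target = el[, 2L],
                     rho = igraph::E(net)$rho,
                     sign = igraph::E(net)$sign %||%
                       ifelse(igraph::E(net)$rho >= 0, "+", "-"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a co-occurrence network written by [write_network()]
#' @param path input path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  net <- if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- .read_table_file(path)
    g <- igraph::graph_from_data_frame(df[, c("source", "target")],
                                       directed = FALSE)
    igraph::E(g)$rho <- df$rho
    igraph::E(g)$sign <- df$sign
    g
  }
  validate_network(net)
  net
}
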