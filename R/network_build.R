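# Spearman correlation matrix with t-approximation p-values,
# Benjamini-Hochberg FDR over the upper triangle, and thresholded
# construction of the undirected co-occurrence network.

#' All-pairs tie-aware Spearman correlation with p- and q-values
#'
#' rho is Pearson correlation of average ranks (the standard tie-aware
#' Spearman); p-values use the t statistic
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (`p = 0` when `|rho| = 1`), matching the behaviour of the usual
#' correlation-matrix packages. q-values are Benjamini-Hochberg adjusted
#' over the upper triangle only (the diagonal is excluded). Taxa with
#' zero rank variance (constant across samples) are flagged and recorded
#' with rho 0, p 1 against every partner.
#'
#' @param rel taxa x samples matrix (relative abundances).
#' @return object of class `correlation_result`: list with `taxa_ids`,
#'   symmetric matrices `rho`, `p`, `q`, logical `constant`, and `n`.
#' @export
spearman_matrix <- function(rel) {
  m <- unclass(as.matrix(rel))
  n <- ncol(m)
  if (n < 5L) abort("spearman_matrix: need at least 5 samples, got ", n)
  if (nrow(m) < 2L) abort("spearman_matrix: need at least 2 taxa")
  ranks <- t(apply(m, 1L, rank))            # average ranks, taxa x samples
  constant <- apply(ranks, 1L, function(r) max(r) == min(r))
  rho <- suppressWarnings(stats::cor(t(ranks)))
  rho[constant, ] <- 0
  rho[, constant] <- 0
  diag(rho) <- 1
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  p[constant, ] <- 1
  p[, constant] <- 1
  diag(p) <- 0
  ut <- upper.tri(rho)
  q <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
  q[ut] <- bh_adjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  structure(list(taxa_ids = rownames(m), rho = rho, p = p, q = q,
                 constant = stats::setNames(constant, rownames(m)), n = n),
            class = "correlation_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j >= i} p_(j) * m / j` over the sorted p-values, clipped
#' at 1; order-preserving.
#'
#' @param p vector of p-values in `[0,1]`.
#' @return vector of adjusted p-values (q-values), same order as input.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m <= 1L) return(p)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("bh_adjust: p outside [0,1]")
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(p[o] * m / seq(m, 1L)))[order(o)]
}

#' Edge-retention thresholds for network construction
#'
#' An edge is kept when `|rho| >= rho_min` and its (adjusted, by default)
#' p-value is below `p_max`. The conventional cutoffs are 0.6 and 0.01.
#'
#' @param rho_min minimum absolute Spearman rho, in `(0,1]`.
#' @param p_max significance cutoff, in `(0,1]`.
#' @param use_adjusted_p apply `p_max` to the BH-adjusted q (default) or
#'   to the raw p.
#' @export
edge_thresholds <- function(rho_min = 0.6, p_max = 0.01,
                            use_adjusted_p = TRUE) {
  stopifnot(rho_min > 0, rho_min <= 1, p_max > 0, p_max <= 1)
  structure(list(rho_min = rho_min, p_max = p_max,
                 use_adjusted_p = isTRUE(use_adjusted_p)),
            class = "edge_thresholds")
}

#' Build the thresholded co-occurrence network
#'
#' Keeps edge (i, j) iff `|rho_ij| >= rho_min` and the chosen p-value is
#' `< p_max` ("equal or greater" on rho, strict on p). Edge sign is the
#' sign of rho. Nodes with no retained edge are removed, so the node
#' count of the network is at most the number of filtered taxa.
#'
#' @param corr a [spearman_matrix()] result.
#' @param thr an [edge_thresholds()] object.
#' @param node_attrs optional data.frame with columns `taxon_id`,
#'   `abundance` (mean relative abundance) and `lifestyle`, attached as
#'   vertex attributes.
#' @return undirected simple igraph; possibly empty.
#' @export
build_network <- function(corr, thr = edge_thresholds(), node_attrs = NULL) {
  stopifnot(inherits(corr, "correlation_result"))
  pmat <- if (thr$use_adjusted_p) corr$q else corr$p
  ok <- abs(corr$rho) >= thr$rho_min & pmat < thr$p_max
  ok[corr$constant, ] <- FALSE
  ok[, corr$constant] <- FALSE
  ok[!upper.tri(ok)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  ids <- corr$taxa_ids
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      rho = corr$rho[idx],
                      sign = ifelse(corr$rho[idx] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  net <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(node_attrs)) {
    i <- match(igraph::V(net)$name, node_attrs$taxon_id)
    if ("abundance" %in% names(node_attrs))
      igraph::V(net)$abundance <- node_attrs$abundance[i]
    if ("lifestyle" %in% names(node_attrs))
      igraph::V(net)$lifestyle <- node_attrs$lifestyle[i]
  }
  validate_network(net)
  net
}

#' Positive / negative edge counts of a network
#' @param net a co-occurrence network.
#' @export
edge_sign_counts <- function(net) {
  if (igraph::ecount(net) == 0) return(c(positive = 0L, negative = 0L))
  s <- igraph::E(net)$sign %||% ifelse(igraph::E(net)$rho >= 0, "+", "-")
  c(positive = sum(s == "+"), negative = sum(s == "-"))
}

#' Long table of all retained (significant) correlation pairs
#' @param corr a [spearman_matrix()] result.
#' @param thr an [edge_thresholds()] object.
#' @export
significant_pairs <- function(corr, thr = edge_thresholds()) {
  pmat <- if (thr$use_adjusted_p) corr$q else corr$p
  ok <- abs(corr$rho) >= thr$rho_min & pmat < thr$p_max
  ok[corr$constant, ] <- FALSE
  ok[, corr$constant] <- FALSE
  ok[!upper.tri(ok)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  data.frame(taxon_i = corr$taxa_ids[idx[, 1L]],
             taxon_j = corr$taxa_ids[idx[, 2L]],
             rho = corr$rho[idx], p = corr$p[idx], q = corr$q[idx],
             stringsAsFactors = FALSE)
}
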