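# Module-level lifestyle composition and Spearman correlation of module
# profiles / keystone taxa against log-transformed environmental factors,
# with significance stars (raw p, no multiple-testing adjustment).

#' Per-sample abundance profile and lifestyle composition of top modules
#'
#' Modules are ranked by node count (partition labels already order
#' modules by decreasing size, ties to the lower id). A module's
#' per-sample profile is the sum of its member taxa's relative
#' abundances; its lifestyle composition is the node-count fraction per
#' lifestyle, `"unassigned"` included.
#'
#' @param net co-occurrence network.
#' @param partition a [detect_modules()] partition.
#' @param rel relative-abundance table covering the network's nodes.
#' @param lifestyles named vector taxon_id -> lifestyle (see
#'   [assign_lifestyles()]); optional.
#' @param top_k number of modules to profile (all, if fewer exist).
#' @return list of `module_profile` objects: `module_id`, `n_nodes`,
#'   `abundance` (named per-sample vector), `composition` (named
#'   fractions summing to 1).
#' @export
module_profiles <- function(net, partition, rel, lifestyles = NULL,
                            top_k = 5L) {
  memb <- partition$membership
  missing <- setdiff(names(memb), rownames(rel))
  if (length(missing))
    abort("module_profiles: taxa missing from rel table: ",
          paste(utils::head(missing, 3L), collapse = ", "))
  mods <- seq_len(min(top_k, partition$n_modules))
  lapply(mods, function(m) {
    members <- names(memb)[memb == m]
    prof <- colSums(rel[members, , drop = FALSE])
    comp <- if (is.null(lifestyles)) NULL else {
      lf <- unname(lifestyles[members])
      lf[is.na(lf)] <- "unassigned"
      tbl <- table(lf) / length(lf)
      stats::setNames(as.numeric(tbl), names(tbl))
    }
    structure(list(module_id = m, n_nodes = length(members),
                   abundance = prof, composition = comp),
              class = "module_profile")
  })
}

#' Significance stars from raw p-values
#'
#' `"**"` for p < 0.01, `"*"` for 0.01 <= p < 0.05, `""` otherwise.
#' @param p numeric vector.
#' @export
stars_for_p <- function(p) {
  out <- rep("", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[is.na(p)] <- ""
  out
}

#' Spearman correlation of sample-wise series against environmental factors
#'
#' Each series (module profile or keystone taxon abundance) is
#' rank-correlated against each environmental factor. Factors are
#' log-transformed as `ln(x + eps)` with `eps` = half the smallest
#' positive observed value of that factor (a standard zero-tolerant
#' offset, needed because enzyme activities can be 0); pH is exempt
#' because it is already a logarithmic quantity. Missing factor values
#' are pairwise-deleted; pairs with fewer than 5 complete samples, or a
#' constant side, are flagged and reported with rho 0, p 1. Stars use
#' raw p (no FDR), per the usual heatmap convention.
#'
#' @param series named list of per-sample numeric vectors (names =
#'   sample ids), or a matrix with rows = entities, cols = samples.
#' @param meta a [sample_metadata()] containing factor columns.
#' @param log_transform apply the ln(x + eps) transform (default TRUE).
#' @param factors environmental factor columns to use (default: the
#'   intersection of [env_factor_names()] with `meta`'s columns).
#' @return data.frame of class `env_correlation` (long format):
#'   `row_id`, `factor`, `rho`, `p`, `stars`, `n`, `flagged`.
#' @export
env_correlate <- function(series, meta, log_transform = TRUE,
                          factors = intersect(env_factor_names(),
                                              names(meta))) {
  if (is.matrix(series))
    series <- stats::setNames(
      lapply(seq_len(nrow(series)), function(i) series[i, ]),
      rownames(series))
  if (!length(factors)) abort("env_correlate: no factor columns in meta")
  env <- meta[, factors, drop = FALSE]
  rownames(env) <- meta$sample_id
  if (log_transform) {
    for (f in setdiff(factors, "pH")) {
      x <- env[[f]]
      pos <- x[!is.na(x) & x > 0]
      eps <- if (length(pos)) min(pos) / 2 else 0
      env[[f]] <- log(x + eps)
    }
  }
  rows <- list()
  for (id in names(series)) {
    s <- series[[id]]
    if (is.null(names(s))) abort("env_correlate: series must be named ",
                                 "by sample id")
    for (f in factors) {
      x <- s
      y <- env[names(s), f]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      flagged <- FALSE
      if (n < 5L || length(unique(x[ok])) == 1L ||
          length(unique(y[ok])) == 1L) {
        rho <- 0; p <- 1; flagged <- TRUE
      } else {
        rx <- rank(x[ok]); ry <- rank(y[ok])
        rho <- stats::cor(rx, ry)
        tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- if (abs(rho) >= 1 - 1e-12) 0
             else 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(row_id = id, factor = f, rho = rho, p = p,
                   stars = stars_for_p(p), n = n, flagged = flagged,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("env_correlation", "data.frame")
  out
}
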