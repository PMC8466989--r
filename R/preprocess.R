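# Relative-abundance normalisation, the prevalence/mean-abundance filter
# applied before network inference, and alpha-diversity indices.

#' Column-normalise a count table to relative abundances
#'
#' @param t a [zotu_table()] (or numeric matrix, taxa x samples).
#' @return matrix of class `rel_abundance`; each sample column sums to 1.
#' @export
relative_abundance <- function(t) {
  m <- unclass(as.matrix(t))
  tot <- colSums(m)
  if (any(tot <= 0))
    abort("relative_abundance: all-zero sample(s): ",
          paste(colnames(m)[tot <= 0], collapse = ", "))
  rel <- sweep(m, 2L, tot, "/")
  storage.mode(rel) <- "double"
  class(rel) <- c("rel_abundance", class(matrix()))
  rel
}

#' Filtering parameters for network construction
#'
#' Taxa are retained when they are present in strictly more than
#' `prevalence_min` of the samples of the group AND their mean (or, under
#' `abundance_rule = "max"`, maximum) relative abundance over the group is
#' at least `mean_abund_min`. Defaults follow the convention of keeping
#' taxa present in more than 30% of samples with mean relative abundance
#' of at least 0.1%.
#'
#' @param prevalence_min fraction in `[0,1)`; strict `>` comparison.
#' @param mean_abund_min fraction in `[0,1)`; `>=` comparison.
#' @param abundance_rule `"mean"` (default) or `"max"`.
#' @export
filter_params <- function(prevalence_min = 0.30, mean_abund_min = 0.001,
                          abundance_rule = c("mean", "max")) {
  abundance_rule <- match.arg(abundance_rule)
  stopifnot(prevalence_min >= 0, prevalence_min < 1,
            mean_abund_min >= 0, mean_abund_min < 1)
  structure(list(prevalence_min = prevalence_min,
                 mean_abund_min = mean_abund_min,
                 abundance_rule = abundance_rule),
            class = "filter_params")
}

#' Prevalence / abundance filter
#'
#' Restricts the table to `sample_subset`, then drops taxa failing either
#' rule. Values are NOT renormalised after dropping taxa, so retained
#' fractions stay interpretable as fractions of the original community.
#'
#' @param rel a [relative_abundance()] table.
#' @param params a [filter_params()].
#' @param sample_subset character vector of sample ids (default: all).
#' @return filtered `rel_abundance` (possibly zero rows, with a warning).
#' @export
filter_taxa <- function(rel, params = filter_params(),
                        sample_subset = colnames(rel)) {
  if (!length(sample_subset)) abort("filter_taxa: empty sample subset")
  missing <- setdiff(sample_subset, colnames(rel))
  if (length(missing))
    abort("filter_taxa: unknown samples: ", paste(missing, collapse = ", "))
  sub <- rel[, sample_subset, drop = FALSE]
  prevalence <- rowMeans(sub > 0)
  abund <- if (params$abundance_rule == "mean") rowMeans(sub)
           else apply(sub, 1L, max)
  keep <- prevalence > params$prevalence_min & abund >= params$mean_abund_min
  if (!any(keep)) warning("filter_taxa: no taxa retained")
  out <- sub[keep, , drop = FALSE]
  class(out) <- class(rel)
  out
}

#' One-line filtering summary (taxa before/after, % reads retained)
#'
#' The percentage is the group-level share of reads belonging to retained
#' taxa: the mean over the group's samples of the per-sample retained
#' fraction, times 100.
#'
#' @param rel_before relative abundances restricted to the group's samples.
#' @param rel_after output of [filter_taxa()] on the same samples.
#' @export
filter_summary <- function(rel_before, rel_after) {
  sub <- rel_before[, colnames(rel_after), drop = FALSE]
  data.frame(n_taxa_before = nrow(sub),
             n_taxa_after = nrow(rel_after),
             abundance_pct_retained =
               100 * mean(colSums(rel_after)) / mean(colSums(sub)))
}

#' Per-sample alpha diversity: Chao1, Shannon, Simpson evenness
#'
#' Chao1 uses the bias-corrected estimator
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` (defined even when there are no
#' doubletons); set `chao1_bias_corrected = FALSE` for the classic
#' `S_obs + f1^2 / (2 f2)` form (NaN when `f2 = 0`). Shannon is in natural
#' log units; Simpson evenness is the inverse Simpson index divided by
#' observed richness.
#'
#' @param t a [zotu_table()].
#' @param chao1_bias_corrected logical.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(t, chao1_bias_corrected = TRUE) {
  m <- unclass(as.matrix(t))
  if (any(colSums(m) <= 0)) abort("alpha_diversity: all-zero sample")
  res <- apply(m, 2L, function(x) {
    s_obs <- sum(x > 0)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- if (chao1_bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
             else s_obs + f1^2 / (2 * f2)
    p <- x[x > 0] / sum(x)
    shannon <- -sum(p * log(p))
    simpson_evenness <- (1 / sum(p^2)) / s_obs
    c(observed = s_obs, chao1 = chao1, shannon = shannon,
      simpson_evenness = simpson_evenness)
  })
  out <- as.data.frame(t(res))
  out <- cbind(data.frame(sample_id = colnames(m), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
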