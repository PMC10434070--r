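#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust]);
#' adjusted values are monotone in raw-p rank and never smaller than the
#' raw p-values.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Sum relative abundances within annotation groups; `level` picks the
# annotation column ("trophic_group", "class", "order").
aggregate_relative <- function(table, annotation, level) {
  check_table(table)
  if (any(colSums(table) == 0)) stop("all-zero sample in table")
  rel <- sweep(table, 2L, colSums(table), "/")
  lab <- annotation[[level]][match(rownames(table), annotation$taxon_id)]
  lab[is.na(lab)] <- "unassigned"
  rowsum(rel, lab)
}

#' Differential abundance of trophic or taxonomic groups
#'
#' Aggregates the table to relative abundances at the requested level and
#' reports, per feature, the log2 fold change of group means with the
#' first group level as the reference:
#' `log2FC = log2((mean_2 + c) / (mean_1 + c))`, with pseudo-fraction `c`
#' defaulting to half the smallest nonzero relative abundance.  The
#' p-value permutes group labels on the difference of group means
#' (two-sided) and is Benjamini-Hochberg adjusted across features.
#'
#' @param table abundance matrix (taxa x samples).
#' @param groups two-level factor over samples; the first level is the
#'   reference (e.g. freshwater), the second the contrast (e.g. salt).
#' @param annotation taxon annotation data.frame (needs `taxon_id` plus
#'   the `level` column); ignored when `level = "taxon"`.
#' @param level `"trophic_group"`, `"class"`, `"order"` or `"taxon"`.
#' @param n_perm number of label permutations.
#' @param seed optional seed.
#' @param alpha significance level applied to adjusted p-values.
#' @param pseudo pseudo-fraction `c`; `NULL` for the default.
#' @return data.frame with `feature_id`, `log2FC`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
differential_abundance <- function(table, groups, annotation = NULL,
                                   level = c("trophic_group", "class",
                                             "order", "taxon"),
                                   n_perm = 999L, seed = NULL,
                                   alpha = 0.05, pseudo = NULL) {
  level <- match.arg(level)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two group levels required")
  if (length(groups) != ncol(table)) stop("one group label per sample")
  if (level == "taxon") {
    check_table(table)
    if (any(colSums(table) == 0)) stop("all-zero sample in table")
    feat <- sweep(table, 2L, colSums(table), "/")
  } else {
    if (is.null(annotation)) stop("annotation required for level ", level)
    feat <- aggregate_relative(table, annotation, level)
  }
  empty <- rowSums(feat) == 0
  if (any(empty)) {
    message("dropping ", sum(empty), " feature(s) absent everywhere")
    feat <- feat[!empty, , drop = FALSE]
  }
  if (nrow(feat) == 0L) stop("no features left")
  if (is.null(pseudo)) pseudo <- min(feat[feat > 0]) / 2
  g2 <- groups == levels(groups)[2L]
  m1 <- rowMeans(feat[, !g2, drop = FALSE])
  m2 <- rowMeans(feat[, g2, drop = FALSE])
  log2fc <- log2((m2 + pseudo) / (m1 + pseudo))
  stat_obs <- abs(m2 - m1)
  n <- ncol(feat)
  exceed <- local_seed(seed, {
    acc <- integer(nrow(feat))
    for (i in seq_len(n_perm)) {
      gp <- g2[sample.int(n)]
      stat <- abs(rowMeans(feat[, gp, drop = FALSE]) -
                    rowMeans(feat[, !gp, drop = FALSE]))
      acc <- acc + (stat >= stat_obs)
    }
    acc
  })
  p_raw <- (1 + exceed) / (1 + n_perm)
  p_adj <- bh_adjust(p_raw)
  data.frame(feature_id = rownames(feat), log2FC = as.numeric(log2fc),
             p_raw = p_raw, p_adj = p_adj, significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
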