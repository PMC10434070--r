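#' Rarefy each sample to a fixed depth
#'
#' Subsamples every column without replacement to exactly `depth` reads
#' (via [vegan::rrarefy]).  Samples shallower than `depth` either raise
#' an error or are dropped, per `policy`.
#'
#' @param table abundance matrix (taxa x samples).
#' @param depth target depth; defaults to the minimum column sum.
#' @param seed optional seed.
#' @param policy what to do with samples shallower than `depth`:
#'   `"error"` (default) or `"drop"`.
#' @return rarefied abundance matrix (same taxa, possibly fewer samples).
#' @export
rarefy <- function(table, depth = min(colSums(table)), seed = NULL,
                   policy = c("error", "drop")) {
  check_table(table)
  policy <- match.arg(policy)
  depth <- as.integer(depth)
  stopifnot(depth >= 1)
  shallow <- colSums(table) < depth
  if (any(shallow)) {
    if (policy == "error")
      stop("samples below depth ", depth, ": ",
           paste(colnames(table)[shallow], collapse = ", "))
    message("dropping ", sum(shallow), " sample(s) below depth ", depth)
    table <- table[, !shallow, drop = FALSE]
    if (ncol(table) == 0L) stop("no samples left after depth filter")
  }
  local_seed(seed, {
    # muffle vegan's advisory about pre-scaled counts; inputs are
    # validated integer counts here
    out <- withCallingHandlers(
      t(vegan::rrarefy(t(table), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    dimnames(out) <- dimnames(table)
    abundance_table(out)
  })
}

#' Shannon diversity of a single count vector
#'
#' `-sum(p * log(p))` over taxa with positive counts.  Natural log by
#' default (the vegan convention); the base is configurable.
#'
#' @param counts non-negative count (or abundance) vector.
#' @param base logarithm base.
#' @return Shannon entropy (nats by default).
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (!any(counts > 0)) stop("all-zero sample has no diversity")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Per-sample alpha diversity after any resampling
#'
#' @param table abundance matrix (taxa x samples).
#' @param base logarithm base for the Shannon index.
#' @return data.frame with `sample_id`, `richness` (observed taxa) and
#'   `shannon`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  check_table(table)
  if (any(colSums(table) == 0)) stop("all-zero sample in table")
  data.frame(
    sample_id = colnames(table),
    richness = as.integer(colSums(table > 0)),
    shannon = as.numeric(vegan::diversity(t(table), index = "shannon",
                                          base = base)),
    stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`, computed
#' with [vegan::vegdist].
#'
#' @param table abundance matrix (taxa x samples) with no all-zero
#'   sample.
#' @return a [stats::dist] of pairwise dissimilarities in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  check_table(table, min_samples = 2L)
  if (any(colSums(table) == 0)) stop("all-zero sample in table")
  vegan::vegdist(t(table), method = "bray")
}
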