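# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state when `seed` is given, leaving the
# caller's RNG untouched; with seed = NULL the expression runs on the
# current stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Draw n child seeds from a master seed, so independent stages of a
# pipeline get independent, reproducible streams.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Validate a taxa-by-samples count matrix; returns it invisibly.
check_table <- function(x, min_taxa = 1L, min_samples = 1L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance table must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance table must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (anyNA(x) || any(!is.finite(x))) stop("counts must be finite and non-missing")
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integers")
  if (nrow(x) < min_taxa) stop("too few taxa (need >= ", min_taxa, ")")
  if (ncol(x) < min_samples) stop("too few samples (need >= ", min_samples, ")")
  invisible(x)
}

# Coerce to a 'dist' and check symmetry / zero diagonal / finiteness.
check_dist <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) {
    if (anyNA(d) || any(!is.finite(d))) stop(what, " has non-finite values")
    return(d)
  }
  if (!is.matrix(d)) stop(what, " must be a 'dist' or a square matrix")
  if (nrow(d) != ncol(d)) stop(what, " must be square")
  if (any(abs(d - t(d)) > 1e-12)) stop(what, " must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop(what, " must have a zero diagonal")
  if (anyNA(d) || any(!is.finite(d))) stop(what, " has non-finite values")
  as.dist(d)
}

# Reorder dist `d2` to the label order of dist `d1`.
align_dist <- function(d1, d2, what = "second matrix") {
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (is.null(l1) || is.null(l2)) {
    if (attr(d1, "Size") != attr(d2, "Size"))
      stop(what, " has a different number of objects")
    return(d2)
  }
  if (!setequal(l1, l2)) stop(what, " has non-matching ids")
  m <- as.matrix(d2)[l1, l1]
  as.dist(m)
}

# Upper-triangle pair labels of a dist, in the same order as unclass(d).
dist_pairs <- function(d) {
  n <- attr(d, "Size")
  lab <- attr(d, "Labels")
  if (is.null(lab)) lab <- as.character(seq_len(n))
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(sample_1 = lab[i], sample_2 = lab[j], stringsAsFactors = FALSE)
}
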