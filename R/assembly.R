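# Null-model quantification of community assembly.
#
# The observed statistic is the between-sample mean nearest taxon
# distance (beta-MNTD); its standardized effect size against a
# tip-shuffle null is the beta-nearest-taxon index (bNTI).  Together with
# the Bray-Curtis-based Raup-Crick metric it partitions sample pairs into
# five assembly processes.

# Vectorized beta-MNTD engine.  fmat: taxa x samples weights (columns sum
# to 1); dmat: taxa x taxa patristic distances, rows/cols aligned with
# fmat.  Returns the full samples x samples matrix.
beta_mntd_engine <- function(fmat, dmat) {
  n_taxa <- nrow(fmat)
  n_samp <- ncol(fmat)
  # nearest[i, m]: distance from taxon i to its closest taxon present in
  # sample m (0 when i itself is present there)
  nearest <- matrix(0, n_taxa, n_samp)
  for (m in seq_len(n_samp)) {
    idx <- which(fmat[, m] > 0)
    sub <- dmat[, idx, drop = FALSE]
    nearest[, m] <- sub[cbind(seq_len(n_taxa),
                              max.col(-sub, ties.method = "first"))]
  }
  a <- crossprod(fmat, nearest)   # a[k, m] = sum_i f_ik * nearest[i, m]
  0.5 * (a + t(a))
}

# Shared input preparation for beta_mntd()/bnti().
prep_phylo_inputs <- function(table, tree, abundance_weighted) {
  check_table(table, min_taxa = 2L, min_samples = 2L)
  validate_tree(tree)
  present <- rowSums(table) > 0
  tab <- table[present, , drop = FALSE]
  missing <- setdiff(rownames(tab), tree$tip.label)
  if (length(missing))
    stop("taxa with nonzero counts absent from tree: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (any(colSums(tab) == 0)) stop("sample with no taxa on the tree")
  dmat <- stats::cophenetic(tree)[rownames(tab), rownames(tab)]
  fmat <- if (abundance_weighted) {
    sweep(tab, 2L, colSums(tab), "/")
  } else {
    occ <- tab > 0
    sweep(occ, 2L, colSums(occ), "/")
  }
  list(fmat = fmat, dmat = dmat, samples = colnames(tab))
}

#' Between-sample mean nearest taxon distance (beta-MNTD)
#'
#' For samples `k` and `m`,
#' `betaMNTD = 0.5 * (sum_i f_ik min_{j in m} d(i, j) +
#'                    sum_j f_jm min_{i in k} d(j, i))`,
#' with `f` the relative abundances (abundance-weighted, the default) or
#' `1/richness` (unweighted) and `d` the patristic distance.  A taxon
#' shared by both samples has nearest-taxon distance zero.
#'
#' @param table abundance matrix (taxa x samples); tree tips must cover
#'   every taxon with nonzero counts.
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param abundance_weighted weight by relative abundance (default) or
#'   by presence only.
#' @return a [stats::dist] of pairwise beta-MNTD values.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  inp <- prep_phylo_inputs(table, tree, abundance_weighted)
  b <- beta_mntd_engine(inp$fmat, inp$dmat)
  dimnames(b) <- list(inp$samples, inp$samples)
  stats::as.dist(b)
}

#' Beta-nearest taxon index (bNTI)
#'
#' Standardized effect size of beta-MNTD against a null that shuffles
#' taxon labels across the tips of the phylogeny:
#' `bNTI = (betaMNTD_obs - mean(betaMNTD_null)) / sd(betaMNTD_null)`.
#' One tip shuffle per null replicate scores all sample pairs, so the
#' result does not depend on pair evaluation order.  Pairs whose null
#' standard deviation is zero are returned as `NA` with a warning.
#'
#' `|bNTI| > 2` is conventionally read as deterministic selection
#' (variable selection above +2, homogeneous selection below -2);
#' `|bNTI| <= 2` leaves the pair to the stochastic side of the partition
#' (see [classify_assembly()]).
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip shuffles (>= 99; 999 by default).
#' @param seed optional seed.
#' @return a [stats::dist] of pairwise bNTI values.
#' @export
bnti <- function(table, tree, n_null = 999L, seed = NULL,
                 abundance_weighted = TRUE) {
  stopifnot(n_null >= 99L)
  inp <- prep_phylo_inputs(table, tree, abundance_weighted)
  obs <- beta_mntd_engine(inp$fmat, inp$dmat)
  n_taxa <- nrow(inp$fmat)
  sum1 <- matrix(0, ncol(inp$fmat), ncol(inp$fmat))
  sum2 <- sum1
  local_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_taxa)
      b <- beta_mntd_engine(inp$fmat, inp$dmat[perm, perm])
      sum1 <- sum1 + b
      sum2 <- sum2 + b^2
    }
  })
  mu <- sum1 / n_null
  sdv <- sqrt(pmax(sum2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA_real_
  diag(z) <- 0
  if (anyNA(z[upper.tri(z)]))
    warning(sum(is.na(z[upper.tri(z)])),
            " pair(s) with zero null variance set to NA")
  dimnames(z) <- list(inp$samples, inp$samples)
  stats::as.dist(z)
}

# One null community per sample: keep the observed richness, draw that
# many taxa with probability proportional to occupancy frequency, give
# each one individual, then fill to the observed total with draws
# proportional to metacommunity relative abundance among the drawn taxa.
rc_null_table <- function(table, occ_freq, pool_rel) {
  n_taxa <- nrow(table)
  out <- matrix(0, n_taxa, ncol(table))
  for (m in seq_len(ncol(table))) {
    s <- sum(table[, m] > 0)
    tot <- sum(table[, m])
    idx <- sample.int(n_taxa, s, prob = occ_freq)
    fill <- tot - s
    ab <- rep(1, s)
    if (fill > 0)
      ab <- ab + as.numeric(rmultinom(1L, fill, pool_rel[idx]))
    out[idx, m] <- ab
  }
  out
}

#' Bray-Curtis-based Raup-Crick (RC_Bray)
#'
#' Ranks each pair's observed Bray-Curtis dissimilarity within a null
#' distribution that preserves per-sample richness and total abundance:
#' null members are drawn by occupancy frequency and filled by
#' metacommunity relative abundance.  The rank is rescaled to
#' `[-1, 1]`:
#' `RC = 2 * ((#\{BC_null < BC_obs\} + 0.5 #\{ties\}) / n_null) - 1`.
#' Values beyond +/-0.95 indicate, under `|bNTI| <= 2`, dispersal
#' limitation (+) or homogenizing dispersal (-).
#'
#' @param table abundance matrix (taxa x samples, >= 2 samples).
#' @param n_null number of null tables (>= 99; 999 by default).
#' @param seed optional seed.
#' @return a [stats::dist] of pairwise RC_Bray values.
#' @export
rc_bray <- function(table, n_null = 999L, seed = NULL) {
  check_table(table, min_taxa = 2L, min_samples = 2L)
  stopifnot(n_null >= 99L)
  if (any(colSums(table) == 0)) stop("all-zero sample in table")
  occ_freq <- rowSums(table > 0)
  pool_rel <- rowSums(table) / sum(table)
  if (all(occ_freq == 0)) stop("empty table")
  obs <- as.matrix(bray_curtis(table))
  n <- ncol(table)
  less <- matrix(0, n, n)
  ties <- matrix(0, n, n)
  eps <- 1e-12
  local_seed(seed, {
    for (r in seq_len(n_null)) {
      nul <- rc_null_table(table, occ_freq, pool_rel)
      colnames(nul) <- colnames(table)
      rownames(nul) <- rownames(table)
      bc <- as.matrix(vegan::vegdist(t(nul), method = "bray"))
      less <- less + (bc < obs - eps)
      ties <- ties + (abs(bc - obs) <= eps)
    }
  })
  rc <- 2 * ((less + 0.5 * ties) / n_null) - 1
  diag(rc) <- 0
  dimnames(rc) <- dimnames(obs)
  stats::as.dist(rc)
}

#' Partition sample pairs into the five assembly processes
#'
#' Applies the conventional thresholds: bNTI above +2 is heterogeneous
#' (variable) selection and below -2 homogeneous selection; among the
#' remaining pairs, RC_Bray above +0.95 is dispersal limitation, below
#' -0.95 homogenizing dispersal, and everything else is undominated.
#' Boundary values (|bNTI| = 2, |RC| = 0.95) fall on the non-extreme
#' side, matching the strict inequalities of the framework.  Pairs with
#' missing bNTI are excluded from the fractions.
#'
#' @param bnti pairwise bNTI values ([stats::dist] or matrix), see
#'   [bnti()].
#' @param rc pairwise RC_Bray values, conformable with `bnti`.
#' @return list of class `assembly_result` with `pairs` (one row per
#'   sample pair: ids, bnti, rc_bray, process), `fractions` (proportions
#'   over the five processes among classified pairs) and `n_classified`.
#' @export
classify_assembly <- function(bnti, rc) {
  bnti <- check_dist_allow_na(bnti, "bnti")
  rc <- align_dist(bnti, check_dist_allow_na(rc, "rc"), "rc")
  pairs <- dist_pairs(bnti)
  b <- as.numeric(bnti)
  r <- as.numeric(rc)
  proc <- rep(NA_character_, length(b))
  ok <- !is.na(b) & !is.na(r)
  proc[ok & b > 2] <- "heterogeneous_selection"
  proc[ok & b < -2] <- "homogeneous_selection"
  sto <- ok & abs(b) <= 2
  proc[sto & r > 0.95] <- "dispersal_limitation"
  proc[sto & r < -0.95] <- "homogenizing_dispersal"
  proc[sto & abs(r) <= 0.95] <- "undominated"
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "undominated")
  pairs$bnti <- b
  pairs$rc_bray <- r
  pairs$process <- factor(proc, levels = lev)
  counts <- table(pairs$process)
  n_cl <- sum(counts)
  fractions <- if (n_cl > 0) as.numeric(counts) / n_cl else rep(NA_real_, 5L)
  names(fractions) <- lev
  structure(list(pairs = pairs, fractions = fractions,
                 n_classified = n_cl),
            class = "assembly_result")
}

# like check_dist() but tolerant of NA entries (excluded pairs)
check_dist_allow_na <- function(d, what) {
  if (inherits(d, "dist")) return(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop(what, " must be square")
  stats::as.dist(d)
}

#' Levins niche breadth
#'
#' For taxon `j` with distribution `P_ij` across the `N` samples (each
#' taxon's counts normalized over samples), `B_j = 1 / sum_i P_ij^2`, so
#' `B = 1` for a taxon confined to one sample and `B = N` for a taxon
#' spread evenly over all samples.  The community-level value `Bcom` of a
#' sample is the mean `B_j` over the taxa occurring in it.
#'
#' @param table abundance matrix (taxa x samples).
#' @return list with `B` (named per-taxon breadths) and `Bcom` (named
#'   per-sample community means).
#' @export
levins_breadth <- function(table) {
  check_table(table, min_samples = 2L)
  zero <- rowSums(table) == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " all-zero taxon/taxa")
    table <- table[!zero, , drop = FALSE]
  }
  if (nrow(table) == 0L) stop("no taxa left")
  p <- table / rowSums(table)
  b <- 1 / rowSums(p^2)
  bcom <- apply(table > 0, 2L, function(pres) {
    if (!any(pres)) NA_real_ else mean(b[pres])
  })
  list(B = b, Bcom = bcom)
}
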