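# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (double loops, exhaustive enumeration,
# direct formulas) and never share code with the package implementation.

# Random taxa x samples count table with guaranteed positive column sums.
make_counts <- function(n_taxa, n_samples, lambda = 5, seed = NULL) {
  gen <- function() {
    m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
                dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                sprintf("s%02d", seq_len(n_samples))))
    m
  }
  m <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  empty <- colSums(m) == 0
  m[1, empty] <- 1
  m
}

# Naive double-loop beta-MNTD between two count vectors.
naive_beta_mntd_pair <- function(x, y, dmat, weighted = TRUE) {
  ix <- which(x > 0); iy <- which(y > 0)
  fx <- if (weighted) x[ix] / sum(x[ix]) else rep(1 / length(ix), length(ix))
  fy <- if (weighted) y[iy] / sum(y[iy]) else rep(1 / length(iy), length(iy))
  s1 <- 0
  for (k in seq_along(ix))
    s1 <- s1 + fx[k] * min(dmat[ix[k], iy])
  s2 <- 0
  for (k in seq_along(iy))
    s2 <- s2 + fy[k] * min(dmat[iy[k], ix])
  (s1 + s2) / 2
}

naive_beta_mntd <- function(table, tree, weighted = TRUE) {
  dmat <- cophenetic(tree)[rownames(table), rownames(table)]
  n <- ncol(table)
  out <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    out[a, b] <- out[b, a] <-
      naive_beta_mntd_pair(table[, a], table[, b], dmat, weighted)
  }
  as.dist(out)
}

# Exhaustive-permutation PERMANOVA p-value for a two-group design:
# enumerate every assignment of group sizes to samples.
exhaustive_permanova_p <- function(d, groups) {
  dm2 <- as.matrix(d)^2
  n <- nrow(dm2)
  fstat <- function(g) {
    g <- factor(g)
    ss_t <- sum(dm2) / (2 * n)
    ss_w <- 0
    for (lv in levels(g)) {
      idx <- which(g == lv)
      ss_w <- ss_w + sum(dm2[idx, idx]) / (2 * length(idx))
    }
    ((ss_t - ss_w) / (nlevels(g) - 1)) / (ss_w / (n - nlevels(g)))
  }
  f_obs <- fstat(groups)
  lv <- levels(factor(groups))
  n1 <- sum(groups == lv[1])
  combos <- combn(n, n1)
  f_all <- apply(combos, 2, function(idx) {
    g <- rep(lv[2], n); g[idx] <- lv[1]
    fstat(g)
  })
  mean(f_all >= f_obs - 1e-12)
}

# Straightforward re-implementation of the Bray-Curtis Raup-Crick metric:
# same null recipe (richness by occupancy, fill by pool abundance, drawn
# sample-by-sample per replicate) but naive dissimilarity and ranking.
naive_rc_bray <- function(table, n_null, seed) {
  bc_pair <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
  n <- ncol(table)
  occ <- rowSums(table > 0)
  pool <- rowSums(table) / sum(table)
  obs <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    obs[a, b] <- obs[b, a] <- bc_pair(table[, a], table[, b])
  less <- matrix(0, n, n); ties <- matrix(0, n, n)
  withr::with_seed(seed, {
    for (r in seq_len(n_null)) {
      nul <- matrix(0, nrow(table), n)
      for (m in seq_len(n)) {
        s <- sum(table[, m] > 0); tot <- sum(table[, m])
        idx <- sample.int(nrow(table), s, prob = occ)
        ab <- rep(1, s)
        if (tot - s > 0)
          ab <- ab + as.numeric(rmultinom(1, tot - s, pool[idx]))
        nul[idx, m] <- ab
      }
      for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        v <- bc_pair(nul[, a], nul[, b])
        if (v < obs[a, b] - 1e-12) less[a, b] <- less[a, b] + 1
        else if (abs(v - obs[a, b]) <= 1e-12) ties[a, b] <- ties[a, b] + 1
      }
    }
  })
  frac <- (less + 0.5 * ties) / n_null
  frac <- frac + t(frac)
  rc <- 2 * frac - 1
  diag(rc) <- 0
  dimnames(rc) <- list(colnames(table), colnames(table))
  as.dist(rc)
}

# Brute-force Benjamini-Hochberg step-up from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) p[o[j]] * m / j)
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

# dist with labels from a plain matrix of coordinates (rows = samples).
coord_dist <- function(x, ids = sprintf("s%02d", seq_len(nrow(x)))) {
  rownames(x) <- ids
  dist(x)
}
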