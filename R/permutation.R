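# Permutational multivariate tests on distance matrices.  The pseudo-F
# follows Anderson's partition of squared inter-point distances; p-values
# use the standard (1 + exceedances) / (1 + n_perm) estimator.

permanova_f <- function(dm2, groups) {
  n <- nrow(dm2)
  a <- nlevels(groups)
  ss_t <- sum(dm2) / (2 * n)
  ss_w <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(dm2[idx, idx]) / (2 * length(idx))
  }
  ss_a <- ss_t - ss_w
  f <- (ss_a / (a - 1)) / (ss_w / (n - a))
  c(f = f, r2 = ss_a / ss_t)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F
#' statistic partitions the total sum of squared pairwise distances into
#' among- and within-group components, and significance is assessed by
#' freely permuting sample labels.
#'
#' @param d a [stats::dist] (or symmetric matrix) of pairwise sample
#'   dissimilarities.
#' @param groups group labels, one per sample (>= 2 groups, each with
#'   >= 2 samples).  If named, they are matched to the distance labels.
#' @param n_perm number of label permutations.
#' @param seed optional seed.
#' @return list with `pseudo_F`, `R2`, `p` and `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL) {
  d <- check_dist(d)
  n <- attr(d, "Size")
  lab <- attr(d, "Labels")
  if (!is.null(names(groups)) && !is.null(lab)) {
    if (!setequal(names(groups), lab)) stop("group names do not match samples")
    groups <- groups[lab]
  }
  if (length(groups) != n) stop("one group label per sample required")
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  dm2 <- as.matrix(d)^2
  obs <- permanova_f(dm2, groups)
  exceed <- local_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      permanova_f(dm2, groups[sample.int(n)])[["f"]] >= obs[["f"]]
    }, logical(1L)))
  })
  list(pseudo_F = obs[["f"]], R2 = obs[["r2"]],
       p = (1 + exceed) / (1 + n_perm), n_perm = as.integer(n_perm))
}

#' Distance-decay regression between two distance matrices
#'
#' Ordinary least squares of the upper-triangle entries of `dist_y`
#' (e.g. Bray-Curtis dissimilarity) on those of `dist_x` (e.g.
#' geographic or salinity distance).  Because pairs are not independent,
#' the p-value comes from a Mantel-style permutation of one matrix's
#' sample ids, two-sided on the slope.
#'
#' @param dist_y,dist_x conformable [stats::dist] objects (matching
#'   ids).
#' @param n_perm number of id permutations.
#' @param seed optional seed.
#' @return list with `slope`, `intercept`, `r2`, `p`, `n_perm`.
#' @export
decay_fit <- function(dist_y, dist_x, n_perm = 999L, seed = NULL) {
  dist_y <- check_dist(dist_y, "dist_y")
  dist_x <- align_dist(dist_y, check_dist(dist_x, "dist_x"), "dist_x")
  y <- as.numeric(dist_y)
  x <- as.numeric(dist_x)
  if (stats::var(x) == 0) stop("constant predictor distances")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  xm <- as.matrix(dist_x)
  n <- nrow(xm)
  exceed <- local_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      xp <- as.numeric(stats::as.dist(xm[p, p]))
      abs(stats::cov(xp, y) / stats::var(xp)) >= abs(slope)
    }, logical(1L)))
  })
  list(slope = slope, intercept = intercept, r2 = r2,
       p = (1 + exceed) / (1 + n_perm), n_perm = as.integer(n_perm))
}

#' Partial Mantel test
#'
#' Correlation between the upper triangles of `dA` and `dB` controlling
#' for `dC`:
#' `r(AB.C) = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`.
#' Significance by permuting the ids of `dA`, two-sided.
#'
#' @param dA,dB,dC conformable [stats::dist] objects.
#' @param n_perm number of id permutations.
#' @param seed optional seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
partial_mantel <- function(dA, dB, dC, n_perm = 999L, seed = NULL) {
  dA <- check_dist(dA, "dA")
  dB <- align_dist(dA, check_dist(dB, "dB"), "dB")
  dC <- align_dist(dA, check_dist(dC, "dC"), "dC")
  a <- as.numeric(dA); b <- as.numeric(dB); cc <- as.numeric(dC)
  partial_r <- function(a) {
    r_ab <- stats::cor(a, b); r_ac <- stats::cor(a, cc)
    r_bc <- stats::cor(b, cc)
    if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12)
      stop("degenerate control matrix (|r| = 1)")
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- partial_r(a)
  am <- as.matrix(dA)
  n <- nrow(am)
  exceed <- local_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      abs(partial_r(as.numeric(stats::as.dist(am[p, p])))) >= abs(r_obs)
    }, logical(1L)))
  })
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}
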