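test_that("shannon matches closed forms and is bounded by log richness", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(6, 2)), -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(shannon(c(6, 2)), 0.5623, tolerance = 1e-4)
  expect_equal(shannon(c(8, 8, 8, 8), base = 2), 2)
  expect_error(shannon(c(0, 0)), "all-zero")

  withr::with_seed(11, {
    for (i in 1:20) {
      x <- rpois(15, 2)
      if (!any(x > 0)) x[1] <- 1
      h <- shannon(x)
      expect_lte(h, log(sum(x > 0)) + 1e-12)
      expect_gte(h, 0)
      expect_equal(shannon(c(x, 0)), h)  # zero-count taxon changes nothing
    }
  })

  tab <- make_counts(12, 5, seed = 3)
  ad <- alpha_diversity(tab)
  expect_equal(ad$richness, unname(colSums(tab > 0)))
  expect_true(all(ad$shannon <= log(ad$richness) + 1e-12))
})

test_that("rarefaction preserves composition in expectation", {
  tab <- make_counts(8, 4, seed = 5)
  same <- rarefy(tab, depth = min(colSums(tab)), seed = 1)
  expect_equal(unname(colSums(same)), rep(min(colSums(tab)), 4))
  expect_true(all(same <= tab))

  one <- matrix(c(10, 0), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(unname(rarefy(one, 5, seed = 1)[, 1]), c(5, 0))

  # hypergeometric expectation: mean of resamples tracks proportions
  col <- matrix(c(60, 30, 10), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  acc <- withr::with_seed(8, {
    rowMeans(vapply(1:1000, function(i) rarefy(col, 10)[, 1], numeric(3)))
  })
  expect_equal(unname(acc), c(6, 3, 1), tolerance = 0.06)

  expect_error(rarefy(tab, depth = max(colSums(tab)) + 1), "below depth")
  expect_equal(ncol(suppressMessages(
    rarefy(tab, depth = sort(colSums(tab))[2], policy = "drop"))), 3L)
})

test_that("bray-curtis matches its formula and is a [0,1] semimetric", {
  two <- matrix(c(3, 1, 3, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.numeric(bray_curtis(two)), 0)
  disj <- matrix(c(3, 0, 0, 7), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  hand <- matrix(c(6, 2, 2, 2), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.numeric(bray_curtis(hand)), 1 - 8 / 12)

  tab <- make_counts(10, 6, seed = 9)
  bc <- as.matrix(bray_curtis(tab))
  expect_true(all(bc >= 0 & bc <= 1))
  expect_equal(bc, t(bc))
  # invariant under taxon reordering
  perm <- withr::with_seed(1, sample(nrow(tab)))
  expect_equal(as.matrix(bray_curtis(tab[perm, ])), bc)
})

test_that("permanova recovers structure and degenerates gracefully", {
  # equidistant samples: no grouping can explain anything
  n <- 8
  m <- matrix(0.5, n, n); diag(m) <- 0
  dimnames(m) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
  res <- permanova(m, rep(c("a", "b"), each = 4), n_perm = 199, seed = 1)
  expect_lt(res$R2, 0.2)
  expect_gt(res$p, 0.5)

  # two well-separated clouds
  pts <- withr::with_seed(2, rbind(matrix(rnorm(8, 0), 4), matrix(rnorm(8, 6), 4)))
  d <- coord_dist(pts)
  g <- rep(c("a", "b"), each = 4)
  res2 <- permanova(d, g, n_perm = 999, seed = 3)
  expect_gt(res2$R2, 0.5)
  expect_lt(res2$p, 0.05)
  # matches vegan's formulation exactly
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res2$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(res2$R2, ad$R2[1], tolerance = 1e-10)

  expect_error(permanova(d, c("a", rep("b", 7))), "at least 2 samples")
})

test_that("distance-decay regression recovers affine relations", {
  pts <- withr::with_seed(4, matrix(rnorm(20), 10, 2))
  dx <- coord_dist(pts)
  fit <- decay_fit(dx, dx, n_perm = 99, seed = 1)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r2, 1)
  dy <- dx * 2
  expect_equal(decay_fit(dy, dx, n_perm = 99, seed = 1)$slope, 2)

  const <- dx; const[] <- 1
  expect_error(decay_fit(dx, const), "constant")
})

test_that("partial mantel isolates and removes shared structure", {
  pts <- withr::with_seed(6, matrix(rnorm(24), 12, 2))
  dA <- coord_dist(pts)
  dC <- coord_dist(withr::with_seed(7, matrix(rnorm(24), 12, 2)))
  # dB = dA, dC independent: near-perfect partial correlation
  r1 <- partial_mantel(dA, dA, dC, n_perm = 99, seed = 1)
  expect_gt(r1$r, 0.95)
  expect_lt(r1$p, 0.05)
  # dC nearly identical to dA: controlling for the confounder kills
  # r(AB.C) even though the raw correlation is high
  noise <- coord_dist(withr::with_seed(8, matrix(rnorm(24), 12, 2)))
  dB <- as.dist(as.matrix(dA) + as.matrix(noise) * 0.2)
  dCc <- coord_dist(pts + withr::with_seed(9, matrix(rnorm(24), 12, 2)) * 0.02)
  raw_r <- cor(as.numeric(dA), as.numeric(dB))
  r2 <- partial_mantel(dA, dB, dCc, n_perm = 99, seed = 2)
  expect_gt(raw_r, 0.8)
  expect_lt(abs(r2$r), 0.5)
  # an exact duplicate control is rejected as degenerate
  expect_error(partial_mantel(dA, dB, dA, n_perm = 99), "degenerate")
  # agrees with vegan's statistic
  vg <- vegan::mantel.partial(dA, dB, dC, permutations = 0)
  expect_equal(partial_mantel(dA, dB, dC, n_perm = 99, seed = 3)$r,
               unname(vg$statistic), tolerance = 1e-10)
})

test_that("differential abundance reports log2 fold changes with BH", {
  # 4 freshwater + 4 salt samples, feature shares engineered 8x apart
  tab <- rbind(cons = c(80, 80, 80, 80, 20, 20, 20, 20),
               sapr = c(20, 20, 20, 20, 80, 80, 80, 80))
  colnames(tab) <- sprintf("s%d", 1:8)
  ann <- data.frame(taxon_id = c("cons", "sapr"),
                    trophic_group = c("consumer", "saprotroph"))
  grp <- factor(rep(c("freshwater", "salt"), each = 4),
                levels = c("freshwater", "salt"))
  res <- differential_abundance(tab, grp, ann, level = "trophic_group",
                                n_perm = 200, seed = 1, pseudo = 1e-12)
  expect_equal(sort(res$feature_id), c("consumer", "saprotroph"))
  expect_equal(res$log2FC[res$feature_id == "saprotroph"], 2, tolerance = 1e-6)
  expect_equal(res$log2FC[res$feature_id == "consumer"], -2, tolerance = 1e-6)
  expect_true(all(res$p_adj >= res$p_raw))

  # identical groups: no change, large p
  flat <- matrix(rep(c(30, 10), 8), 2, 8,
                 dimnames = list(c("cons", "sapr"), sprintf("s%d", 1:8)))
  res0 <- differential_abundance(flat, grp, ann, level = "trophic_group",
                                 n_perm = 200, seed = 2)
  expect_equal(res0$log2FC, c(0, 0))
  expect_true(all(res0$p_raw > 0.9))
})

test_that("benjamini-hochberg adjustment matches brute-force step-up", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(bh_adjust(p), brute_bh(p))
  withr::with_seed(13, {
    for (i in 1:10) {
      q <- runif(7)
      adj <- bh_adjust(q)
      expect_equal(adj, brute_bh(q))
      expect_true(all(adj >= q))
      expect_true(all(diff(adj[order(q)]) >= -1e-12))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
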