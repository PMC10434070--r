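test_that("prevalence filter keeps taxa at or above the occurrence cutoff", {
  tab <- matrix(0, 3, 10,
                dimnames = list(c("keep4", "drop3", "keep10"),
                                sprintf("s%d", 1:10)))
  tab["keep4", 1:4] <- 1
  tab["drop3", 1:3] <- 1
  tab["keep10", ] <- 2
  out <- filter_prevalence(tab, 0.4)
  expect_setequal(rownames(out), c("keep4", "keep10"))
  expect_identical(filter_prevalence(tab, 0), tab)
  solo <- tab["drop3", , drop = FALSE]
  expect_error(filter_prevalence(solo, 0.4), "prevalence")
})

test_that("log-abundance correlations behave like Pearson should", {
  # affine-related log-transformed vectors correlate perfectly
  y <- c(0, 1, 3, 7, 15)
  x <- (y + 1)^2 - 1  # log1p(x) = 2 * log1p(y)
  tab <- rbind(a = x, b = y, c = c(5, 0, 2, 1, 9))
  colnames(tab) <- sprintf("s%d", 1:5)
  cc <- correlation_matrix(tab)
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc["a", "b"], 1)

  # hand-computed textbook Pearson on the log scale
  la <- log(tab["a", ] + 1); lc <- log(tab["c", ] + 1)
  hand <- sum((la - mean(la)) * (lc - mean(lc))) /
    sqrt(sum((la - mean(la))^2) * sum((lc - mean(lc))^2))
  expect_equal(cc["a", "c"], hand)

  expect_error(correlation_matrix(tab[, 1:3]), "samples")
  flat <- rbind(tab, d = rep(3, 5))
  expect_message(correlation_matrix(flat), "zero-variance")
})

test_that("RMT threshold finds planted structure and falls back cleanly", {
  # no structure: identity correlations give no edges anywhere
  id <- diag(25)
  dimnames(id) <- list(sprintf("t%d", 1:25), sprintf("t%d", 1:25))
  expect_warning(res <- rmt_threshold(id), "fallback")
  expect_true(res$fallback)
  expect_equal(res$threshold, 0.8)

  # planted two-block correlation: cutoff lands between the block levels
  cc <- matrix(0.1, 30, 30)
  cc[1:15, 1:15] <- 0.9
  cc[16:30, 16:30] <- 0.9
  diag(cc) <- 1
  dimnames(cc) <- list(sprintf("t%d", 1:30), sprintf("t%d", 1:30))
  res2 <- rmt_threshold(cc)
  expect_false(res2$fallback)
  expect_gt(res2$threshold, 0.1)
  expect_lte(res2$threshold, 0.9)
  g <- build_network(cc, res2$threshold)
  expect_equal(igraph::components(g)$no, 2L)

  # a GOE spectrum is Wigner-like, not Poisson-like
  ev <- withr::with_seed(77, {
    a <- matrix(rnorm(500 * 500), 500)
    eigen((a + t(a)) / sqrt(2), symmetric = TRUE, only.values = TRUE)$values
  })
  fit <- nnsd_fit(ev)
  expect_gt(fit$chisq_poisson, fit$chisq_goe)
})

test_that("network construction thresholds |r| and keeps signs", {
  cc <- diag(3)
  cc[1, 2] <- cc[2, 1] <- 0.9
  cc[2, 3] <- cc[3, 2] <- 0.2
  cc[1, 3] <- cc[3, 1] <- -0.95
  dimnames(cc) <- list(c("a", "b", "c"), c("a", "b", "c"))
  g <- build_network(cc, 0.8)
  expect_equal(igraph::ecount(g), 2L)
  expect_setequal(igraph::E(g)$sign, c(1, -1))
  expect_equal(topology_panel(g, seed = 1)$positive_edge_fraction, 0.5)

  # lowering the threshold can only add edges
  withr::with_seed(21, {
    for (i in 1:5) {
      m <- matrix(runif(100, -1, 1), 10)
      m <- (m + t(m)) / 2; diag(m) <- 1
      dimnames(m) <- list(sprintf("t%d", 1:10), sprintf("t%d", 1:10))
      lo <- tryCatch(build_network(m, 0.3), error = function(e) NULL)
      hi <- tryCatch(build_network(m, 0.7), error = function(e) NULL)
      e_lo <- if (is.null(lo)) 0 else igraph::ecount(lo)
      e_hi <- if (is.null(hi)) 0 else igraph::ecount(hi)
      expect_gte(e_lo, e_hi)
    }
  })
})

test_that("module detection recovers planted modules with known Q", {
  two <- igraph::disjoint_union(igraph::make_full_graph(5),
                                igraph::make_full_graph(5))
  igraph::V(two)$name <- sprintf("n%d", 1:10)
  md <- detect_modules(two, seed = 1)
  expect_equal(length(unique(md$membership)), 2L)
  expect_equal(md$modularity, 0.5)  # Q = sum(e_ii - a_i^2) for equal cliques

  full <- igraph::make_full_graph(6)
  igraph::V(full)$name <- sprintf("n%d", 1:6)
  mdf <- detect_modules(full, seed = 1)
  expect_lte(mdf$modularity, 1e-9)
  expect_gte(md$modularity, 0)  # beats the trivial one-module partition
})

test_that("topology panel matches hand enumeration on small graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  pt <- topology_panel(tri, seed = 1)
  expect_equal(pt$average_clustering_coefficient, 1)
  expect_equal(pt$average_path_distance, 1)
  expect_equal(pt$transitivity, 1)
  expect_equal(pt$connectedness, 1)
  expect_equal(pt$average_degree, 2)

  path <- igraph::make_graph(~ A - B, B - C)
  pp <- topology_panel(path, seed = 1)
  expect_equal(pp$average_path_distance, 4 / 3)
  expect_equal(pp$geodesic_efficiency, 5 / 6)
  expect_equal(pp$harmonic_geodesic_distance, 3 / (1 + 1 + 0.5))

  twopair <- igraph::make_graph(~ A - B, C - D)
  expect_equal(topology_panel(twopair, seed = 1)$connectedness, 1 / 3)
})

test_that("maslov-sneppen rewiring preserves degrees; stars cannot move", {
  g <- withr::with_seed(31, igraph::sample_gnm(30, 60))
  igraph::V(g)$name <- sprintf("n%d", 1:30)
  r <- maslov_sneppen(g, n_swaps_per_edge = 20, seed = 1)
  expect_equal(sort(igraph::degree(r)), sort(igraph::degree(g)))
  expect_false(igraph::identical_graphs(r, g))

  star <- igraph::make_star(8, mode = "undirected")
  igraph::V(star)$name <- sprintf("n%d", 1:8)
  expect_warning(rs <- maslov_sneppen(star, seed = 1), "unchanged")
  expect_equal(igraph::as_edgelist(rs), igraph::as_edgelist(star))
})

test_that("natural connectivity matches spectral closed forms", {
  none <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(natural_connectivity(none), 0)

  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)

  # K_n: eigenvalues are (n-1) once and -1 (n-1) times
  vals <- sapply(4:10, function(n)
    natural_connectivity(igraph::make_full_graph(n)))
  expected <- sapply(4:10, function(n)
    log((exp(n - 1) + (n - 1) * exp(-1)) / n))
  expect_equal(vals, expected, tolerance = 1e-9)
  expect_true(all(diff(vals) > 0))
})

test_that("robustness curves anchor at the intact network and fragment stars", {
  full <- igraph::make_full_graph(10)
  rc <- robustness_curve(full, fractions = c(0, 0.2, 0.5), n_reps = 20,
                         seed = 1)
  expect_equal(rc$lcc_mean[1], 1)
  expect_equal(rc$lcc_sd[1], 0)
  expect_equal(rc$natcon_mean[1], natural_connectivity(full))
  expect_true(all(rc$lcc_mean == 1))  # complete graphs never fragment

  # star: removing the hub shatters everything; exact expectation is
  # E[lcc] = (k/N) * 1/(N-k) + (1 - k/N) * 1 for k removed of N
  star <- igraph::make_star(20, mode = "undirected")
  n <- 20; k <- floor(0.25 * n)
  exp_lcc <- (k / n) * (1 / (n - k)) + (1 - k / n) * 1
  rcs <- robustness_curve(star, fractions = c(0, 0.25), n_reps = 400,
                          seed = 2)
  expect_equal(rcs$lcc_mean[2], exp_lcc, tolerance = 0.05)
})

test_that("Zi-Pi roles follow the published cutoffs", {
  # module with an internal star: the hub's within-module degree z-score
  # clears 2.5, and all its links stay inside -> module hub
  g <- igraph::make_star(14, mode = "undirected", center = 1)
  g <- igraph::add_vertices(g, 3)
  g <- igraph::add_edges(g, c(15, 16, 16, 17, 15, 17))
  igraph::V(g)$name <- sprintf("n%d", 1:17)
  mem <- c(rep(1, 14), rep(2, 3))
  zp <- zi_pi(g, mem)
  hub <- zp[zp$node == "n1", ]
  expect_gte(hub$zi, 2.5)
  expect_equal(hub$pi, 0)
  expect_equal(hub$role, "module_hub")
  leaf <- zp[zp$node == "n2", ]
  expect_equal(leaf$role, "peripheral")

  # node with k = 4 split 2/2 across two modules: Pi = 0.5
  h <- igraph::make_graph(~ x - a, x - b, x - c, x - d, a - b, c - d)
  memh <- c(1, 1, 1, 2, 2)  # x,a,b | c,d
  names(memh) <- c("x", "a", "b", "c", "d")
  zph <- zi_pi(h, memh[igraph::V(h)$name])
  expect_equal(zph$pi[zph$node == "x"], 0.5)

  # connector and network hub thresholds: Pi >= 0.62 flips the role
  expect_equal(zi_pi_role(zi = 3.0, pi = 0.7), "network_hub")
  expect_equal(zi_pi_role(zi = 1.0, pi = 0.7), "connector")
  expect_equal(zi_pi_role(zi = 3.0, pi = 0.5), "module_hub")
  expect_equal(zi_pi_role(zi = 1.0, pi = 0.5), "peripheral")
})

test_that("trophic edge summaries count group pairs exhaustively", {
  g <- igraph::make_graph(~ p1 - c1, p1 - c2, p2 - c1, p2 - c2, p1 - p2)
  igraph::V(g)$trophic_group <-
    ifelse(grepl("^p", igraph::V(g)$name), "photosynthetic", "consumer")
  ts <- trophic_edge_summary(g)
  expect_equal(ts$edge_counts["photosynthetic", "consumer"], 4)
  expect_equal(ts$edge_counts["photosynthetic", "photosynthetic"], 1)
  expect_equal(ts$edge_counts["consumer", "consumer"], 0)
  expect_equal(sum(ts$degree_share), 1)
  # photosynthetic degree: 3 + 3 of total 10
  expect_equal(unname(ts$degree_share["photosynthetic"]), 0.6)

  one <- igraph::make_full_graph(4)
  igraph::V(one)$trophic_group <- rep("consumer", 4)
  to <- trophic_edge_summary(one)
  expect_equal(unname(to$edge_counts["consumer", "consumer"]), 6L)
})
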