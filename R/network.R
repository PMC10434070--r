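# Signed co-occurrence networks: construction from log-abundance Pearson
# correlations with an RMT-guided cutoff, topology/complexity panel,
# degree-preserving random ensembles, stability (robustness, natural
# connectivity) and Zi-Pi node roles.  All topology and stability metrics
# treat the graph as unweighted; the signed correlation is kept as an
# edge attribute only.

#' Prevalence filter
#'
#' Keeps taxa detected in at least `ceil(min_fraction * n_samples)`
#' samples; 40 percent is the conventional cutoff before correlation
#' network construction.
#'
#' @param table abundance matrix (taxa x samples).
#' @param min_fraction minimum occurrence fraction in \[0, 1\].
#' @return filtered abundance matrix.
#' @export
filter_prevalence <- function(table, min_fraction = 0.4) {
  check_table(table)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(table))
  keep <- rowSums(table > 0) >= need
  if (!any(keep))
    stop("no taxa pass the prevalence filter (", sum(keep), " of ",
         nrow(table), ")")
  table[keep, , drop = FALSE]
}

#' Pearson correlations of log-transformed abundances
#'
#' Computes pairwise Pearson correlations between taxa on
#' `log(count + 1)` across samples.  Taxa with zero variance after the
#' transform are dropped with a message.
#'
#' @param table abundance matrix (taxa x samples, >= 4 samples).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  check_table(table, min_taxa = 2L, min_samples = 4L)
  lx <- log(table + 1)
  v <- apply(lx, 1L, stats::var)
  if (any(v == 0)) {
    message("dropping ", sum(v == 0), " zero-variance taxon/taxa")
    lx <- lx[v > 0, , drop = FALSE]
  }
  if (nrow(lx) < 2L) stop("fewer than 2 taxa with variance")
  stats::cor(t(lx))
}

#' Nearest-neighbour spacing distribution fit
#'
#' Unfolds a symmetric-matrix spectrum with a smoothed empirical CDF
#' (smoothing spline; raw ECDF when fewer than 5 distinct eigenvalues),
#' normalizes spacings to unit mean, bins them on \[0, 3\] (values above
#' 3 fall in the last bin) and returns chi-squared distances of the
#' binned spacing density to the Poisson law `exp(-s)` and to the
#' Gaussian-orthogonal-ensemble Wigner surmise
#' `(pi s / 2) exp(-pi s^2 / 4)`.  A Poisson-like spacing distribution is
#' the random-matrix-theory signature of a graph spectrum dominated by
#' modular (non-random) structure.
#'
#' @param eigenvalues numeric vector of eigenvalues (>= 8).
#' @param n_bins number of spacing bins.
#' @return list with `chisq_poisson`, `chisq_goe` and the unit-mean
#'   `spacings`.
#' @export
nnsd_fit <- function(eigenvalues, n_bins = 20L) {
  ev <- sort(eigenvalues)
  n <- length(ev)
  if (n < 8L) stop("need at least 8 eigenvalues")
  ux <- unique(ev)
  if (length(ux) >= 5L) {
    df <- min(15, max(4, round(sqrt(n))))
    fit <- stats::smooth.spline(ev, seq_len(n) / n, df = df)
    e <- n * stats::predict(fit, ev)$y
  } else {
    e <- n * stats::ecdf(ev)(ev)
  }
  s <- diff(sort(e))
  if (mean(s) <= 0) stop("degenerate spectrum: no spread in eigenvalues")
  s <- s / mean(s)
  breaks <- seq(0, 3, length.out = n_bins + 1L)
  o <- tabulate(findInterval(pmin(s, 3 - 1e-12), breaks,
                             rightmost.closed = TRUE), n_bins) / length(s)
  cdf_p <- function(x) 1 - exp(-x)
  cdf_g <- function(x) 1 - exp(-pi * x^2 / 4)
  e_p <- diff(cdf_p(breaks)); e_p[n_bins] <- e_p[n_bins] + 1 - cdf_p(3)
  e_g <- diff(cdf_g(breaks)); e_g[n_bins] <- e_g[n_bins] + 1 - cdf_g(3)
  list(chisq_poisson = sum((o - e_p)^2 / e_p),
       chisq_goe = sum((o - e_g)^2 / e_g),
       spacings = s)
}

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate cutoffs from `t_min` to `t_max`: at each cutoff the
#' adjacency `|r| >= t` is formed, the spectrum of the largest connected
#' component is unfolded, and its nearest-neighbour spacing distribution
#' is compared against Poisson and GOE laws ([nnsd_fit()]).  The smallest
#' cutoff at which the spacings fit Poisson better than GOE, with a
#' Poisson chi-squared below `acceptance_level`, is returned.  When no
#' candidate qualifies (for example a structureless correlation matrix
#' with no edges), the configured `fallback` threshold is returned with a
#' warning.
#'
#' @param corr symmetric Pearson correlation matrix (>= 20 x 20 for a
#'   meaningful spectrum).
#' @param t_min,t_max,step candidate threshold grid.
#' @param n_bins spacing bins passed to [nnsd_fit()].
#' @param acceptance_level maximum acceptable chi-squared distance to
#'   Poisson.
#' @param min_nodes smallest component size whose spectrum is trusted.
#' @param fallback threshold used when the scan fails.
#' @return list with `threshold`, `fallback` (logical) and the per-
#'   candidate scan table.
#' @export
rmt_threshold <- function(corr, t_min = 0.3, t_max = 0.95, step = 0.01,
                          n_bins = 20L, acceptance_level = 10,
                          min_nodes = 10L, fallback = 0.8) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  scan <- list()
  for (t in seq(t_min, t_max, by = step)) {
    a <- abs(corr) >= t
    diag(a) <- FALSE
    if (!any(a)) next
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    comp <- igraph::components(g)
    if (max(comp$csize) < min_nodes) next
    big <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(g, big)
    ev <- eigen(igraph::as_adjacency_matrix(sub, sparse = FALSE),
                symmetric = TRUE, only.values = TRUE)$values
    fit <- tryCatch(nnsd_fit(ev, n_bins), error = function(e) NULL)
    if (is.null(fit)) next
    scan[[length(scan) + 1L]] <-
      data.frame(threshold = t, nodes = length(big),
                 chisq_poisson = fit$chisq_poisson,
                 chisq_goe = fit$chisq_goe)
    if (fit$chisq_poisson < fit$chisq_goe &&
        fit$chisq_poisson <= acceptance_level)
      return(list(threshold = t, fallback = FALSE,
                  scan = do.call(rbind, scan)))
  }
  warning("RMT scan found no Poisson-like threshold; using fallback ",
          fallback)
  list(threshold = fallback, fallback = TRUE,
       scan = if (length(scan)) do.call(rbind, scan) else NULL)
}

#' Build a signed co-occurrence network from a correlation matrix
#'
#' Draws an undirected edge between taxa `i != j` whenever
#' `|r_ij| >= threshold`; the signed correlation is stored as the edge
#' `weight` and its sign as `sign`.  Isolated nodes are removed, and
#' trophic-group attributes are attached when an annotation is supplied.
#'
#' @param corr symmetric correlation matrix with taxon dimnames.
#' @param threshold correlation cutoff in (0, 1).
#' @param annotation optional annotation data.frame (`taxon_id`,
#'   `trophic_group`).
#' @return an undirected [igraph::igraph] network.
#' @export
build_network <- function(corr, threshold, annotation = NULL) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            threshold > 0, threshold < 1)
  a <- abs(corr) >= threshold
  diag(a) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  if (igraph::ecount(g) == 0L) stop("no edges at threshold ", threshold)
  ends <- igraph::as_edgelist(g, names = FALSE)
  r <- corr[cbind(ends[, 1L], ends[, 2L])]
  igraph::E(g)$weight <- r
  igraph::E(g)$sign <- sign(r)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  if (!is.null(annotation)) {
    idx <- match(igraph::V(g)$name, annotation$taxon_id)
    igraph::V(g)$trophic_group <- annotation$trophic_group[idx]
  }
  g
}

#' Detect network modules
#'
#' Multilevel (Louvain) greedy modularity maximization on the unweighted
#' graph, deterministic given the seed, returning the partition and the
#' Newman-Girvan modularity Q.
#'
#' @param net an [igraph::igraph] network.
#' @param seed optional seed.
#' @return list with `membership` (named integer vector) and
#'   `modularity`.
#' @export
detect_modules <- function(net, seed = NULL) {
  stopifnot(igraph::is_igraph(net))
  local_seed(seed, {
    cl <- igraph::cluster_louvain(net, weights = NA)
    mem <- igraph::membership(cl)
    ones <- rep(1, igraph::ecount(net))
    list(membership = mem,
         modularity = igraph::modularity(net, mem, weights = ones))
  })
}

#' Topology panel of a co-occurrence network
#'
#' Standard unweighted metrics: node and link counts, fraction of
#' positive edges, average degree (`2L/N`), Watts-Strogatz average
#' clustering coefficient (nodes of degree < 2 contribute 0), average
#' geodesic distance over connected pairs, harmonic mean geodesic
#' distance (disconnected pairs excluded), geodesic efficiency (mean of
#' `1/d` with disconnected pairs contributing 0), connectedness
#' (fraction of node pairs joined by a path), modularity Q, global
#' transitivity, and the R-squared of an ordinary log-log fit of the
#' degree distribution (`NA` when fewer than 3 distinct degrees).
#'
#' @param net an [igraph::igraph] network.
#' @param membership optional module partition; computed via
#'   [detect_modules()] when absent.
#' @param seed seed for module detection when `membership` is `NULL`.
#' @return named list of metrics.
#' @export
topology_panel <- function(net, membership = NULL, seed = NULL) {
  stopifnot(igraph::is_igraph(net), igraph::vcount(net) > 0L)
  n <- igraph::vcount(net)
  l <- igraph::ecount(net)
  pos_frac <- if ("sign" %in% igraph::edge_attr_names(net) && l > 0)
    mean(igraph::E(net)$sign > 0)
  else if ("weight" %in% igraph::edge_attr_names(net) && l > 0)
    mean(igraph::E(net)$weight > 0)
  else NA_real_
  if (is.null(membership)) membership <- detect_modules(net, seed)$membership
  dmat <- igraph::distances(net, weights = NA)
  geo <- dmat[upper.tri(dmat)]
  finite <- is.finite(geo)
  harm <- if (any(finite)) sum(finite) / sum(1 / geo[finite]) else NA_real_
  eff <- if (length(geo)) mean(ifelse(finite, 1 / geo, 0)) else NA_real_
  conn <- if (length(geo)) mean(finite) else NA_real_
  deg <- igraph::degree(net)
  tab <- table(deg[deg >= 1L])
  pl_r2 <- if (length(tab) >= 3L) {
    k <- as.numeric(names(tab))
    pk <- as.numeric(tab) / sum(tab)
    summary(stats::lm(log(pk) ~ log(k)))$r.squared
  } else NA_real_
  list(total_nodes = n,
       total_links = l,
       positive_edge_fraction = pos_frac,
       average_degree = 2 * l / n,
       average_clustering_coefficient =
         igraph::transitivity(net, type = "localaverage", isolates = "zero"),
       average_path_distance =
         igraph::mean_distance(net, weights = NA, unconnected = TRUE),
       harmonic_geodesic_distance = harm,
       geodesic_efficiency = eff,
       connectedness = conn,
       modularity = igraph::modularity(net, membership,
                                       weights = rep(1, l)),
       transitivity = igraph::transitivity(net, type = "global"),
       powerlaw_R2 = pl_r2)
}

#' Maslov-Sneppen degree-preserving rewiring
#'
#' Randomizes a network by double-edge swaps that preserve every node's
#' degree; swaps that would create self-loops or multi-edges are never
#' applied.
#' Graphs admitting no valid swap (e.g. a star) are returned unchanged
#' with a warning.  Edge weights are dropped: a rewired edge has no
#' meaningful correlation.
#'
#' @param net an [igraph::igraph] network with >= 2 edges.
#' @param n_swaps_per_edge attempted swaps per edge.
#' @param seed optional seed.
#' @return a rewired [igraph::igraph] network with the same degree
#'   sequence.
#' @export
maslov_sneppen <- function(net, n_swaps_per_edge = 100L, seed = NULL) {
  stopifnot(igraph::is_igraph(net), igraph::ecount(net) >= 2L)
  g <- net
  for (a in igraph::edge_attr_names(g)) g <- igraph::delete_edge_attr(g, a)
  out <- local_seed(seed, {
    igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = n_swaps_per_edge * igraph::ecount(g)))
  })
  same <- igraph::identical_graphs(
    out, g) || igraph::ecount(igraph::difference(out, g)) == 0L
  if (same) warning("no valid degree-preserving swap; graph unchanged")
  out
}

#' Random-network ensemble baseline
#'
#' Generates `n` Maslov-Sneppen randomizations of a network and reports
#' the mean and standard deviation of each [topology_panel()] metric over
#' the ensemble, the conventional baseline for judging whether empirical
#' modularity or clustering exceeds random expectation.
#'
#' @param net an [igraph::igraph] network.
#' @param n ensemble size (100 by default).
#' @param n_swaps_per_edge attempted swaps per edge per randomization.
#' @param seed optional seed.
#' @return list with `mean` and `sd` (named numeric vectors) and `n`.
#' @export
random_ensemble <- function(net, n = 100L, n_swaps_per_edge = 100L,
                            seed = NULL) {
  seeds <- derive_seeds(seed, 2L * n)
  vals <- vapply(seq_len(n), function(i) {
    r <- suppressWarnings(
      maslov_sneppen(net, n_swaps_per_edge, seed = seeds[i]))
    unlist(topology_panel(r, seed = seeds[n + i]))
  }, numeric(12L))
  list(mean = rowMeans(vals),
       sd = apply(vals, 1L, stats::sd),
       n = as.integer(n))
}

#' Natural connectivity
#'
#' `ln((1/N) sum_i exp(lambda_i))` over the eigenvalues of the unweighted
#' adjacency matrix, computed with a max-eigenvalue shift for overflow
#' safety.  A spectral measure of how well connected the graph remains
#' under perturbation; an edgeless graph scores 0.
#'
#' @param net an [igraph::igraph] network with >= 1 node.
#' @return natural connectivity (a real number).
#' @export
natural_connectivity <- function(net) {
  stopifnot(igraph::is_igraph(net), igraph::vcount(net) >= 1L)
  a <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

#' Robustness under random node removal
#'
#' Simulates species extinction: for each removal fraction, deletes that
#' share of nodes uniformly at random and records the fraction of
#' remaining nodes in the largest component and the natural connectivity
#' of the remnant, averaged over replicates.  The area under the mean
#' largest-component curve is reported as a scalar robustness.
#'
#' @param net an [igraph::igraph] network.
#' @param fractions removal fractions (must start at 0 to anchor the
#'   intact value).
#' @param n_reps replicates per fraction.
#' @param seed optional seed.
#' @return list with `fractions`, `lcc_mean`, `lcc_sd`, `natcon_mean`,
#'   `natcon_sd` and `auc`.
#' @export
robustness_curve <- function(net, fractions = seq(0, 0.8, by = 0.05),
                             n_reps = 100L, seed = NULL) {
  stopifnot(igraph::is_igraph(net), igraph::vcount(net) >= 1L,
            all(fractions >= 0), all(fractions < 1))
  n <- igraph::vcount(net)
  one <- function(k) {
    sub <- if (k == 0L) net else
      igraph::delete_vertices(net, sample.int(n, k))
    c(lcc = max(igraph::components(sub)$csize) / igraph::vcount(sub),
      natcon = natural_connectivity(sub))
  }
  res <- local_seed(seed, {
    lapply(fractions, function(f) {
      k <- floor(f * n)
      if (k == 0L) {
        v <- one(0L)
        matrix(rep(v, n_reps), nrow = 2L,
               dimnames = list(c("lcc", "natcon"), NULL))
      } else if (k >= n) {
        stop("removal fraction leaves no nodes")
      } else {
        vapply(seq_len(n_reps), function(i) one(k), numeric(2L))
      }
    })
  })
  lcc_mean <- vapply(res, function(m) mean(m["lcc", ]), numeric(1L))
  lcc_sd <- vapply(res, function(m) stats::sd(m["lcc", ]), numeric(1L))
  nc_mean <- vapply(res, function(m) mean(m["natcon", ]), numeric(1L))
  nc_sd <- vapply(res, function(m) stats::sd(m["natcon", ]), numeric(1L))
  auc <- sum(diff(fractions) * (utils::head(lcc_mean, -1L) +
                                  utils::tail(lcc_mean, -1L)) / 2)
  list(fractions = fractions, lcc_mean = lcc_mean, lcc_sd = lcc_sd,
       natcon_mean = nc_mean, natcon_sd = nc_sd, auc = auc)
}

#' Map Zi/Pi values to topological roles
#'
#' Module hubs have `Zi >= 2.5` and `Pi < 0.62`; connectors `Zi < 2.5`
#' and `Pi >= 0.62`; network hubs both; everything else (including nodes
#' with undefined Pi) is peripheral.
#'
#' @param zi,pi numeric vectors (recycled to a common length).
#' @return character vector of roles.
#' @export
zi_pi_role <- function(zi, pi) {
  n <- max(length(zi), length(pi))
  zi <- rep_len(zi, n); pi <- rep_len(pi, n)
  role <- rep("peripheral", n)
  ok <- !is.na(pi) & !is.na(zi)
  role[ok & zi >= 2.5 & pi < 0.62] <- "module_hub"
  role[ok & zi < 2.5 & pi >= 0.62] <- "connector"
  role[ok & zi >= 2.5 & pi >= 0.62] <- "network_hub"
  role
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' `Zi` is the z-score of a node's within-module degree relative to the
#' other nodes of its module (0 by convention when the module's degrees
#' have zero spread); `Pi = 1 - sum_s (k_is / k_i)^2` over modules `s`.
#' Roles follow the conventional cutoffs: module hubs (`Zi >= 2.5`,
#' `Pi < 0.62`), connectors (`Zi < 2.5`, `Pi >= 0.62`), network hubs
#' (`Zi >= 2.5`, `Pi >= 0.62`), all others peripheral.  Isolated nodes
#' have undefined Pi and are classed peripheral.
#'
#' @param net an [igraph::igraph] network.
#' @param membership module partition covering all nodes (from
#'   [detect_modules()]).
#' @return data.frame with `node`, `module`, `zi`, `pi`, `role`.
#' @export
zi_pi <- function(net, membership) {
  stopifnot(igraph::is_igraph(net),
            length(membership) == igraph::vcount(net))
  mem <- as.integer(membership)
  a <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  k <- rowSums(a)
  mods <- sort(unique(mem))
  # k_is: links of node i into module s
  kis <- vapply(mods, function(s) rowSums(a[, mem == s, drop = FALSE]),
                numeric(nrow(a)))
  kown <- kis[cbind(seq_along(mem), match(mem, mods))]
  zi <- numeric(length(mem))
  for (s in mods) {
    idx <- mem == s
    mu <- mean(kown[idx]); sdv <- stats::sd(kown[idx])
    zi[idx] <- if (is.na(sdv) || sdv == 0) 0 else (kown[idx] - mu) / sdv
  }
  pi <- ifelse(k > 0, 1 - rowSums((kis / pmax(k, 1))^2), NA_real_)
  if (anyNA(pi)) message(sum(is.na(pi)),
                         " isolated node(s) classed peripheral")
  role <- zi_pi_role(zi, pi)
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_along(mem))
  data.frame(node = nm, module = mem, zi = zi, pi = pi, role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Edge counts and degree shares by trophic group
#'
#' @param net an [igraph::igraph] network whose vertices carry a
#'   `trophic_group` attribute (or supply `annotation`).
#' @param annotation optional annotation data.frame (`taxon_id`,
#'   `trophic_group`) used when the attribute is absent.
#' @return list with `edge_counts` (symmetric group x group matrix) and
#'   `degree_share` (per-group share of total degree, summing to 1).
#' @export
trophic_edge_summary <- function(net, annotation = NULL) {
  stopifnot(igraph::is_igraph(net))
  grp <- if ("trophic_group" %in% igraph::vertex_attr_names(net)) {
    igraph::V(net)$trophic_group
  } else if (!is.null(annotation)) {
    annotation$trophic_group[match(igraph::V(net)$name,
                                   annotation$taxon_id)]
  } else stop("no trophic annotation available")
  grp[is.na(grp)] <- "unclassified"
  lev <- sort(unique(grp))
  counts <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  ends <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(ends)) {
    g1 <- grp[ends[, 1L]]; g2 <- grp[ends[, 2L]]
    for (e in seq_len(nrow(ends))) {
      counts[g1[e], g2[e]] <- counts[g1[e], g2[e]] + 1L
      if (g1[e] != g2[e]) counts[g2[e], g1[e]] <- counts[g2[e], g1[e]] + 1L
    }
  }
  deg <- igraph::degree(net)
  share <- tapply(deg, factor(grp, levels = lev), sum)
  share[is.na(share)] <- 0
  total <- sum(share)
  share <- if (total > 0) share / total else share
  list(edge_counts = counts, degree_share = share)
}
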