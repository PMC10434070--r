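#' Simulation configuration for synthetic lake communities
#'
#' Bundles the knobs of the synthetic community generator.  Defaults
#' emulate a survey of eight lakes spanning a salinity gradient from
#' fresh (<1 percent) to saline (~11.3 percent), roughly a thousand
#' denoised taxa, and post-rarefaction sequencing depth.
#'
#' @param n_lakes number of lakes.
#' @param samples_per_lake surface-water samples per lake.
#' @param n_taxa regional species-pool size.
#' @param salinity_levels per-lake salinity levels (percent); recycled or
#'   truncated to `n_lakes`.
#' @param filtering_strength exponent `w >= 0` on the Gaussian niche
#'   filter; `w = 0` is the neutral (no-selection) regime.
#' @param niche_width Gaussian niche breadth sigma on the salinity axis
#'   (percent units).
#' @param brownian_rate Brownian-motion rate for the evolution of
#'   salinity optima along the phylogeny (trait sd per unit branch
#'   length).
#' @param sequencing_depth reads per sample (multinomial total); at least
#'   100.
#' @param regional_lognormal `c(meanlog, sdlog)` of the i.i.d. lognormal
#'   regional abundances.
#' @param salinity_jitter_sd sd of the lognormal jitter applied to each
#'   lake's salinity level across its samples.
#' @param root_optimum salinity optimum at the root of the phylogeny.
#' @param trophic_proportions named probabilities over the six trophic
#'   groups (must sum to 1); the default weights photosynthetic taxa
#'   highest, as in algae-dominated lake communities.
#' @param n_classes,n_orders number of synthetic class / order labels cut
#'   from the phylogeny for rank-aggregation analyses.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @return a list of validated settings (class `lakeco_config`).
#' @export
simulation_config <- function(n_lakes = 8L,
                              samples_per_lake = 10L,
                              n_taxa = 1000L,
                              salinity_levels = c(0.3, 0.5, 0.6, 0.7, 0.9,
                                                  3.6, 6.2, 11.3),
                              filtering_strength = 1,
                              niche_width = 1.5,
                              brownian_rate = 2,
                              sequencing_depth = 10000L,
                              regional_lognormal = c(meanlog = 0, sdlog = 1),
                              salinity_jitter_sd = 0.05,
                              root_optimum = 2,
                              trophic_proportions = c(consumer = 0.15,
                                                      saprotroph = 0.08,
                                                      parasite = 0.07,
                                                      photosynthetic = 0.50,
                                                      mixotroph = 0.08,
                                                      unclassified = 0.12),
                              n_classes = 15L, n_orders = 45L,
                              seed = 1L) {
  cfg <- list(n_lakes = as.integer(n_lakes),
              samples_per_lake = as.integer(samples_per_lake),
              n_taxa = as.integer(n_taxa),
              salinity_levels = rep_len(salinity_levels, n_lakes),
              filtering_strength = filtering_strength,
              niche_width = niche_width,
              brownian_rate = brownian_rate,
              sequencing_depth = as.integer(sequencing_depth),
              regional_lognormal = regional_lognormal,
              salinity_jitter_sd = salinity_jitter_sd,
              root_optimum = root_optimum,
              trophic_proportions = trophic_proportions,
              n_classes = as.integer(n_classes),
              n_orders = as.integer(n_orders),
              seed = as.integer(seed))
  stopifnot(cfg$n_lakes >= 1, cfg$samples_per_lake >= 1, cfg$n_taxa >= 3,
            all(cfg$salinity_levels >= 0), cfg$filtering_strength >= 0,
            cfg$niche_width > 0, cfg$brownian_rate >= 0,
            cfg$sequencing_depth >= 100, cfg$salinity_jitter_sd >= 0,
            length(cfg$regional_lognormal) == 2)
  if (abs(sum(cfg$trophic_proportions) - 1) > 1e-8 ||
      any(cfg$trophic_proportions < 0) ||
      !setequal(names(cfg$trophic_proportions), trophic_levels()))
    stop("trophic_proportions must be named over the six groups and sum to 1")
  class(cfg) <- "lakeco_config"
  cfg
}

#' Simulate sample metadata along a salinity gradient
#'
#' Each lake gets a fixed salinity level; samples within a lake jitter
#' around it lognormally.  Lake coordinates, altitude, water temperature,
#' nutrients and climate covariates (MAT, MAP, APDSI) are drawn once per
#' lake; APDSI is generated negatively correlated with log salinity, so a
#' drought signal is present for biomarker models.
#'
#' @param cfg a [simulation_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return metadata data.frame (one row per sample) with `sample_id`,
#'   `lake`, `salinity`, `water_class` and covariate columns.
#' @export
simulate_environment <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "lakeco_config"))
  local_seed(seed, {
    nl <- cfg$n_lakes; ns <- cfg$samples_per_lake
    lakes <- sprintf("L%02d", seq_len(nl))
    lat <- runif(nl, 37, 49)
    lon <- runif(nl, 87, 117)
    alt <- runif(nl, 300, 2100)
    mat <- rnorm(nl, 6, 2)
    map <- rnorm(nl, 250, 80)
    lev <- cfg$salinity_levels
    zsal <- log(lev + 0.05)
    zsal <- if (nl > 1 && stats::sd(zsal) > 0)
      (zsal - mean(zsal)) / stats::sd(zsal) else rep(0, nl)
    apdsi_lake <- -1 * zsal + rnorm(nl, 0, 0.6)
    out <- do.call(rbind, lapply(seq_len(nl), function(i) {
      sal <- lev[i] * exp(rnorm(ns, 0, cfg$salinity_jitter_sd))
      data.frame(
        sample_id = sprintf("%s_S%02d", lakes[i], seq_len(ns)),
        lake = lakes[i],
        salinity = sal,
        wt = rnorm(ns, 18, 2),
        tn = rlnorm(ns, 0.5, 0.4),
        tp = rlnorm(ns, -1.5, 0.4),
        apdsi = apdsi_lake[i] + rnorm(ns, 0, 0.3),
        mat = mat[i], map = map[i],
        latitude = lat[i], longitude = lon[i], altitude = alt[i],
        stringsAsFactors = FALSE)
    }))
    out$water_class <- water_class(out$salinity)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed optional seed.
#' @return an ultrametric rooted binary [ape::phylo] tree with tips
#'   labelled `ZOTU0001`, `ZOTU0002`, ...
#' @export
simulate_phylogeny <- function(n_taxa, seed = NULL) {
  stopifnot(n_taxa >= 3)
  local_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tr$tip.label <- sprintf("ZOTU%04d", seq_len(n_taxa))
    tr
  })
}

#' Evolve salinity niche optima along a phylogeny
#'
#' Optima follow Brownian motion along branches (variance
#' `brownian_rate^2` per unit branch length) from `root_optimum`, then
#' are clipped to the `clip` range; regional abundances are i.i.d.
#' lognormal.  Brownian evolution is what gives selection a phylogenetic
#' signal, the premise of nearest-taxon-based null models.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param brownian_rate Brownian sd per unit branch length (0 collapses
#'   all optima onto the root value).
#' @param root_optimum trait value at the root (salinity percent).
#' @param regional_lognormal `c(meanlog, sdlog)` of regional abundances.
#' @param clip clipping range for optima (percent).
#' @param seed optional seed.
#' @return data.frame with `taxon_id`, `optimum`, `regional_abundance`.
#' @export
evolve_niche_optima <- function(tree, brownian_rate = 2, root_optimum = 2,
                                regional_lognormal = c(0, 1),
                                clip = c(0, 15), seed = NULL) {
  validate_tree(tree)
  stopifnot(brownian_rate >= 0, length(clip) == 2L, clip[1] < clip[2])
  local_seed(seed, {
    opt <- ape::rTraitCont(tree, model = "BM", sigma = brownian_rate,
                           root.value = root_optimum)
    opt <- pmin(pmax(opt, clip[1]), clip[2])
    reg <- rlnorm(length(opt), regional_lognormal[1], regional_lognormal[2])
    data.frame(taxon_id = names(opt), optimum = as.numeric(opt),
               regional_abundance = reg, stringsAsFactors = FALSE)
  })
}

#' Assemble multinomial communities under Gaussian salinity filtering
#'
#' For a sample at salinity `s`, taxon `j` is drawn with weight
#' proportional to `regional_j * exp(-w (s - opt_j)^2 / (2 sigma^2))`,
#' where `w` is the filtering strength and `sigma` the niche width;
#' counts are multinomial at fixed `depth` (so the table behaves like a
#' post-rarefaction table).  `w = 0` gives the neutral regime in which
#' expected composition is identical across salinities.
#'
#' @param metadata data.frame with `sample_id` and `salinity` columns.
#' @param profiles niche profiles from [evolve_niche_optima()].
#' @param filtering_strength selection exponent `w >= 0`.
#' @param niche_width Gaussian niche sd (percent).
#' @param depth multinomial total per sample.
#' @param seed optional seed.
#' @return abundance matrix (taxa x samples).
#' @export
assemble_communities <- function(metadata, profiles, filtering_strength = 1,
                                 niche_width = 1.5, depth = 10000L,
                                 seed = NULL) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "salinity") %in% names(metadata)),
            is.data.frame(profiles),
            all(c("taxon_id", "optimum", "regional_abundance") %in%
                  names(profiles)),
            filtering_strength >= 0, niche_width > 0, depth >= 1)
  w <- filtering_strength
  lreg <- log(profiles$regional_abundance)
  if (any(!is.finite(lreg))) stop("regional abundances must be positive")
  local_seed(seed, {
    counts <- vapply(seq_len(nrow(metadata)), function(i) {
      s <- metadata$salinity[i]
      lw <- lreg - w * (s - profiles$optimum)^2 / (2 * niche_width^2)
      lw <- lw - max(lw)
      p <- exp(lw)
      if (!any(p > 0) || anyNA(p))
        stop("all sampling weights vanished; niche_width too small?")
      as.numeric(rmultinom(1L, depth, p))
    }, numeric(nrow(profiles)))
    dimnames(counts) <- list(profiles$taxon_id, metadata$sample_id)
    abundance_table(counts)
  })
}

#' Assign trophic groups at random
#'
#' I.i.d. categorical assignment of the six trophic labels.
#'
#' @param taxon_ids character vector of taxon ids.
#' @param proportions named probabilities over the six groups, summing
#'   to 1.
#' @param seed optional seed.
#' @return data.frame with `taxon_id` and `trophic_group`.
#' @export
assign_trophic_groups <- function(taxon_ids,
                                  proportions = c(consumer = 0.15,
                                                  saprotroph = 0.08,
                                                  parasite = 0.07,
                                                  photosynthetic = 0.50,
                                                  mixotroph = 0.08,
                                                  unclassified = 0.12),
                                  seed = NULL) {
  if (!setequal(names(proportions), trophic_levels()) ||
      any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be named over the six trophic groups and sum to 1")
  local_seed(seed, {
    grp <- sample(names(proportions), length(taxon_ids), replace = TRUE,
                  prob = proportions)
    data.frame(taxon_id = taxon_ids, trophic_group = grp,
               stringsAsFactors = FALSE)
  })
}

# Cut the tip set of a tree into nested coarse (class) and fine (order)
# groups via hierarchical clustering of patristic distances; cutree on a
# single dendrogram guarantees that orders nest within classes.
assign_taxonomy <- function(tree, n_classes = 15L, n_orders = 45L) {
  d <- patristic_distances(tree)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ntip <- length(tree$tip.label)
  ncl <- min(n_classes, ntip)
  nor <- min(max(n_orders, ncl), ntip)
  data.frame(taxon_id = hc$labels,
             class = sprintf("Class%02d", stats::cutree(hc, k = ncl)),
             order = sprintf("Order%03d", stats::cutree(hc, k = nor)),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic lake survey
#'
#' Runs the whole generator: environment, Yule phylogeny, Brownian
#' salinity optima, multinomial assembly under the configured filtering
#' strength, and trophic plus synthetic class/order annotations.  All
#' randomness derives from the single master seed in `cfg`, so identical
#' configurations reproduce bit-identical surveys.
#'
#' @param cfg a [simulation_config()].
#' @return list with `table` (taxa x samples counts), `tree`, `metadata`,
#'   `profiles` and `annotation`.
#' @examples
#' sim <- simulate_community(simulation_config(n_taxa = 50,
#'   samples_per_lake = 2, sequencing_depth = 500))
#' dim(sim$table)
#' @export
simulate_community <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "lakeco_config"))
  seeds <- derive_seeds(cfg$seed, 5L)
  metadata <- simulate_environment(cfg, seed = seeds[1])
  tree <- simulate_phylogeny(cfg$n_taxa, seed = seeds[2])
  profiles <- evolve_niche_optima(tree, cfg$brownian_rate, cfg$root_optimum,
                                  cfg$regional_lognormal, seed = seeds[3])
  table <- assemble_communities(metadata, profiles, cfg$filtering_strength,
                                cfg$niche_width, cfg$sequencing_depth,
                                seed = seeds[4])
  trophic <- assign_trophic_groups(profiles$taxon_id,
                                   cfg$trophic_proportions, seed = seeds[5])
  taxonomy <- assign_taxonomy(tree, cfg$n_classes, cfg$n_orders)
  annotation <- merge(trophic, taxonomy, by = "taxon_id", sort = FALSE)
  annotation <- annotation[match(profiles$taxon_id, annotation$taxon_id), ]
  rownames(annotation) <- NULL
  list(table = table, tree = tree, metadata = metadata,
       profiles = profiles, annotation = annotation, config = cfg)
}

#' Write a simulated survey to an output directory
#'
#' Writes the abundance TSV, metadata TSV, newick tree, annotation TSV
#' and a JSON provenance record holding all generator parameters and the
#' seed.
#'
#' @param sim result of [simulate_community()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(sim$table, file.path(out_dir, "abundance.tsv"))
  write_metadata(sim$metadata, file.path(out_dir, "metadata.tsv"))
  write_annotation(sim$annotation, file.path(out_dir, "annotation.tsv"))
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  prov <- unclass(sim$config)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
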