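# lakeco

Community ecology inference for lake microeukaryote (18S amplicon)
surveys along salinity gradients.

Salinity is a dominant environmental filter on lake plankton: it erodes
diversity, narrows realized niches, tips community assembly from
stochastic toward deterministic processes, and rewires co-occurrence
structure. `lakeco` packages the statistical stack used to quantify
these effects from a taxa-by-sample ZOTU count table, a rooted
phylogeny, sample metadata and a trophic annotation:

* **Diversity & beta diversity** — rarefaction, richness, Shannon
  entropy, Bray-Curtis dissimilarity, distance-decay regressions,
  PERMANOVA, Mantel and partial Mantel permutation tests.
* **Assembly processes** — between-sample mean nearest taxon distance
  (βMNTD) and its tip-shuffle standardized effect size
  βNTI = (βMNTD_obs − μ_null)/σ_null; Bray-Curtis-based Raup-Crick
  (RC_Bray) from a richness- and abundance-preserving null; the
  five-process partition (heterogeneous selection βNTI > 2, homogeneous
  selection βNTI < −2, dispersal limitation RC > 0.95, homogenizing
  dispersal RC < −0.95, undominated otherwise); Levins niche breadth
  B_j = 1/Σ_i P_ij².
* **Networks** — Pearson correlations of log-transformed abundances
  with a 40 % prevalence filter, random-matrix-theory threshold
  selection (nearest-neighbour spacing distribution vs Poisson/GOE),
  topology panel, Maslov-Sneppen degree-preserving random ensembles,
  natural connectivity ln(mean eᵏ) over adjacency eigenvalues,
  robustness under random extinction, and Zi–Pi keystone roles
  (module hubs Zi ≥ 2.5, connectors Pi ≥ 0.62).
* **Differential abundance** — log2 fold changes of trophic or
  taxonomic group relative abundances (freshwater reference) with
  label-permutation p-values and Benjamini-Hochberg adjustment.
* **Biomarker models** — rfcv-style 10-fold cross-validated
  feature-size selection and 70/30 train/test evaluation of a
  1,000-tree random-forest regressor (injectable contract) predicting
  salinity or a drought index from taxon relative abundances at ZOTU,
  order or class resolution.

A synthetic survey generator (`simulate_community()`) with
phylogenetically conserved salinity optima and a tunable
deterministic-filtering strength `w` makes every stage testable end to
end: `w = 0` is exactly neutral, `w ≥ 3` is strong selection. See the
methods vignette (`vignettes/lake-community-inference.Rmd`) for the
models, parameter meanings and design choices.

## Worked example

```r
library(lakeco)

cfg <- simulation_config(n_taxa = 150, samples_per_lake = 3,
                         sequencing_depth = 1500, filtering_strength = 3,
                         seed = 42)
sim <- simulate_community(cfg)          # 8 lakes x 3 samples, 150 taxa

bc <- bray_curtis(sim$table)
pm <- permanova(bc, setNames(sim$metadata$lake, sim$metadata$sample_id),
                n_perm = 999, seed = 1)

ds <- dist(sim$metadata$salinity)
attr(ds, "Labels") <- sim$metadata$sample_id
dec <- decay_fit(bc, ds, n_perm = 999, seed = 2)

bn <- bnti(sim$table, sim$tree, n_null = 999, seed = 3)
rc <- rc_bray(sim$table, n_null = 999, seed = 4)
cl <- classify_assembly(bn, rc)
```

This prints (seed 42):

```
PERMANOVA by lake: R2 = 0.969, pseudo-F = 72.6, p = 0.001
Salinity decay: slope = 0.0825, R2 = 0.599, p = 0.001
heterogeneous_selection   homogeneous_selection    dispersal_limitation
                  0.363                   0.018                   0.143
 homogenizing_dispersal             undominated
                  0.311                   0.165
Bcom: freshwater 12.61 vs saline 5.10
```

Read: lake identity explains ~97 % of community variance; dissimilarity
rises significantly with salinity difference; under strong filtering
heterogeneous selection is the modal assembly process across the
salinity-spanning pair set (36 % of pairs); and community niche breadth
(Bcom, mean Levins B of the taxa present) is substantially narrower in
saline than in freshwater samples. With `filtering_strength = 0` the
same pipeline returns a null-calibrated βNTI (≈95 % of pairs inside
±2) and a stochastic-process majority.

A thin command-line wrapper covering the six pipeline stages is
installed at `inst/cli/lakeco.R`:

```sh
Rscript inst/cli/lakeco.R simulate --n-taxa 300 --w 3 --seed 7 --out-dir run1
Rscript inst/cli/lakeco.R assembly --table run1/abundance.tsv \
    --tree run1/tree.nwk --n-null 999 --seed 7 --out-dir run1/assembly
```

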