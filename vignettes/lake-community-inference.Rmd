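---
title: "Inferring community assembly, networks and biomarkers along lake salinity gradients"
author: "lakeco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly, networks and biomarkers along lake salinity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeco)
```

## The scientific problem

Inland lakes in arid and semi-arid regions span steep salinity gradients,
from fresh (below 1 %) to hypersaline water. Salinity acts as a strong
environmental filter on microeukaryotic plankton: it shrinks realized
niches, reorganizes trophic structure, and shifts the balance between
stochastic and deterministic community assembly. `lakeco` implements the
inference stack used to quantify these effects from a denoised amplicon
(ZOTU) count table, a rooted phylogeny, sample metadata and a trophic
annotation: diversity and distance-decay statistics, null-model assembly
partitioning, niche breadth, co-occurrence network complexity and
stability, trophic differential abundance, and cross-validated biomarker
regressions.

Everything operates on four inputs with fixed conventions:

* **abundance table** — integer counts, taxa x samples;
* **metadata** — one row per sample with `salinity` (%) and covariates;
  the derived `water_class` uses cutoffs freshwater < 1 %, brackish
  [1, 5), subsalt [5, 10), salt >= 10 % (configurable; the class
  boundaries between saline categories are conventions, not measured
  quantities);
* **tree** — rooted, branch lengths, tips covering the taxa;
* **annotation** — one trophic group per taxon among consumer,
  saprotroph, parasite, photosynthetic, mixotroph, unclassified.

## Null-model assembly partitioning

The core statistic is the between-sample mean nearest taxon distance

$$\beta\mathrm{MNTD}(k,m) = \tfrac12\Big(\sum_i f_{ik}\min_{j\in m} d_{ij}
  + \sum_j f_{jm}\min_{i\in k} d_{ij}\Big),$$

with $f$ relative abundances (abundance-weighted by default, a flag
exposes the presence-only variant) and $d$ patristic distance. Its
standardized effect size against a tip-shuffle null is the
beta-nearest-taxon index,
$\beta\mathrm{NTI} = (\beta\mathrm{MNTD}_{obs} - \mu_{null})/\sigma_{null}$.
Each null replicate shuffles taxon labels across all tree tips once and
scores every sample pair, so results cannot depend on the order in which
pairs are evaluated; 999 replicates is the default (the framework's
convention — the number of randomizations is a choice, not a measured
quantity). Pairs with zero null spread are returned as `NA` and excluded
from downstream fractions.

The Bray-Curtis-based Raup-Crick metric ranks each pair's observed
dissimilarity inside a null that preserves per-sample richness and total
abundance: null members are drawn with probability proportional to
occupancy frequency, seeded with one individual each, and filled to the
observed total by draws proportional to metacommunity relative
abundance. The rank is rescaled to $[-1, 1]$ with ties counted half.

`classify_assembly()` applies the conventional partition: βNTI > 2 →
heterogeneous (variable) selection; βNTI < −2 → homogeneous selection;
otherwise RC > 0.95 → dispersal limitation, RC < −0.95 → homogenizing
dispersal, everything else undominated. Boundary values (|βNTI| = 2,
|RC| = 0.95) fall on the non-extreme side, matching the strict
inequalities of the framework. βNTI and RC are computed for **all**
sample pairs; restricting to within-group pairs is left to the caller as
a post-filter, since the choice of pair universe is an analysis decision
rather than part of the statistic.

Levins niche breadth is $B_j = 1/\sum_i P_{ij}^2$ where $P_{ij}$ is
taxon $j$'s distribution **across** samples (each taxon's counts
normalized over samples). This row-normalized reading is the standard
Levins resource-use formulation and is what makes $B$ range from 1
(confined to one sample) to $N$ (even spread over all $N$ samples); the
alternative within-sample normalization would not have that range. The
per-sample community value `Bcom` is the mean $B_j$ over taxa occurring
in the sample.

## Diversity, decay and permutation tests

Alpha diversity (observed richness and Shannon entropy, natural log by
default with a configurable base) is intended for tables rarefied to a
common depth; `rarefy()` subsamples without replacement, defaulting to
the minimum column sum, with an explicit policy for shallower samples
(error or drop — never silent). Bray-Curtis dissimilarity, PERMANOVA
(Anderson's pseudo-F with freely permuted sample labels — the survey has
no blocking structure), distance-decay ordinary least squares with
Mantel-style id-permutation p-values, and the partial Mantel test follow
their textbook definitions. All permutation p-values use the
$(1 + \#\{\text{exceedances}\})/(1 + n_{perm})$ estimator and are
two-sided where a direction is not inherent; under exchangeable nulls
these tests are calibrated, and the test suite verifies nominal type-I
error at 1,000 simulations.

Differential abundance of trophic or taxonomic groups is reported as the
log2 fold change of group-mean **relative** abundances with the
freshwater-type group as reference,
$\log_2((\bar x_{salt} + c)/(\bar x_{fresh} + c))$, a label-permutation
p-value on the difference of group means, and Benjamini-Hochberg
adjustment across features. The pseudo-fraction $c$ defaults to half the
smallest nonzero relative abundance. A negative-binomial Wald model
would operate on normalized raw counts instead; the permutation test on
relative abundances was chosen because the reported quantity is the fold
change itself and a permutation null makes no distributional
assumptions. The two approaches can differ when library sizes are very
uneven, which is why rarefied input is recommended.

## Co-occurrence networks

Networks are built per sample group. We use the freshwater and salt
water-class subsets as the default contrast, each with the 40 %
prevalence filter applied **within** the group's samples, Pearson
correlation on $\ln(\mathrm{count}+1)$ (the offset makes zeros
well-defined; correlations are computed on rarefied counts by
preference), and an edge wherever $|r|$ clears the threshold. The signed
correlation is kept as an edge attribute; every topology and stability
metric treats the graph as unweighted, which is how the panel's
definitions (clustering, modularity, spacing statistics) are stated.

The threshold is selected by a random-matrix-theory scan: at each
candidate cutoff the spectrum of the largest connected component is
unfolded and its nearest-neighbour spacing distribution compared, by a
chi-squared distance over 20 bins on [0, 3], against the Poisson law
$e^{-s}$ and the Gaussian-orthogonal-ensemble Wigner surmise. The
smallest cutoff whose spacings are closer to Poisson (and below an
acceptance level, default 10) is kept; a failed scan falls back to a
configurable threshold (default 0.8) with a warning. One numerical
subtlety: unfolding with the raw empirical CDF evaluated at its own
eigenvalues yields constant spacings, so the CDF is smoothed with a
modest-df smoothing spline (df ≈ √N, capped at 15) before spacings are
taken; with fewer than five distinct eigenvalues the raw ECDF is used,
which correctly preserves degenerate (zero) spacings for clique-like
spectra.

Module detection is multilevel (Louvain) greedy modularity maximization,
seed-deterministic; modularity Q is Newman-Girvan on the unweighted
graph. Random baselines are Maslov-Sneppen degree-preserving double-edge
swaps (100 per edge, 100 ensemble replicates by default) with ensemble
means and standard deviations of the whole topology panel. Stability is
measured two ways: natural connectivity
$\ln\big(\frac1N\sum_i e^{\lambda_i}\big)$ (computed with a
max-eigenvalue shift so large graphs do not overflow), and robustness
curves under uniform random node removal, summarized by the area under
the mean largest-component-fraction curve — the paper-style "robustness"
has no published formula, so the AUC is this package's explicit choice.
Node roles use the within-module degree z-score and among-module
connectivity with the conventional cutoffs (module hubs Zi ≥ 2.5 and
Pi < 0.62, connectors Zi < 2.5 and Pi ≥ 0.62, network hubs both); a
module with zero degree spread gives Zi = 0 by convention and isolated
nodes are peripheral.

## Biomarker models

`cv_feature_sizes()` mirrors the recursive cross-validation idiom: rank
features by importance from a fit on all data, then score k-fold CV
error (10 folds, 5 repeats by default) at halving feature-set sizes.
The chosen size is the smallest whose error is within 5 % of the
minimum (with an absolute floor so numerically-zero errors do not defeat
the ratio rule). `train_evaluate()` splits 70/30 at random and reports
*prediction accuracy* as test-set explained variance,
$100\,(1 - \mathrm{MSE}/\mathrm{Var}(y_{test}))$ — accuracy for a
regression target has no standard definition, and this is the package's
single largest interpretive choice; it is bounded above by 100 and can
go negative for models worse than the test mean, which is reported
rather than clipped. The regressor sits behind a fit/predict/importances
contract; the default is a 1,000-tree random forest, and a deterministic
least-squares stub (`linear_regressor()`) exercises the pipeline logic
in tests. `compare_ranks()` repeats the procedure at class, order and
taxon resolution on rank-aggregated relative abundances.

## The synthetic community generator

`simulate_community()` produces surveys with the statistical structure
the analyses assume, so the whole pipeline is testable without any
sequencing data:

* eight lakes with salinity levels {0.3, 0.5, 0.6, 0.7, 0.9, 3.6, 6.2,
  11.3} % — five freshwater, one brackish, one subsaline, one saline —
  with small lognormal within-lake jitter (sd 0.05 on the log scale),
  and ten samples per lake; covariates include a drought index generated
  negatively correlated with log salinity;
* a pure-birth (Yule) phylogeny; salinity optima evolve along it by
  Brownian motion (rate 2 %/√branch-length from a root optimum of 2 %,
  clipped to [0, 15] %), which is what gives selection a phylogenetic
  signal — the premise of nearest-taxon null models;
* regional abundances i.i.d. lognormal(0, 1); a sample at salinity $s$
  draws taxa multinomially with weight
  $\propto \mathrm{regional}_j \cdot \exp(-w\,(s-\mathrm{opt}_j)^2 /
  (2\sigma_{niche}^2))$, at fixed depth. The filtering strength $w$ is
  the single knob separating regimes: $w = 0$ is exactly neutral (every
  sample draws from the same pool), large $w$ is strong deterministic
  filtering. The Gaussian response acts on the raw salinity axis — the
  simplest unimodal filter; nothing in the motivating system pins the
  response shape. Defaults (1,000 taxa, depth 10,000, niche width
  1.5 %) approximate the scale of a real survey while staying fast;
* trophic groups are assigned i.i.d. with photosynthetic taxa weighted
  highest (0.50), matching algae-dominated lake communities; synthetic
  class and order labels are nested cuts of the phylogeny's average-
  linkage dendrogram, so rank aggregation behaves like real taxonomy.

Because the multinomial draw happens at fixed depth, tables behave like
post-rarefaction tables. The generator does **not** emulate sequencing
error, chimeras, PCR or compositional bias, temporal dynamics, or
spatially autocorrelated dispersal; a passing pipeline therefore
demonstrates statistical correctness and parameter recovery under the
stated generative model, not robustness to those artefacts. All
randomness flows from one master seed (child streams per stage), so
identical configurations reproduce bit-identical surveys; no real
samples are dropped anywhere unless a depth policy says so.

Under this model the expected qualitative behaviour — verified by the
test suite rather than asserted — is: neutral surveys give
null-calibrated βNTI and a stochastic-process majority; strong filtering
($w \ge 3$) makes heterogeneous selection the modal process across the
salinity-spanning pair set, shrinks community niche breadth in saline
lakes, produces a positive Bray-Curtis vs salinity-difference decay
slope, leaves the saline-subset network with fewer nodes and links than
the freshwater-subset network, and lets a random forest predict salinity
from taxon relative abundances with high explained variance.

## Problem sizes, tolerances and degenerate inputs

The test suite and the acceptance script run deliberately scaled-down
surveys chosen as a package decision to keep the full pipeline fast on a
single core: assembly calibration uses 120 taxa, 16 samples, depth
1,000 and 999 null replicates; the survey-level analyses (PERMANOVA,
decay, networks, random forest) use 300 taxa, 80 samples and depth
2,000; permutation-test calibration uses 1,000 simulated datasets at 99
permutations each. Exact identities are checked to 1e-9 or tighter;
oracle equivalences (naive double-loop βMNTD, exhaustive-relabeling
PERMANOVA, an independent Raup-Crick reimplementation) to numerical
precision; stochastic calibrations to ±2 percentage points.

Degenerate inputs are handled explicitly rather than silently: all-zero
samples and taxa are errors or logged drops; zero-variance taxa leave
the correlation step with a message; a failed RMT scan falls back with a
warning; zero null variance flags βNTI pairs `NA`; a zero-spread module
gives Zi = 0; an exactly duplicated control matrix makes the partial
Mantel error rather than return 0/0.

## Limitations

Fold changes on relative abundances are compositional: a strong shift in
one dominant group necessarily moves the others. The RMT scan needs a
correlation matrix large enough for spectral statistics (≳ 20 taxa
after the prevalence filter) and degrades to the fallback threshold
below that. The Raup-Crick null conditions on occupancy and abundance as
observed, so very small surveys give coarse RC values. Network
contrasts between groups with very different sample sizes inherit the
different power of their correlation estimates; the package reports
both networks' panels and leaves the comparison ordinal.
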